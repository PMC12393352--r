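# Calcium-imaging quantification: crop window, compartment brightness with
# distance-transform background correction, trace statistics and signed head
# angles from whole-body skeletons.

#' Compute the fixed crop window around a tracked region
#'
#' The window center is the mean over frames of the per-frame mask centers
#' of mass (rounded); the size x size rectangle is clamped inside the
#' frame and identical for all frames, so compartment coordinates stay
#' comparable through the video.
#'
#' @param regionMasks list of logical matrices, one per frame.
#' @param size window edge length in px (default 110).
#' @param frameDim (rows, cols) of the full frame; defaults to the mask
#'   dimensions.
#' @return list with \code{rows} and \code{cols} (integer ranges) and
#'   \code{center}.
#' @export
computeCropWindow <- function(regionMasks, size = 110L, frameDim = NULL) {
  coms <- do.call(rbind, lapply(regionMasks, function(m) {
    p <- .pix(m)
    if (!any(p)) return(NULL)
    w <- which(p, arr.ind = TRUE)
    c(mean(w[, 1L]), mean(w[, 2L]))
  }))
  if (is.null(coms) || !nrow(coms)) stop("all region masks are empty")
  if (is.null(frameDim)) frameDim <- dim(.pix(regionMasks[[1L]]))
  ctr <- round(colMeans(coms))
  start <- ctr - floor(size / 2)
  start <- pmin(pmax(start, 1L), frameDim - size + 1L)
  list(rows = start[1L]:(start[1L] + size - 1L),
       cols = start[2L]:(start[2L] + size - 1L),
       center = ctr)
}

#' Estimate background intensity far from all structures
#'
#' The distance transform of the structure-free region identifies pixels
#' at least \code{minDistance} px from any segmented object; \code{nRegions}
#' of them are sampled uniformly without replacement (fixed seed for
#' reproducibility) and their mean intensity is the background estimate.
#' If too few pixels qualify, all eligible pixels are used; if none
#' qualify, the distance requirement is halved until some do (flagged).
#'
#' @param frame numeric matrix, the grayscale image.
#' @param structureMask combined logical mask of all segmented structures.
#' @param nRegions number of background samples (default 100).
#' @param minDistance minimum distance from any structure, px (default 40).
#' @param seed sampling seed (default 7).
#' @return background intensity scalar; attributes \code{nUsed} and
#'   \code{relaxedTo} document degraded sampling.
#' @export
sampleBackground <- function(frame, structureMask, nRegions = 100L,
                             minDistance = 40, seed = 7L) {
  p <- .pix(structureMask)
  if (!any(p)) {
    dt <- matrix(Inf, nrow(p), ncol(p))
  } else {
    free <- matrix(as.numeric(!p), nrow(p), ncol(p))
    dt <- EBImage::distmap(free)   # distance of free pixels to nearest structure
  }
  md <- minDistance
  eligible <- which(dt >= md & !p)
  relaxed <- NA_real_
  while (!length(eligible) && md > 0.5) {
    md <- md / 2
    relaxed <- md
    eligible <- which(dt >= md & !p)
  }
  if (!length(eligible)) stop("no background pixels available")
  if (length(eligible) < nRegions) {
    message("sampleBackground: only ", length(eligible),
            " eligible pixels; using all")
    sel <- eligible
  } else {
    sel <- .withSeed(seed, sample(eligible, nRegions))
  }
  out <- mean(frame[sel])
  attr(out, "nUsed") <- length(sel)
  if (!is.na(relaxed)) attr(out, "relaxedTo") <- relaxed
  out
}

#' Extract background-corrected compartment brightness traces
#'
#' Per compartment and frame, raw brightness is the mean image intensity
#' over the compartment mask; the frame's background estimate is
#' subtracted to give corrected brightness. Frames whose mask is empty
#' even after upstream interpolation yield NA and are flagged.
#'
#' @param frames H x W x T numeric array of grayscale frames.
#' @param compartmentMasks named list (one entry per compartment) of
#'   per-frame mask lists, or of single static masks.
#' @param background per-frame background vector, or NULL to estimate via
#'   \code{\link{sampleBackground}} from the union of all compartment
#'   masks.
#' @param backgroundMode with estimated background, "frame" uses each
#'   frame's own estimate; "recording" uses the mean of the per-frame
#'   estimates for all frames (appropriate for stationary illumination,
#'   and lower-variance).
#' @param nRegions,minDistance,seed background sampling controls.
#' @return a \linkS4class{CompartmentTraces}.
#' @export
extractBrightness <- function(frames, compartmentMasks, background = NULL,
                              backgroundMode = c("frame", "recording"),
                              nRegions = 100L, minDistance = 40, seed = 7L) {
  backgroundMode <- match.arg(backgroundMode)
  nT <- dim(frames)[3L]
  comps <- names(compartmentMasks)
  maskAt <- function(comp, t) {
    m <- compartmentMasks[[comp]]
    if (is.list(m)) .pix(m[[t]]) else .pix(m)
  }
  if (is.null(background)) {
    background <- vapply(seq_len(nT), function(t) {
      allm <- Reduce(`|`, lapply(comps, maskAt, t = t))
      as.numeric(sampleBackground(frames[, , t], allm, nRegions, minDistance,
                                  seed = seed + t))
    }, numeric(1))
    if (backgroundMode == "recording")
      background <- rep(mean(background), nT)
  }
  raw <- matrix(NA_real_, nT, length(comps), dimnames = list(NULL, comps))
  for (j in seq_along(comps)) {
    for (t in seq_len(nT)) {
      m <- maskAt(comps[j], t)
      if (any(m)) raw[t, j] <- mean(frames[, , t][m])
    }
  }
  if (anyNA(raw))
    message("extractBrightness: ", sum(is.na(raw)),
            " compartment-frames had empty masks (NA)")
  CompartmentTraces(raw, background, comps)
}

#' Normalize a fluorescence trace
#'
#' Default is min-max normalization to [0, 1] over the recording;
#' \code{method = "dff"} gives deltaF/F with F0 the 10th-percentile
#' baseline. A constant trace normalizes to all zeros (flagged).
#'
#' @param trace numeric vector.
#' @param method "minmax" or "dff".
#' @param f0Quantile baseline quantile for "dff" (default 0.1).
#' @return normalized numeric vector.
#' @export
normalizeTrace <- function(trace, method = c("minmax", "dff"),
                           f0Quantile = 0.1) {
  method <- match.arg(method)
  ok <- !is.na(trace)
  rng <- range(trace[ok])
  if (diff(rng) == 0) {
    warning("constant trace: normalized to zeros")
    out <- ifelse(ok, 0, NA_real_)
    attr(out, "flag") <- "constant_trace"
    return(out)
  }
  if (method == "minmax") {
    (trace - rng[1L]) / diff(rng)
  } else {
    f0 <- quantile(trace[ok], f0Quantile, names = FALSE)
    (trace - f0) / f0
  }
}

#' Mean absolute difference from the mean
#'
#' The excursion statistic behind flattening comparisons: a trace whose
#' transients were artificially flattened to baseline scores strictly
#' lower than the intact trace.
#'
#' @param trace numeric vector, length >= 2.
#' @return mean of |x_i - mean(x)|.
#' @export
meanAbsDiffFromMean <- function(trace) {
  trace <- trace[!is.na(trace)]
  stopifnot(length(trace) >= 2L)
  mean(abs(trace - mean(trace)))
}

#' Head angle from whole-body skeletons
#'
#' The head vector is the endpoint-to-endpoint direction of the anterior
#' portion of the skeleton, the body vector that of the posterior portion;
#' the signed angle between them (degrees, 0 = straight) is smoothed with
#' a centered 3-frame moving average to suppress segmentation-outline
#' jitter. Skeletons must be oriented head first (in the microfluidic
#' modality the head is the end facing the stimulus stream).
#'
#' @param skeletons list of oriented \linkS4class{WormSkeleton}.
#' @param anteriorFraction fraction of points forming the head portion
#'   (default 0.3).
#' @param smoothWindow temporal smoothing window in frames (default 3).
#' @return numeric vector of signed head angles in degrees, one per frame.
#' @export
headAngleFromBody <- function(skeletons, anteriorFraction = 0.3,
                              smoothWindow = 3L) {
  raw <- vapply(skeletons, function(sk) {
    p <- skelPoints(sk)
    n <- nrow(p)
    na <- max(2L, round(anteriorFraction * n))
    hv <- p[1L, ] - p[na, ]
    bv <- p[na, ] - p[n, ]
    if (sqrt(sum(hv^2)) < 1e-9 || sqrt(sum(bv^2)) < 1e-9) return(NA_real_)
    ang <- atan2(bv[1L] * hv[2L] - bv[2L] * hv[1L], sum(bv * hv)) * 180 / pi
    if (ang <= -180) ang + 360 else ang
  }, numeric(1))
  if (smoothWindow <= 1L) return(raw)
  half <- floor(smoothWindow / 2)
  n <- length(raw)
  vapply(seq_len(n), function(t) {
    idx <- max(1L, t - half):min(n, t + half)
    mean(raw[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Resolve the dorsoventral sign of head angles
#'
#' Animals are mounted on their left or right side; the mounting side is
#' inferred from the sign of the cross product of the loop-to-nrD centroid
#' offset with the local body axis, by majority over frames where both
#' masks are present. Angle signs are flipped if needed so that positive
#' means dorsal. If the evidence is indeterminate the angles are returned
#' side-relative and flagged.
#'
#' @param angles per-frame signed head angles (degrees).
#' @param loopMasks,nrDMasks per-frame mask lists of the loop and nrD
#'   compartments.
#' @param bodyAxes n x 2 matrix of per-frame body-axis direction vectors
#'   (anterior-pointing, e.g. head minus mid-body from the whole-body
#'   skeleton).
#' @return list with \code{angles} (positive = dorsal), \code{side}
#'   ("left"/"right"/NA) and \code{flipped}.
#' @export
resolveDorsoventralSign <- function(angles, loopMasks, nrDMasks, bodyAxes) {
  com <- function(m) {
    p <- .pix(m)
    if (!any(p)) return(c(NA_real_, NA_real_))
    w <- which(p, arr.ind = TRUE)
    c(mean(w[, 1L]), mean(w[, 2L]))
  }
  votes <- vapply(seq_along(loopMasks), function(t) {
    lc <- com(loopMasks[[t]]); nc <- com(nrDMasks[[t]])
    if (anyNA(lc) || anyNA(nc)) return(0)
    v <- lc - nc
    ax <- bodyAxes[t, ]
    sign(v[1L] * ax[2L] - v[2L] * ax[1L])
  }, numeric(1))
  tot <- sum(votes)
  if (tot == 0) {
    warning("mounting side indeterminate; angles left side-relative")
    return(list(angles = angles, side = NA_character_, flipped = FALSE))
  }
  # convention: loop to the right of the anterior body axis = right-mounted;
  # right-mounted recordings need no flip for positive = dorsal
  side <- if (tot > 0) "right" else "left"
  flipped <- side == "left"
  list(angles = if (flipped) -angles else angles, side = side,
       flipped = flipped)
}

#' Convert relative ellipse head estimates to degrees
#'
#' Maps values in [-1, 1] linearly onto [-90, 90] degrees; out-of-range
#' inputs are clamped (and logged).
#'
#' @param values numeric vector in [-1, 1] (small tolerance).
#' @return values * 90, after clamping.
#' @export
ellipseToDegrees <- function(values) {
  out <- pmin(pmax(values, -1), 1)
  nClamp <- sum(out != values, na.rm = TRUE)
  if (nClamp > 0)
    message("ellipseToDegrees: clamped ", nClamp, " out-of-range value(s)")
  90 * out
}

#' Write compartment traces and head angles as CSV
#'
#' Columns: frame, per-compartment raw/corrected/normalized brightness,
#' background and head angle. Optional stimulus epochs (list of
#' \code{[start_s, end_s, label]}) are merged in as a per-frame label.
#'
#' @param traces a \linkS4class{CompartmentTraces}.
#' @param path output CSV path.
#' @param headAngles optional per-frame signed head angles.
#' @param epochs optional stimulus epoch list; each element
#'   \code{list(start_s, end_s, label)}.
#' @param fps frames per second (needed when epochs are given).
#' @export
writeTraceCSV <- function(traces, path, headAngles = NULL, epochs = NULL,
                          fps = 10) {
  raw <- rawBrightness(traces)
  corr <- correctedBrightness(traces)
  df <- data.frame(frame = seq_len(nrow(raw)) - 1L)
  for (cp in traces@compartments) {
    df[[paste0(cp, "_raw")]] <- raw[, cp]
    df[[paste0(cp, "_corrected")]] <- corr[, cp]
    df[[paste0(cp, "_normalized")]] <- suppressWarnings(normalizeTrace(corr[, cp]))
  }
  df$background <- backgroundTrace(traces)
  if (!is.null(headAngles)) df$head_angle_deg <- headAngles
  if (!is.null(epochs)) {
    tsec <- df$frame / fps
    lab <- rep(NA_character_, nrow(df))
    for (ep in epochs)
      lab[tsec >= ep[[1L]] & tsec < ep[[2L]]] <- as.character(ep[[3L]])
    df$stimulus <- lab
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
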