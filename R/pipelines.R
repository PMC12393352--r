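# Pipeline drivers binding the stages per modality, plus serializable
# configuration. The Rscript front-end in inst/scripts/analyze.R is a thin
# wrapper over these functions.

#' Build a pipeline configuration
#'
#' Every tunable of every stage, with its documented default. Values can be
#' overridden by passing nested lists, e.g.
#' \code{pipelineConfig("swim", posture = list(curvature_sigma = 8))}.
#'
#' @param modality one of "static", "swim", "crawl", "calcium".
#' @param fps frames per second of the recording.
#' @param seed integer seed for every stochastic step.
#' @param ... named nested lists overriding stage defaults.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(modality = c("static", "swim", "crawl", "calcium"),
                           fps = 10, seed = 1L, ...) {
  modality <- match.arg(modality)
  cfg <- list(
    modality = modality,
    fps = fps,
    seed = as.integer(seed),
    masks = list(
      min_area = 50,              # small-particle floor (px)
      connectivity = 8,           # component connectivity (4 or 8)
      max_gap = 3,                # longest interpolatable mask dropout
      qc_max_area = NA,           # NA = 5x median stream area
      classifier_min_elongation = 4,
      classifier_solidity_min = 0.02,
      classifier_solidity_max = 0.7
    ),
    skeleton = list(
      n_points = 100              # resampled centerline resolution
    ),
    posture = list(
      curvature_window = 50,      # Gaussian window (points)
      curvature_sigma = 10,       # Gaussian sigma (points)
      welch_window = 30,          # temporal PSD window (frames)
      welch_overlap = 25,         # temporal PSD overlap (frames)
      peak_prominence = 0.25,     # wavelength peak floor (fraction of max)
      thresholds = shapeThresholds()
    ),
    tracking = list(
      head_window = 5,            # head-assignment sliding window (frames)
      jump_history = 5,           # jump-repair trailing history (frames)
      jump_factor = 3,            # jump threshold multiple
      head_fraction = 0.15,       # head-region extent for bend angle
      sg_window = 11,             # Savitzky-Golay window (frames, odd)
      sg_polyorder = 3,
      stationary_threshold = 0.5, # px/frame
      min_run = 3                 # shortest credible motion run (frames)
    ),
    fluorescence = list(
      crop_size = 110,            # fixed crop window edge (px)
      n_background = 100,         # background sample count
      min_background_distance = 40, # px from any structure
      background_seed = 7,
      background_mode = "frame",  # or "recording" (mean over frames)
      anterior_fraction = 0.3,    # head-vector extent for head angle
      smooth_window = 3,          # temporal head-angle smoothing (frames)
      normalization = "minmax"    # or "dff"
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Save / load a pipeline configuration (YAML)
#'
#' \code{loadPipelineConfig(savePipelineConfig(cfg, path))} reproduces the
#' configuration exactly.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path YAML file path.
#' @return \code{savePipelineConfig}: the path, invisibly;
#'   \code{loadPipelineConfig}: the configuration.
#' @export
savePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname savePipelineConfig
#' @export
loadPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipelineConfig,
                 c(list(modality = raw$modality, fps = raw$fps, seed = raw$seed),
                   raw[setdiff(names(raw), c("modality", "fps", "seed"))]))
  cfg
}

# mask -> cleaned -> resampled skeleton with widths
.maskToSkeleton <- function(mask, cfg, frameIdx = 0L) {
  p <- .pix(mask)
  p <- cleanSmallParticles(p, minArea = cfg$masks$min_area,
                           connectivity = cfg$masks$connectivity)
  maskToSkeleton(p, nPoints = cfg$skeleton$n_points, frameIndex = frameIdx)
}

#' Static-image morphometry pipeline
#'
#' Edge exclusion, classification, overlap resolution, then skeleton and
#' morphometry per retained worm. One output row per worm; an empty
#' candidate set yields an empty table with a warning (not an error).
#'
#' @param masks list of \linkS4class{LabeledMask} candidates for one image.
#' @param frameShape (rows, cols) of the image.
#' @param config a \code{\link{pipelineConfig}}.
#' @param classifier pluggable classifier for
#'   \code{\link{classifyCandidates}}; default shape heuristic with the
#'   configured settings.
#' @param outDir optional output directory for \code{morphometry.csv}.
#' @return data.frame: worm, area_px, perimeter_px, length_px,
#'   mean_width_px, max_width_px.
#' @export
runStatic <- function(masks, frameShape, config = pipelineConfig("static"),
                      classifier = NULL, outDir = NULL) {
  if (is.null(classifier))
    classifier <- shapeHeuristicClassifier(
      minElongation = config$masks$classifier_min_elongation,
      solidityBand = c(config$masks$classifier_solidity_min,
                       config$masks$classifier_solidity_max))
  emptyOut <- data.frame(worm = integer(0), area_px = numeric(0),
                         perimeter_px = numeric(0), length_px = numeric(0),
                         mean_width_px = numeric(0), max_width_px = numeric(0))
  res <- emptyOut
  if (length(masks)) {
    masks <- excludeEdgeMasks(masks, frameShape)
    masks <- classifyCandidates(masks, classifier = classifier)
    masks <- masks[vapply(masks, maskLabel, character(1)) == "worm"]
    masks <- resolveOverlappingMasks(masks)
    if (length(masks)) {
      rows <- lapply(seq_along(masks), function(i) {
        sk <- .maskToSkeleton(masks[[i]], config)
        mo <- measureMorphometry(cleanSmallParticles(
          .pix(masks[[i]]), config$masks$min_area,
          config$masks$connectivity), sk)
        data.frame(worm = i, area_px = mo$area_px,
                   perimeter_px = mo$perimeter_px, length_px = mo$length_px,
                   mean_width_px = mo$mean_width_px,
                   max_width_px = mo$max_width_px)
      })
      res <- do.call(rbind, rows)
    }
  }
  if (!nrow(res)) warning("runStatic: no worm masks retained")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res, file.path(outDir, "morphometry.csv"), row.names = FALSE)
  }
  res
}

#' Swimming posture pipeline
#'
#' Per frame: mask cleanup, skeletonization with self-touch correction,
#' spline resampling, curvature/amplitude, then (second pass, once
#' video-level length statistics exist) shape class, wavelength and wave
#' number, and finally the per-frame dominant temporal frequency of the
#' mean absolute curvature series. No frame is dropped: frames that fail a
#' stage carry a flag and NA metrics.
#'
#' @param masksByFrame list of per-frame single-worm masks.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory (\code{posture.csv}).
#' @return list: \code{frames} (per-frame data.frame), \code{skeletons},
#'   \code{curvatureProfiles} (frames x points matrix),
#'   \code{amplitudeProfiles}.
#' @export
runSwim <- function(masksByFrame, config = pipelineConfig("swim"),
                    outDir = NULL) {
  nF <- length(masksByFrame)
  skels <- vector("list", nF)
  flags <- character(nF)
  for (t in seq_len(nF)) {
    skels[[t]] <- tryCatch(
      .maskToSkeleton(masksByFrame[[t]], config, frameIdx = t - 1L),
      error = function(e) {
        flags[t] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(skels, is.null, logical(1))
  lens <- rep(NA_real_, nF)
  lens[ok] <- vapply(skels[ok], pixelLength, numeric(1))
  mu <- mean(lens, na.rm = TRUE); sdv <- sd(lens, na.rm = TRUE)
  if (is.na(sdv)) sdv <- 0
  np <- config$skeleton$n_points
  curvM <- matrix(NA_real_, nF, np)
  ampM <- matrix(NA_real_, nF, np)
  frames <- data.frame(frame = seq_len(nF) - 1L, flag = flags,
                       length_px = lens, shape_class = NA_character_,
                       max_amplitude = NA_real_, mean_abs_curvature = NA_real_,
                       wavelength_px = NA_real_, wave_number = NA_real_,
                       dominant_freq_hz = NA_real_)
  for (t in which(ok)) {
    pf <- tryCatch(
      postureFrame(skels[[t]], mu, sdv,
                   thresholds = config$posture$thresholds,
                   window = config$posture$curvature_window,
                   sigma = config$posture$curvature_sigma),
      error = function(e) {
        frames$flag[t] <<- conditionMessage(e)
        NULL
      })
    if (is.null(pf)) next
    curvM[t, ] <- pf$curvature
    ampM[t, ] <- pf$amplitude
    frames$shape_class[t] <- pf$shape_class
    frames$max_amplitude[t] <- pf$max_amplitude
    frames$mean_abs_curvature[t] <- pf$mean_abs_curvature
    frames$wavelength_px[t] <- pf$wavelength_px
    frames$wave_number[t] <- pf$wave_number
  }
  series <- frames$mean_abs_curvature
  if (anyNA(series)) {
    filled <- approx(which(!is.na(series)), series[!is.na(series)],
                     xout = seq_len(nF), rule = 2)$y
    series <- filled
  }
  if (sum(!is.na(series)) >= 4 && sd(series) > 0)
    frames$dominant_freq_hz <- as.numeric(
      temporalDominantFrequency(series, config$fps,
                                config$posture$welch_window,
                                config$posture$welch_overlap))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(frames, file.path(outDir, "posture.csv"), row.names = FALSE)
  }
  list(frames = frames, skeletons = skels, curvatureProfiles = curvM,
       amplitudeProfiles = ampM)
}

#' Crawling tracking pipeline
#'
#' Skeletons per frame, head-tail assignment with jump repair, head-bend
#' angles, smoothed centroid path, motion classification with contextual
#' correction, bouts and path summary.
#'
#' @param masksByFrame list of per-frame single-worm masks.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory (\code{track.csv},
#'   \code{bouts.csv}, \code{summary.json}).
#' @return list: \code{track} (per-frame data.frame), \code{bouts},
#'   \code{summary}, \code{skeletons} (oriented).
#' @export
runCrawl <- function(masksByFrame, config = pipelineConfig("crawl"),
                     outDir = NULL) {
  nF <- length(masksByFrame)
  skels <- vector("list", nF)
  flags <- character(nF)
  cents <- matrix(NA_real_, nF, 2L)
  for (t in seq_len(nF)) {
    p <- .pix(masksByFrame[[t]])
    w <- which(p, arr.ind = TRUE)
    if (nrow(w)) cents[t, ] <- c(mean(w[, 1L]), mean(w[, 2L]))
    skels[[t]] <- tryCatch(
      .maskToSkeleton(masksByFrame[[t]], config, frameIdx = t - 1L),
      error = function(e) {
        flags[t] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(skels, is.null, logical(1))
  if (!all(ok)) {
    # keep frame count intact: reuse the nearest good skeleton, flagged
    goodIdx <- which(ok)
    for (t in which(!ok)) {
      j <- goodIdx[which.min(abs(goodIdx - t))]
      skels[[t]] <- skels[[j]]
      flags[t] <- paste0(flags[t], "|skeleton_borrowed_from_", j - 1L)
    }
  }
  skels <- assignHeadTail(skels, window = config$tracking$head_window)
  skels <- correctHeadJumps(skels, history = config$tracking$jump_history,
                            factor = config$tracking$jump_factor)
  heads <- t(vapply(skels, function(s) skelPoints(s)[1L, ], numeric(2)))
  tails <- t(vapply(skels, function(s) {
    p <- skelPoints(s); p[nrow(p), ]
  }, numeric(2)))
  bendDeg <- vapply(skels, headBendAngle,
                    numeric(1), headFraction = config$tracking$head_fraction)
  if (anyNA(cents[, 1L])) {
    for (j in 1:2)
      cents[, j] <- approx(which(!is.na(cents[, j])),
                           cents[!is.na(cents[, j]), j],
                           xout = seq_len(nF), rule = 2)$y
  }
  sm <- smoothCentroid(cents, window = config$tracking$sg_window,
                       polyorder = config$tracking$sg_polyorder)
  labels <- classifyMotion(sm, heads,
                           stationaryThreshold = config$tracking$stationary_threshold)
  labels <- correctMotionLabels(labels, minRun = config$tracking$min_run)
  speed <- c(0, sqrt(rowSums((sm[-1L, , drop = FALSE] -
                              sm[-nF, , drop = FALSE])^2)))
  speed[1L] <- speed[2L]
  bouts <- extractBouts(labels, sm)
  summ <- summarizePath(labels, sm, bouts)
  track <- data.frame(frame = seq_len(nF) - 1L, flag = flags,
                      centroid_row = sm[, 1L], centroid_col = sm[, 2L],
                      head_row = heads[, 1L], head_col = heads[, 2L],
                      tail_row = tails[, 1L], tail_col = tails[, 2L],
                      speed = speed, motion = labels,
                      head_angle_deg = bendDeg)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(track, file.path(outDir, "track.csv"), row.names = FALSE)
    write.csv(bouts, file.path(outDir, "bouts.csv"), row.names = FALSE)
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(track = track, bouts = bouts, summary = summ, skeletons = skels)
}

#' Orient skeletons so the head faces a reference point
#'
#' In the microfluidic modality the head is the end nearest the stimulus
#' stream / crop center (device geometry), not a tracked identity.
#'
#' @param skeletons list of \linkS4class{WormSkeleton}.
#' @param point (row, col) reference the head faces.
#' @return skeleton list ordered head first.
#' @export
orientSkeletonsToward <- function(skeletons, point) {
  lapply(skeletons, function(sk) {
    p <- skelPoints(sk)
    dHead <- sum((p[1L, ] - point)^2)
    dTail <- sum((p[nrow(p), ] - point)^2)
    if (dTail < dHead) {
      sk@points <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      if (length(sk@widths)) sk@widths <- rev(sk@widths)
    }
    sk
  })
}

#' Calcium-imaging pipeline
#'
#' Compartment-mask QC and gap interpolation, fixed crop window,
#' per-frame background estimation, background-corrected brightness, and
#' (when whole-body masks are provided) signed head angles with
#' dorsoventral resolution.
#'
#' @param frames H x W x T grayscale array.
#' @param compartmentMasks named list (nrD/nrV/loop) of per-frame mask
#'   lists.
#' @param bodyMasks optional per-frame whole-body masks for head angles.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory (\code{traces.csv},
#'   \code{qc.csv}).
#' @param epochs optional stimulus epochs for the trace CSV.
#' @return list: \code{traces} (\linkS4class{CompartmentTraces}),
#'   \code{normalized}, \code{headAngles}, \code{side}, \code{qc},
#'   \code{crop}.
#' @export
runCalcium <- function(frames, compartmentMasks, bodyMasks = NULL,
                       config = pipelineConfig("calcium"), outDir = NULL,
                       epochs = NULL) {
  fl <- config$fluorescence
  nT <- dim(frames)[3L]
  comps <- names(compartmentMasks)
  qcs <- lapply(comps, function(cp) {
    sib <- NULL
    others <- setdiff(comps, cp)
    if (length(others))
      sib <- lapply(seq_len(nT), function(t)
        Reduce(`|`, lapply(others, function(o) .pix(compartmentMasks[[o]][[t]]))))
    cbind(compartment = cp,
          qcMaskStream(compartmentMasks[[cp]],
                       maxArea = if (is.na(config$masks$qc_max_area)) NULL
                                 else config$masks$qc_max_area,
                       siblingMasks = sib))
  })
  qc <- do.call(rbind, qcs)
  compartmentMasks <- lapply(compartmentMasks, function(ms)
    interpolateMissingMasks(ms, maxGap = config$masks$max_gap,
                            connectivity = config$masks$connectivity))
  regionMasks <- lapply(seq_len(nT), function(t)
    Reduce(`|`, lapply(comps, function(cp) .pix(compartmentMasks[[cp]][[t]]))))
  crop <- computeCropWindow(regionMasks, size = min(fl$crop_size, dim(frames)[1L]),
                            frameDim = dim(frames)[1:2])
  traces <- extractBrightness(frames, compartmentMasks,
                              backgroundMode = fl$background_mode,
                              nRegions = fl$n_background,
                              minDistance = fl$min_background_distance,
                              seed = fl$background_seed)
  corr <- correctedBrightness(traces)
  normd <- apply(corr, 2L, function(x)
    suppressWarnings(normalizeTrace(x, method = fl$normalization)))
  headAngles <- NULL; side <- NA_character_
  if (!is.null(bodyMasks)) {
    bodySkels <- lapply(seq_along(bodyMasks), function(t)
      .maskToSkeleton(bodyMasks[[t]], config, frameIdx = t - 1L))
    bodySkels <- orientSkeletonsToward(bodySkels, crop$center)
    headAngles <- headAngleFromBody(bodySkels,
                                    anteriorFraction = fl$anterior_fraction,
                                    smoothWindow = fl$smooth_window)
    axes <- t(vapply(bodySkels, function(sk) {
      p <- skelPoints(sk)
      v <- p[1L, ] - p[round(nrow(p) / 2), ]
      v / max(sqrt(sum(v^2)), 1e-12)
    }, numeric(2)))
    dv <- resolveDorsoventralSign(headAngles, compartmentMasks$loop,
                                  compartmentMasks$nrD, axes)
    headAngles <- dv$angles
    side <- dv$side
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTraceCSV(traces, file.path(outDir, "traces.csv"),
                  headAngles = headAngles, epochs = epochs, fps = config$fps)
    write.csv(qc, file.path(outDir, "qc.csv"), row.names = FALSE)
  }
  list(traces = traces, normalized = normd, headAngles = headAngles,
       side = side, qc = qc, crop = crop)
}
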