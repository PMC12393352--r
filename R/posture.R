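# Swimming posture metrics: curvature, amplitude, shape classes, wavelength,
# wave number, spatial and temporal undulation frequency.

#' Gaussian-weighted signed curvature along a skeleton
#'
#' Tangent angles are taken from consecutive-point differences, their
#' (wrapped) increments smoothed with a normalized Gaussian kernel and
#' divided by the local arc-length spacing, giving signed curvature in
#' 1/px. The sign convention is consistent along the body: positive means
#' a bend towards the left of travel along increasing point order
#' (image coordinates, rows growing downward).
#'
#' @param skeleton a \linkS4class{WormSkeleton}.
#' @param window Gaussian kernel window size in points (default 50).
#' @param sigma Gaussian kernel standard deviation in points (default 10).
#' @return numeric vector of signed curvature, one value per skeleton point.
#' @export
gaussianCurvatureProfile <- function(skeleton, window = 50, sigma = 10) {
  pts <- skelPoints(skeleton)
  n <- nrow(pts)
  if (n < max(4L, ceiling(window / 2)))
    stop("skeleton too short for the requested curvature window")
  seg <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  slen <- sqrt(rowSums(seg^2))
  if (any(slen <= 0)) stop("degenerate skeleton: repeated points")
  theta <- atan2(seg[, 1L], seg[, 2L])
  dtheta <- diff(theta)
  dtheta <- atan2(sin(dtheta), cos(dtheta))      # wrap to (-pi, pi]
  half <- floor(window / 2)
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- length(dtheta)
  padIdx <- function(i) {                        # reflect at boundaries
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > m, 2L * m - i, pmin(pmax(i, 1L), m))
  }
  sm <- vapply(seq_len(m), function(i) {
    sum(k * dtheta[padIdx(i + x)])
  }, numeric(1))
  ds <- (slen[-length(slen)] + slen[-1L]) / 2
  core <- sm / ds
  c(core[1L], core, core[length(core)])
}

#' Bending amplitude profile
#'
#' Per-point unsigned perpendicular distance from the skeleton to the
#' straight head-tail chord (the infinite line through the two skeleton
#' endpoints). For closed postures whose endpoints (nearly) coincide, the
#' line through the two most distant skeleton points is used instead and
#' the result carries \code{attr(, "fallback") = TRUE}.
#'
#' @param skeleton a \linkS4class{WormSkeleton}.
#' @return numeric vector of non-negative distances (px), one per point.
#' @export
amplitudeProfile <- function(skeleton) {
  pts <- skelPoints(skeleton)
  n <- nrow(pts)
  a <- pts[1L, ]; b <- pts[n, ]
  L <- pixelLength(skeleton)
  fallback <- FALSE
  if (sqrt(sum((b - a)^2)) < max(1e-8, 0.02 * L)) {
    fallback <- TRUE
    d2 <- as.matrix(dist(pts))
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
    a <- pts[ij[1L], ]; b <- pts[ij[2L], ]
  }
  u <- (b - a) / sqrt(sum((b - a)^2))
  rel <- sweep(pts, 2L, a)
  amp <- abs(rel[, 1L] * u[2L] - rel[, 2L] * u[1L])
  attr(amp, "fallback") <- fallback
  amp
}

#' Default shape-classification thresholds
#'
#' The decision table works on two dimensionless posture features:
#' \code{bend} = mean absolute curvature x body length (total absolute
#' turning along the body, radians) and \code{ampn} = maximum amplitude /
#' body length. Published work gives verbal class definitions only, so the
#' numeric boundaries here were calibrated once on synthetic exemplars of
#' each class and are fully user-editable.
#'
#' @return named list of threshold values.
#' @export
shapeThresholds <- function() {
  list(
    bend_six = 5.0,       # very high curvature: 6-shapes
    bend_o = 4.2,         # high curvature: O-shapes
    amp_high = 0.34,      # high vs moderate normalized amplitude
    bend_moderate = 1.1,  # lower bound of C/U bends
    amp_low = 0.13,       # s-family amplitude ceiling
    bend_s = 2.2,         # s_shape vs mild_s
    bend_straight = 0.5,  # below this (and no undulation): straight
    sign_changes_s = 2,   # curvature sign changes marking an S body wave
    sign_deadband = 0.1   # |curvature| fraction of max treated as zero
  )
}

.signChanges <- function(curv, deadband = 0.1) {
  thr <- deadband * max(abs(curv), 1e-12)
  s <- sign(curv)
  s[abs(curv) < thr] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Classify the per-frame body shape
#'
#' Classification runs on curvature and amplitude. A worm whose length has
#' dropped more than one standard deviation below the video mean is turned
#' on the z-plane ("turned", checked first); otherwise a decision table on
#' total bend (mean |curvature| x length) and length-normalized maximum
#' amplitude assigns one of straight, mild_s, s_shape, c_shape, u_shape,
#' six_shape, o_shape.
#'
#' @param curvature signed curvature profile (1/px).
#' @param amplitude amplitude profile (px).
#' @param lengthPx skeleton length of this frame (px).
#' @param videoLengthMean,videoLengthSd video-level skeleton length
#'   statistics (two-pass processing).
#' @param thresholds threshold list, see \code{\link{shapeThresholds}}.
#' @return single character shape class.
#' @export
classifyShape <- function(curvature, amplitude, lengthPx,
                          videoLengthMean, videoLengthSd,
                          thresholds = shapeThresholds()) {
  if (missing(videoLengthMean) || missing(videoLengthSd) ||
      is.na(videoLengthMean) || is.na(videoLengthSd))
    stop("video-level length statistics missing: two-pass processing ",
         "required (compute lengths over all frames first, then classify)")
  th <- thresholds
  if (lengthPx < videoLengthMean - videoLengthSd) return("turned")
  bend <- mean(abs(curvature)) * lengthPx
  ampn <- max(amplitude) / lengthPx
  sc <- .signChanges(curvature, th$sign_deadband)
  if (sc >= th$sign_changes_s && ampn <= th$amp_low && bend >= th$bend_straight)
    return(if (bend >= th$bend_s) "s_shape" else "mild_s")
  if (bend >= th$bend_six && ampn < th$amp_high) return("six_shape")
  if (bend >= th$bend_o && ampn >= th$amp_high) return("o_shape")
  if (bend >= th$bend_moderate)
    return(if (ampn >= th$amp_high) "u_shape" else "c_shape")
  "straight"
}

#' Undulation wavelength of one frame
#'
#' S-shaped worms: twice the mean arc-length spacing between successive
#' curvature extrema of alternating sign. C-shapes: fixed at twice the worm
#' length. Straight or turned worms have no wavelength. U-, O- and 6-shapes
#' follow the C rule (single deep bend) and are flagged.
#'
#' @param shapeClass class from \code{\link{classifyShape}}.
#' @param curvature signed curvature profile.
#' @param lengthPx skeleton length (px).
#' @param prominence peak height floor as a fraction of max |curvature|
#'   (default 0.25).
#' @return wavelength in px, or NA for straight/turned frames. Carries
#'   \code{attr(, "flag")} when a fallback rule fired.
#' @export
wavelengthOfFrame <- function(shapeClass, curvature, lengthPx,
                              prominence = 0.25) {
  flagAttr <- function(x, f) { attr(x, "flag") <- f; x }
  if (shapeClass %in% c("straight", "turned")) return(NA_real_)
  if (shapeClass %in% c("c_shape"))
    return(2 * lengthPx)
  if (shapeClass %in% c("u_shape", "o_shape", "six_shape"))
    return(flagAttr(2 * lengthPx, "c_rule_applied"))
  # s_shape / mild_s: alternating curvature extrema
  n <- length(curvature)
  s <- seq(0, lengthPx, length.out = n)
  thr <- prominence * max(abs(curvature))
  pk <- pracma::findpeaks(curvature, minpeakheight = thr)
  tr <- pracma::findpeaks(-curvature, minpeakheight = thr)
  ext <- rbind(
    if (!is.null(pk)) cbind(pos = pk[, 2L], sgn = 1) else NULL,
    if (!is.null(tr)) cbind(pos = tr[, 2L], sgn = -1) else NULL
  )
  if (is.null(ext) || nrow(ext) < 2L)
    return(flagAttr(2 * lengthPx, "too_few_peaks_c_rule"))
  ext <- ext[order(ext[, "pos"]), , drop = FALSE]
  keep <- c(TRUE, diff(ext[, "sgn"]) != 0)
  ext <- ext[keep, , drop = FALSE]
  if (nrow(ext) < 2L)
    return(flagAttr(2 * lengthPx, "too_few_peaks_c_rule"))
  2 * mean(diff(s[ext[, "pos"]]))
}

#' Dominant spatial frequency of a curvature profile
#'
#' Discrete-Fourier magnitude spectrum of the mean-subtracted curvature
#' profile; returns the argmax frequency in cycles per body length (zero
#' bin excluded). A constant profile has no undulation and returns NA.
#'
#' @param curvature signed curvature profile sampled along the body.
#' @return dominant frequency (cycles/body length) or NA.
#' @export
spatialFrequency <- function(curvature) {
  x <- curvature - mean(curvature)
  n <- length(x)
  if (max(abs(x)) < 1e-9 * max(abs(curvature), 1e-12) || max(abs(x)) == 0)
    return(NA_real_)
  sp <- Mod(fft(x))[2:(floor(n / 2) + 1L)]
  as.numeric(which.max(sp))
}

#' Per-frame dominant temporal frequency of the curvature time series
#'
#' The z-scored series is analyzed in sliding windows (window size and
#' overlap in frames); each window position yields a Hann-windowed,
#' mean-removed power spectral density, whose highest-power spectral peak
#' (or, if no peak is found, the highest-power frequency) is the window's
#' dominant frequency, assigned to the window center. Dominant frequencies
#' are then linearly interpolated across the entire series so every frame
#' has a value, extended constantly at the ends.
#'
#' @param series per-frame scalar curvature summary (e.g. mean absolute
#'   curvature per frame).
#' @param fps frames per second of the recording.
#' @param window window size in frames (default 30).
#' @param overlap window overlap in frames (default 25).
#' @return numeric vector, one dominant frequency (Hz) per frame, with the
#'   per-window values in \code{attr(, "windows")}.
#' @export
temporalDominantFrequency <- function(series, fps, window = 30, overlap = 25) {
  stopifnot(overlap >= 0, overlap < window)
  n <- length(series)
  sdv <- sd(series)
  x <- if (sdv > 0) (series - mean(series)) / sdv else series - mean(series)
  domOfSegment <- function(seg) {
    m <- length(seg)
    seg <- seg - mean(seg)
    w <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
    P <- Mod(fft(seg * w))^2
    nf <- floor(m / 2)
    P <- P[2:(nf + 1L)]
    freqs <- seq_len(nf) * fps / m
    pk <- pracma::findpeaks(P)
    sel <- if (!is.null(pk) && nrow(pk)) pk[which.max(pk[, 1L]), 2L]
           else which.max(P)
    freqs[sel]
  }
  if (n < window) {
    f <- domOfSegment(x)
    out <- rep(f, n)
    attr(out, "windows") <- data.frame(center = (n + 1) / 2, freq = f)
    attr(out, "flag") <- "series_shorter_than_window"
    return(out)
  }
  starts <- seq(1L, n - window + 1L, by = window - overlap)
  freqs <- vapply(starts, function(s0) domOfSegment(x[s0:(s0 + window - 1L)]),
                  numeric(1))
  centers <- starts + (window - 1) / 2
  out <- if (length(starts) > 1L)
    approx(centers, freqs, xout = seq_len(n), rule = 2)$y
  else rep(freqs, n)
  attr(out, "windows") <- data.frame(center = centers, freq = freqs)
  out
}

#' Full posture metrics for one frame
#'
#' Convenience wrapper assembling curvature, amplitude, shape class,
#' wavelength and wave number for one skeleton.
#'
#' @param skeleton a \linkS4class{WormSkeleton}.
#' @param videoLengthMean,videoLengthSd video-level length statistics.
#' @param thresholds shape thresholds.
#' @param window,sigma curvature smoothing parameters.
#' @return list with fields frame_index, curvature, amplitude,
#'   max_amplitude, mean_abs_curvature, shape_class, wavelength_px,
#'   wave_number, length_px.
#' @export
postureFrame <- function(skeleton, videoLengthMean, videoLengthSd,
                         thresholds = shapeThresholds(),
                         window = 50, sigma = 10) {
  curv <- gaussianCurvatureProfile(skeleton, window, sigma)
  amp <- amplitudeProfile(skeleton)
  L <- pixelLength(skeleton)
  cls <- classifyShape(curv, amp, L, videoLengthMean, videoLengthSd, thresholds)
  wl <- wavelengthOfFrame(cls, curv, L)
  list(
    frame_index = frameIndex(skeleton),
    curvature = curv,
    amplitude = as.numeric(amp),
    max_amplitude = max(amp),
    mean_abs_curvature = mean(abs(curv)),
    shape_class = cls,
    wavelength_px = as.numeric(wl),
    wave_number = if (is.na(wl)) NA_real_ else L / as.numeric(wl),
    length_px = L
  )
}
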