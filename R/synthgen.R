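# Synthetic worms, recordings and fluorescence videos with exact analytic
# ground truth. Every downstream stage is validated against these.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic worm
#'
#' The centerline is a member of a parametric family; the body is the
#' union of disks of the local half-width centered along it, so centerline,
#' width profile and curvature ground truth are all analytic.
#'
#' @param shape one of \code{"straight"}, \code{"arc"}, \code{"sine"},
#'   \code{"c_shape"}, \code{"u_shape"}, \code{"o_gap"}, \code{"six_shape"}.
#' @param lengthPx body length along the centerline (px).
#' @param maxWidth maximum body width (diameter, px).
#' @param taper taper exponent of the width profile
#'   \code{w(s) = maxWidth * (4 s (1-s))^taper} with \code{s} the
#'   normalized arc position; 0 gives constant width.
#' @param radius arc radius (shape "arc" only; other arc-based shapes fix
#'   their own radius from \code{lengthPx}).
#' @param amplitude,periods sine shape: displacement amplitude (px) and
#'   number of full waves along the body.
#' @param gapAngleDeg opening of the "o_gap" ring in degrees.
#' @param center (row, col) placement of the worm's bounding-box center;
#'   default the frame center.
#' @param rotationDeg rigid rotation of the whole worm.
#' @param frameDim (rows, cols) canvas size.
#' @param seed integer seed (noise realizations only; geometry is
#'   deterministic).
#' @return list of class \code{"wormSpec"}.
#' @export
wormSpec <- function(shape = "sine", lengthPx = 300, maxWidth = 12,
                     taper = 0.35, radius = NULL, amplitude = 30, periods = 1,
                     gapAngleDeg = 60, center = NULL, rotationDeg = 0,
                     frameDim = c(512L, 612L), seed = 1L) {
  shape <- match.arg(shape, c("straight", "arc", "sine", "c_shape",
                              "u_shape", "o_gap", "six_shape"))
  structure(list(
    shape = shape, lengthPx = lengthPx, maxWidth = maxWidth, taper = taper,
    radius = radius, amplitude = amplitude, periods = periods,
    gapAngleDeg = gapAngleDeg, center = center, rotationDeg = rotationDeg,
    frameDim = as.integer(frameDim), seed = as.integer(seed)
  ), class = "wormSpec")
}

.widthAt <- function(sNorm, maxWidth, taper) {
  if (taper == 0) rep(maxWidth, length(sNorm))
  else maxWidth * (4 * sNorm * (1 - sNorm))^taper
}

# dense centerline in body coordinates. Index 1 is the s = 0 end (the head
# for sequence rendering). Returns list(points, curvature, s).
.centerlineDense <- function(spec, ds = 0.25) {
  L <- spec$lengthPx
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  if (spec$shape == "sine") {
    A <- spec$amplitude; p <- spec$periods
    arclen <- function(X) {
      u <- seq(0, 1, length.out = 4001L)
      dx <- X
      dy <- 2 * pi * p * A * cos(2 * pi * p * u)
      sum(sqrt(dx^2 + dy^2)) / length(u)
    }
    X <- uniroot(function(X) arclen(X) - L, c(L / 20, L))$root
    u <- seq(0, 1, length.out = 8001L)
    pts <- cbind(row = A * sin(2 * pi * p * u), col = X * u)
    dd <- sqrt(rowSums((pts[-1L, ] - pts[-nrow(pts), ])^2))
    cu <- c(0, cumsum(dd))
    # analytic curvature vs x, then mapped to arc position
    yp <- 2 * pi * p * A / X * cos(2 * pi * p * u)
    ypp <- -(2 * pi * p / X)^2 * A * sin(2 * pi * p * u)
    kap <- ypp / (1 + yp^2)^1.5
    rowI <- approx(cu, pts[, 1L], xout = pmin(s, max(cu)))$y
    colI <- approx(cu, pts[, 2L], xout = pmin(s, max(cu)))$y
    kapI <- approx(cu, kap, xout = pmin(s, max(cu)))$y
    out <- list(points = cbind(rowI, colI), curvature = kapI, s = s)
  } else {
    kapFun <- switch(spec$shape,
      straight = function(s) rep(0, length(s)),
      arc = {
        R <- if (is.null(spec$radius)) L / 2.0 else spec$radius
        function(s) rep(1 / R, length(s))
      },
      c_shape = {
        R <- L / 2.6           # 149 degree sweep: a wide C
        function(s) rep(1 / R, length(s))
      },
      u_shape = {
        R <- 0.5 * L / pi      # straight arm, 180 degree bend, straight arm
        function(s) ifelse(s >= 0.25 * L & s <= 0.75 * L, 1 / R, 0)
      },
      o_gap = {
        phi <- 2 * pi - spec$gapAngleDeg * pi / 180
        R <- L / phi
        function(s) rep(1 / R, length(s))
      },
      six_shape = {
        stem <- 0.3 * L        # straight stem, then a full closed loop
        R <- (L - stem) / (2 * pi)
        function(s) ifelse(s > stem, 1 / R, 0)
      })
    kap <- kapFun(s)
    # integrate heading: theta from the +col axis, positive kap bends
    # towards +row (image convention)
    dtheta <- c(0, (kap[-1L] + kap[-length(kap)]) / 2 * diff(s))
    theta <- cumsum(dtheta)
    dcol <- cos(theta); drow <- sin(theta)
    pts <- cbind(row = c(0, cumsum((drow[-1L] + drow[-length(drow)]) / 2 * diff(s))),
                 col = c(0, cumsum((dcol[-1L] + dcol[-length(dcol)]) / 2 * diff(s))))
    out <- list(points = pts, curvature = kap, s = s)
  }
  th <- spec$rotationDeg * pi / 180
  if (th != 0) {
    Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    out$points <- out$points %*% t(Rm)
  }
  out
}

.placeCenterline <- function(dense, spec) {
  fd <- spec$frameDim
  ctr <- if (is.null(spec$center)) (fd + 1) / 2 else spec$center
  bboxCtr <- c(mean(range(dense$points[, 1L])), mean(range(dense$points[, 2L])))
  dense$points <- sweep(dense$points, 2L, bboxCtr - ctr)
  dense
}

.paintDisks <- function(points, radii, frameDim) {
  H <- frameDim[1L]; W <- frameDim[2L]
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(points))) {
    r <- points[i, 1L]; c <- points[i, 2L]; rad <- radii[i]
    if (rad <= 0) next
    r0 <- floor(r - rad); r1 <- ceiling(r + rad)
    c0 <- floor(c - rad); c1 <- ceiling(c + rad)
    if (r1 < 1 || r0 > H || c1 < 1 || c0 > W)
      stop("worm leaves the frame; enlarge frameDim or recenter")
    rs <- max(1L, r0):min(H, r1)
    cs <- max(1L, c0):min(W, c1)
    d2 <- outer((rs - r)^2, (cs - c)^2, `+`)
    mask[rs, cs] <- mask[rs, cs] | (d2 <= rad^2)
  }
  mask
}

# resample a dense centerline to n equally spaced arc-length points
.resampleTruth <- function(dense, n = 100L) {
  pts <- dense$points
  dd <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cu <- c(0, cumsum(dd))
  ss <- seq(0, max(cu), length.out = n)
  cbind(approx(cu, pts[, 1L], xout = ss)$y,
        approx(cu, pts[, 2L], xout = ss)$y)
}

#' Render a synthetic worm mask with ground truth
#'
#' @param spec a \code{\link{wormSpec}}.
#' @param nTruthPoints number of ground-truth centerline points (default
#'   100, matching the skeleton resolution).
#' @return list with \code{mask} (logical matrix), \code{truth} (list:
#'   \code{points} n x 2, \code{widths}, \code{curvature}, \code{length},
#'   \code{selfTouching}) and \code{spec}.
#' @export
renderWorm <- function(spec, nTruthPoints = 100L) {
  minR <- {
    dense0 <- .centerlineDense(spec)
    kmax <- max(abs(dense0$curvature))
    if (kmax > 0) 1 / kmax else Inf
  }
  if (spec$maxWidth >= 2 * minR)
    stop("body width must be below twice the minimum curvature radius")
  dense <- .placeCenterline(dense0, spec)
  sNorm <- dense$s / spec$lengthPx
  radii <- .widthAt(sNorm, spec$maxWidth, spec$taper) / 2
  mask <- .paintDisks(dense$points, radii, spec$frameDim)
  # self-touch detection: non-adjacent centerline samples whose disks merge
  pts <- dense$points
  sub <- seq(1L, nrow(pts), by = 8L)
  selfTouch <- FALSE
  if (length(sub) > 3L) {
    d <- as.matrix(dist(pts[sub, ]))
    sepS <- abs(outer(dense$s[sub], dense$s[sub], `-`))
    rr <- outer(radii[sub], radii[sub], `+`)
    selfTouch <- any(d < rr & sepS > 4 * spec$maxWidth)
  }
  truthPts <- .resampleTruth(dense, nTruthPoints)
  ss <- seq(0, 1, length.out = nTruthPoints)
  truth <- list(
    points = truthPts,
    widths = .widthAt(ss, spec$maxWidth, spec$taper),
    curvature = approx(dense$s, dense$curvature,
                       xout = ss * spec$lengthPx)$y,
    length = spec$lengthPx,
    selfTouching = selfTouch
  )
  if (selfTouch)
    message("renderWorm: self-touching posture rendered (exercises skeleton correction)")
  list(mask = mask, truth = truth, spec = spec)
}

#' Specify a synthetic moving-worm sequence
#'
#' @param worm a \code{\link{wormSpec}} (the body shape; its s = 0 end is
#'   the head).
#' @param motionProgram data.frame with columns \code{state} (one of
#'   forward/backward/stationary), \code{duration} (frames), \code{speed}
#'   (px/frame, unsigned).
#' @param headOscAmpDeg,headOscFreqHz sinusoidal head swing amplitude
#'   (degrees) and frequency (Hz); the anterior quarter of the body rotates
#'   about its base.
#' @param fps frames per second.
#' @param saltPepperRate fraction of frame pixels flipped to speckle noise
#'   per frame (default 0).
#' @param seed integer seed.
#' @return list of class \code{"sequenceSpec"}.
#' @export
sequenceSpec <- function(worm = wormSpec(shape = "sine", lengthPx = 140,
                                         maxWidth = 6, amplitude = 12,
                                         periods = 1.5,
                                         frameDim = c(512L, 612L)),
                         motionProgram = data.frame(
                           state = c("forward", "stationary", "backward", "forward"),
                           duration = c(30L, 20L, 10L, 40L),
                           speed = c(2, 0, 2, 2)),
                         headOscAmpDeg = 20, headOscFreqHz = 1, fps = 10,
                         saltPepperRate = 0, seed = 1L) {
  structure(list(worm = worm, motionProgram = motionProgram,
                 headOscAmpDeg = headOscAmpDeg, headOscFreqHz = headOscFreqHz,
                 fps = fps, saltPepperRate = saltPepperRate,
                 seed = as.integer(seed)), class = "sequenceSpec")
}

.rot2 <- function(pts, pivot, th) {
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  sweep(sweep(pts, 2L, pivot) %*% t(Rm), 2L, pivot, `+`)
}

#' Render a moving-worm sequence with per-frame ground truth
#'
#' The worm advances along its head tangent per the motion program
#' (forward towards the head, backward away), while the anterior quarter
#' oscillates sinusoidally about its base. Ground-truth head identity,
#' centroid and motion state are emitted for every frame.
#'
#' @param spec a \code{\link{sequenceSpec}}.
#' @param renderMasks render binary masks (TRUE) or return centerline truth
#'   only (faster; FALSE).
#' @return list with \code{masks} (list of logical matrices or NULL),
#'   \code{truth} (data.frame: frame, state, head_row, head_col, tail_row,
#'   tail_col, centroid_row, centroid_col) and \code{centerlines}
#'   (list of 100 x 2 matrices ordered head to tail).
#' @export
renderSequence <- function(spec, renderMasks = TRUE) {
  worm <- spec$worm
  prog <- spec$motionProgram
  states <- rep(as.character(prog$state), prog$duration)
  speeds <- rep(prog$speed, prog$duration)
  nF <- length(states)
  dense <- .placeCenterline(.centerlineDense(worm), worm)
  L <- worm$lengthPx
  headDir <- dense$points[1L, ] - dense$points[5L, ]
  headDir <- headDir / sqrt(sum(headDir^2))
  pivotIdx <- which.min(abs(dense$s - 0.25 * L))
  sNorm <- dense$s / L
  radii <- .widthAt(sNorm, worm$maxWidth, worm$taper) / 2
  masks <- if (renderMasks) vector("list", nF) else NULL
  centerlines <- vector("list", nF)
  truth <- data.frame(frame = seq_len(nF) - 1L, state = states,
                      head_row = 0, head_col = 0, tail_row = 0, tail_col = 0,
                      centroid_row = 0, centroid_col = 0)
  offset <- c(0, 0)
  .withSeed(spec$seed, {
    for (t in seq_len(nF)) {
      v <- switch(states[t], forward = speeds[t], backward = -speeds[t], 0)
      offset <- offset + v * headDir
      pts <- dense$points
      phi <- spec$headOscAmpDeg * pi / 180 *
        sin(2 * pi * spec$headOscFreqHz * (t - 1) / spec$fps)
      if (phi != 0) {
        ant <- seq_len(pivotIdx)
        pts[ant, ] <- .rot2(pts[ant, , drop = FALSE], pts[pivotIdx, ], phi)
      }
      pts <- sweep(pts, 2L, offset, `+`)
      cl <- .resampleTruth(list(points = pts), 100L)
      centerlines[[t]] <- cl
      truth$head_row[t] <- pts[1L, 1L]; truth$head_col[t] <- pts[1L, 2L]
      truth$tail_row[t] <- pts[nrow(pts), 1L]
      truth$tail_col[t] <- pts[nrow(pts), 2L]
      if (renderMasks) {
        m <- .paintDisks(pts, radii, worm$frameDim)
        if (spec$saltPepperRate > 0) {
          nFlip <- round(spec$saltPepperRate * length(m))
          if (nFlip > 0) {
            flip <- sample(length(m), nFlip)
            m[flip] <- !m[flip]
          }
        }
        masks[[t]] <- m
        com <- which(m, arr.ind = TRUE)
        truth$centroid_row[t] <- mean(com[, 1L])
        truth$centroid_col[t] <- mean(com[, 2L])
      } else {
        truth$centroid_row[t] <- mean(cl[, 1L])
        truth$centroid_col[t] <- mean(cl[, 2L])
      }
    }
  })
  list(masks = masks, truth = truth, centerlines = centerlines, spec = spec)
}

#' Render a synthetic fluorescence recording
#'
#' Three elliptical compartments with programmed per-frame intensities sit
#' on a uniform background with Gaussian noise, emulating calcium-imaging
#' stacks of the RIA axonal compartments.
#'
#' @param programs frames x compartments numeric matrix of true (noise-free)
#'   compartment intensities (camera units). Column names become
#'   compartment names; default nrD/nrV/loop.
#' @param frameDim (rows, cols) of each frame (default 256 x 256).
#' @param layout named list of ellipses (center = c(row, col), semi =
#'   c(a, b), angleDeg); default three small compartments near the frame
#'   center.
#' @param background uniform background level (camera units).
#' @param noiseSd Gaussian noise standard deviation (camera units).
#' @param seed integer seed (noise realization only).
#' @return list with \code{frames} (H x W x T array), \code{masks}
#'   (named list of logical matrices), \code{truth} (the programs),
#'   \code{background}, \code{noiseSd}.
#' @export
renderFluorescence <- function(programs, frameDim = c(256L, 256L),
                               layout = NULL, background = 100,
                               noiseSd = 5, seed = 1L) {
  programs <- as.matrix(programs)
  if (is.null(colnames(programs)))
    colnames(programs) <- c("nrD", "nrV", "loop")[seq_len(ncol(programs))]
  H <- frameDim[1L]; W <- frameDim[2L]
  if (is.null(layout)) {
    cr <- H / 2; cc <- W / 2
    layout <- list(
      nrD = list(center = c(cr - 25, cc), semi = c(6, 10), angleDeg = 20),
      nrV = list(center = c(cr + 25, cc), semi = c(6, 10), angleDeg = -20),
      loop = list(center = c(cr, cc + 30), semi = c(9, 5), angleDeg = 0)
    )[seq_len(ncol(programs))]
    names(layout) <- colnames(programs)
  }
  ellipseMask <- function(e) {
    th <- e$angleDeg * pi / 180
    rr <- matrix(seq_len(H), H, W) - e$center[1L]
    cc2 <- matrix(seq_len(W), H, W, byrow = TRUE) - e$center[2L]
    u <- rr * cos(th) + cc2 * sin(th)
    v <- -rr * sin(th) + cc2 * cos(th)
    (u / e$semi[1L])^2 + (v / e$semi[2L])^2 <= 1
  }
  masks <- lapply(layout, ellipseMask)
  nT <- nrow(programs)
  frames <- array(0, dim = c(H, W, nT))
  .withSeed(seed, {
    for (t in seq_len(nT)) {
      f <- matrix(background, H, W)
      for (j in seq_along(masks))
        f[masks[[j]]] <- programs[t, j]
      if (noiseSd > 0)
        f <- f + matrix(rnorm(H * W, 0, noiseSd), H, W)
      frames[, , t] <- pmax(f, 0)
    }
  })
  list(frames = frames, masks = masks, truth = programs,
       background = background, noiseSd = noiseSd)
}
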