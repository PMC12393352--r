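# Centerline extraction: mask -> one-pixel-wide skeleton -> ordered medial
# path (with self-touch correction) -> fixed-resolution spline skeleton with
# width profile and scalar morphometry.

.shiftMat <- function(m, dr, dc) {
  # out[i, j] = m[i + dr, j + dc], FALSE outside
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(ri) && length(ci))
    out[ri, ci] <- m[ri + dr, ci + dc]
  out
}

#' Morphologically thin a mask to a one-pixel-wide skeleton
#'
#' Iterative two-subpass thinning (Zhang-Suen) preserving 8-connectivity.
#' The mask must be a single connected component; multi-component input is
#' an error directing the caller to \code{\link{cleanSmallParticles}}.
#'
#' @param mask \linkS4class{LabeledMask} or logical matrix.
#' @return logical matrix of skeleton pixels (same dimensions as the mask).
#' @export
skeletonizeMask <- function(mask) {
  p <- .pix(mask)
  if (!any(p)) stop("empty mask cannot be skeletonized")
  lab <- labelComponents(p, 8)
  if (max(lab) > 1L)
    stop("mask has ", max(lab),
         " connected components; run cleanSmallParticles first")
  nr <- nrow(p); nc <- ncol(p)
  img <- matrix(FALSE, nr + 2L, nc + 2L)
  img[2:(nr + 1L), 2:(nc + 1L)] <- p
  nbrOff <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                 c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P <- lapply(nbrOff, function(o) .shiftMat(img, o[1L], o[2L]))
      B <- Reduce(`+`, P)
      seqP <- c(P, P[1L])
      A <- Reduce(`+`, lapply(seq_len(8L), function(k)
        (!seqP[[k]]) & seqP[[k + 1L]]))
      if (pass == 1L) {
        rot <- !(P[[1L]] & P[[3L]] & P[[5L]]) & !(P[[3L]] & P[[5L]] & P[[7L]])
      } else {
        rot <- !(P[[1L]] & P[[3L]] & P[[7L]]) & !(P[[1L]] & P[[5L]] & P[[7L]])
      }
      del <- img & B >= 2 & B <= 6 & A == 1 & rot
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- img[2:(nr + 1L), 2:(nc + 1L)]
  if (!any(out)) {
    # pathological tiny blob thinned away entirely: keep its central pixel
    idx <- which(p, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    nearest <- idx[which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2), ]
    out[nearest[1], nearest[2]] <- TRUE
  }
  out
}

.skelCoords <- function(skeleton) {
  if (is.matrix(skeleton) && is.logical(skeleton))
    which(skeleton, arr.ind = TRUE)
  else {
    m <- as.matrix(skeleton)
    dimnames(m) <- NULL
    m
  }
}

# skeleton pixel graph: nodes = pixels, edges between 8-neighbours weighted
# by Euclidean step (1 / sqrt(2)). A diagonal edge whose two pixels share an
# orthogonal skeleton neighbour is redundant (the path exists through that
# neighbour) and would create spurious 3-cycles, so it is dropped.
.skeletonGraph <- function(coords) {
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2], sep = ",")
  idx <- seq_len(n)
  names(idx) <- key
  lookup <- function(r, c) {
    v <- idx[paste(r, c, sep = ",")]
    ifelse(is.na(v), 0L, v)
  }
  edges <- NULL
  w <- numeric(0)
  for (o in list(c(0L, 1L), c(1L, 0L))) {
    to <- lookup(coords[, 1] + o[1L], coords[, 2] + o[2L])
    hit <- to > 0L
    edges <- rbind(edges, cbind(idx[hit], to[hit]))
    w <- c(w, rep(1, sum(hit)))
  }
  for (o in list(c(1L, 1L), c(1L, -1L))) {
    to <- lookup(coords[, 1] + o[1L], coords[, 2] + o[2L])
    sh1 <- lookup(coords[, 1] + o[1L], coords[, 2]) > 0L
    sh2 <- lookup(coords[, 1], coords[, 2] + o[2L]) > 0L
    hit <- to > 0L & !sh1 & !sh2
    edges <- rbind(edges, cbind(idx[hit], to[hit]))
    w <- c(w, rep(sqrt(2), sum(hit)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges), weight = w)
  igraph::V(g)$row <- coords[, 1]
  igraph::V(g)$col <- coords[, 2]
  g
}

.graphEndpoints <- function(g) {
  which(igraph::degree(g) == 1L)
}

# deterministic endpoint ordering: by (row, col)
.orderEndpoints <- function(g, eps) {
  eps[order(igraph::V(g)$row[eps], igraph::V(g)$col[eps])]
}

.maxEndpointDist <- function(g) {
  eps <- .graphEndpoints(g)
  if (length(eps) < 2L) return(0)
  d <- igraph::distances(g, v = eps, to = eps, weights = igraph::E(g)$weight)
  m <- max(d[is.finite(d)])
  if (is.finite(m)) m else 0
}

.medialPathFromGraph <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("degenerate posture: skeleton reduced to a single point")
  if (igraph::ecount(g) >= n)
    stop("cyclic skeleton: run correctSelfTouching first")
  eps <- .orderEndpoints(g, .graphEndpoints(g))
  if (length(eps) < 2L)
    stop("skeleton graph has fewer than two endpoints")
  d <- igraph::distances(g, v = eps, to = eps, weights = igraph::E(g)$weight)
  best <- c(1L, 2L); bestLen <- -Inf
  for (i in seq_along(eps)) for (j in seq_along(eps)) {
    if (j <= i) next
    if (is.finite(d[i, j]) && d[i, j] > bestLen + 1e-9) {
      bestLen <- d[i, j]; best <- c(i, j)
    }
  }
  vp <- igraph::shortest_paths(g, from = eps[best[1L]], to = eps[best[2L]],
                               weights = igraph::E(g)$weight)$vpath[[1L]]
  cbind(row = igraph::V(g)$row[as.integer(vp)],
        col = igraph::V(g)$col[as.integer(vp)])
}

#' Extract the ordered medial path from skeleton pixels
#'
#' Builds the skeleton pixel graph (8-neighbour edges weighted 1 or
#' sqrt(2)) and returns the maximum-total-length simple path between two
#' degree-1 endpoints; side branches are pruned by construction. Ties are
#' broken towards the lexicographically smallest (row, col) endpoint pair.
#'
#' @param skeleton logical matrix of skeleton pixels, or an n x 2 coordinate
#'   matrix. Must form one connected component.
#' @return ordered n x 2 matrix of (row, col) pixel coordinates.
#' @export
extractMedialPath <- function(skeleton) {
  coords <- .skelCoords(skeleton)
  g <- .skeletonGraph(coords)
  comp <- igraph::components(g)
  if (comp$no > 1L) stop("skeleton pixels must form one connected component")
  .medialPathFromGraph(g)
}

#' Open up self-touching skeletons
#'
#' Self-touching postures (O- and 6-shapes) produce loops in the raw
#' skeleton. This routine restores a single continuous centerline: while the
#' skeleton graph contains cycles, it removes the cycle edge whose deletion
#' least reduces the maximum endpoint-to-endpoint path length, then extracts
#' the medial path. The result is always branchless and acyclic and at least
#' as long as the longest acyclic path of the input graph.
#'
#' @param skeleton logical matrix or n x 2 coordinates of skeleton pixels.
#' @param mask the originating mask (kept for interface compatibility /
#'   diagnostics; the correction itself is purely graph-based).
#' @return ordered n x 2 matrix of (row, col) path coordinates.
#' @export
correctSelfTouching <- function(skeleton, mask = NULL) {
  coords <- .skelCoords(skeleton)
  if (nrow(coords) < 2L)
    stop("degenerate posture: skeleton reduced to a single point")
  g <- .skeletonGraph(coords)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  while (igraph::ecount(g) > igraph::vcount(g) - 1L) {
    brid <- igraph::bridges(g)
    cand <- setdiff(seq_len(igraph::ecount(g)), as.integer(brid))
    best <- cand[1L]; bestObj <- -Inf
    for (e in cand) {
      g2 <- igraph::delete_edges(g, e)
      obj <- .maxEndpointDist(g2)
      if (obj > bestObj + 1e-9) {
        bestObj <- obj
        best <- e
      }
    }
    g <- igraph::delete_edges(g, best)
  }
  .medialPathFromGraph(g)
}

#' Resample an ordered pixel path to a fixed-resolution spline skeleton
#'
#' Fits a smoothing spline to each coordinate against cumulative arc
#' length and samples \code{nPoints} positions at equal parameter spacing.
#' Smoothing removes pixel-grid jaggedness while preserving endpoints
#' within the smoothing tolerance.
#'
#' @param path ordered n x 2 (row, col) matrix, n >= 4.
#' @param nPoints number of output points (default 100).
#' @param df effective degrees of freedom of the smoothing spline; default
#'   one third of the path length (moderate smoothing).
#' @param frameIndex frame index carried into the result.
#' @return a \linkS4class{WormSkeleton} (widths all zero until
#'   \code{\link{measureWidths}}).
#' @export
resampleSpline <- function(path, nPoints = 100L, df = NULL, frameIndex = 0L) {
  path <- as.matrix(path)
  if (nrow(path) < 4L)
    stop("degenerate posture: path shorter than 4 points")
  step <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                        path[-nrow(path), , drop = FALSE])^2))
  keep <- c(TRUE, step > 0)
  path <- path[keep, , drop = FALSE]
  if (nrow(path) < 4L)
    stop("degenerate posture: path shorter than 4 distinct points")
  tt <- c(0, cumsum(sqrt(rowSums((path[-1L, , drop = FALSE] -
                                  path[-nrow(path), , drop = FALSE])^2))))
  n <- nrow(path)
  if (is.null(df)) df <- min(max(4L, round(n / 3)), n - 1L)
  fitCoord <- function(y) {
    if (sd(y) < 1e-12) return(rep(y[1L], nPoints))
    out <- tryCatch({
      fit <- smooth.spline(tt, y, df = df)
      predict(fit, seq(0, max(tt), length.out = nPoints))$y
    }, error = function(e) NULL)
    if (is.null(out))
      out <- approx(tt, y, xout = seq(0, max(tt), length.out = nPoints))$y
    out
  }
  pts <- cbind(fitCoord(path[, 1L]), fitCoord(path[, 2L]))
  # guard against numerically repeated points after heavy smoothing
  d <- sqrt(rowSums((pts[-1L, ] - pts[-nPoints, ])^2))
  if (any(d <= 0)) {
    pts <- cbind(approx(tt, path[, 1L], n = nPoints)$y,
                 approx(tt, path[, 2L], n = nPoints)$y)
  }
  WormSkeleton(pts, frameIndex = frameIndex)
}

.bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- min(max(r, 1), nr); c <- min(max(c, 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r1, c0] * fr * (1 - fc) +
    m[r0, c1] * (1 - fr) * fc + m[r1, c1] * fr * fc
}

.insideMask <- function(p, r, c) {
  ri <- round(r); ci <- round(c)
  ri >= 1 && ri <= nrow(p) && ci >= 1 && ci <= ncol(p) && p[ri, ci]
}

.extendPathEnds <- function(path, mask, dm, step = 0.25) {
  # thinning erodes the skeleton short of the body tips; extend each end
  # along its outward tangent until the mask boundary, capped by the
  # distance-transform value at the endpoint (so blunt ends do not run
  # into a corner)
  p <- .pix(mask)
  m <- nrow(path)
  extend1 <- function(pt, dir) {
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) return(NULL)
    dir <- dir / nrm
    cap <- .bilinear(dm, pt[1L], pt[2L]) + 1
    d <- 0
    repeat {
      if (d + step > cap) break
      if (!.insideMask(p, pt[1L] + (d + step) * dir[1L],
                       pt[2L] + (d + step) * dir[2L])) break
      d <- d + step
    }
    if (d > 0.5) pt + d * dir else NULL
  }
  tipA <- extend1(path[1L, ], path[1L, ] - path[min(6L, m), ])
  tipB <- extend1(path[m, ], path[m, ] - path[max(1L, m - 5L), ])
  rbind(if (!is.null(tipA)) tipA, path, if (!is.null(tipB)) tipB)
}

#' Refine skeleton points to the sub-pixel medial ridge
#'
#' Thinned skeletons carry coherent sub-pixel wiggle that corrupts
#' curvature estimates. Each interior point is moved along its local
#' normal to the parabolic maximum of the mask's distance transform (the
#' medial ridge), clamped to \code{maxShift}.
#'
#' @param skeleton a \linkS4class{WormSkeleton} or n x 2 point matrix.
#' @param mask the originating mask.
#' @param maxShift largest allowed per-point displacement (px).
#' @param iterations refinement passes (default 2; tangents improve after
#'   the first pass).
#' @return object of the same type with refined point coordinates.
#' @export
refineToRidge <- function(skeleton, mask, maxShift = 1.5, iterations = 2L) {
  p <- .pix(mask)
  dm <- EBImage::distmap(matrix(as.numeric(p), nrow(p), ncol(p)))
  pts <- if (is(skeleton, "WormSkeleton")) skelPoints(skeleton) else as.matrix(skeleton)
  off <- seq(-2.5, 2.5, by = 0.25)
  X <- cbind(1, off, off^2)
  for (it in seq_len(iterations)) {
    m <- nrow(pts)
    for (i in 2:(m - 1L)) {
      tg <- pts[min(i + 2L, m), ] - pts[max(i - 2L, 1L), ]
      nrm <- sqrt(sum(tg^2))
      if (nrm < 1e-9) next
      tg <- tg / nrm
      nv <- c(-tg[2L], tg[1L])
      vals <- vapply(off, function(d)
        .bilinear(dm, pts[i, 1L] + d * nv[1L], pts[i, 2L] + d * nv[2L]),
        numeric(1))
      beta <- stats::lm.fit(X, vals)$coefficients
      if (is.na(beta[3L]) || beta[3L] >= 0) next
      v <- -beta[2L] / (2 * beta[3L])
      v <- max(min(v, maxShift), -maxShift)
      pts[i, ] <- pts[i, ] + v * nv
    }
  }
  if (is(skeleton, "WormSkeleton")) {
    skeleton@points <- pts
    skeleton
  } else pts
}

#' Full mask-to-skeleton chain
#'
#' Thinning, self-touch correction, tip extension, spline resampling,
#' sub-pixel ridge refinement, a final smoothing respline, and width
#' measurement. This is the skeleton used by every pipeline.
#'
#' @param mask single-worm mask (cleaned; see
#'   \code{\link{cleanSmallParticles}}).
#' @param nPoints output resolution (default 100).
#' @param frameIndex frame index carried into the skeleton.
#' @param finalDf degrees of freedom of the final smoothing respline
#'   (default 12; low enough to suppress residual ridge noise, high
#'   enough to follow deep bends).
#' @param widths measure the width profile (default TRUE).
#' @return a \linkS4class{WormSkeleton}.
#' @export
maskToSkeleton <- function(mask, nPoints = 100L, frameIndex = 0L,
                           finalDf = 12L, widths = TRUE) {
  p <- .pix(mask)
  dm <- EBImage::distmap(matrix(as.numeric(p), nrow(p), ncol(p)))
  path <- correctSelfTouching(skeletonizeMask(p), p)
  path <- .extendPathEnds(path, p, dm)
  ws <- resampleSpline(path, nPoints = nPoints, frameIndex = frameIndex)
  ws <- refineToRidge(ws, p)
  ws <- resampleSpline(skelPoints(ws), nPoints = nPoints,
                       df = min(finalDf, nPoints - 1L), frameIndex = frameIndex)
  if (widths) ws <- measureWidths(ws, p)
  ws
}

#' Measure the body width profile along a skeleton
#'
#' Width at a centerline point is the extent of the mask along the local
#' normal (a diameter, not a half-width), measured between the two
#' boundary crossings (pixels as unit squares). It is computed from the
#' distance transform at the point (2 d - 1, the center-to-boundary
#' distance on each side); where that estimate and a direct normal
#' ray-cast disagree by more than 20\% the ray-cast wins (the distance
#' transform underestimates near strong bends).
#'
#' @param skeleton a \linkS4class{WormSkeleton}.
#' @param mask the single-worm mask the skeleton came from.
#' @return the skeleton with its \code{widths} slot filled.
#' @export
measureWidths <- function(skeleton, mask) {
  p <- .pix(mask)
  dm <- EBImage::distmap(matrix(as.numeric(p), nrow(p), ncol(p)))
  pts <- skelPoints(skeleton)
  n <- nrow(pts)
  tangents <- rbind(pts[2L, ] - pts[1L, ],
                    (pts[3:n, , drop = FALSE] - pts[1:(n - 2L), , drop = FALSE]) / 2,
                    pts[n, ] - pts[n - 1L, ])
  widths <- numeric(n)
  outside <- 0L
  for (i in seq_len(n)) {
    r <- pts[i, 1L]; c <- pts[i, 2L]
    if (!.insideMask(p, r, c)) {
      # smoothed point drifted outside: use the nearest interior pixel
      outside <- outside + 1L
      idx <- which(p, arr.ind = TRUE)
      j <- which.min((idx[, 1] - r)^2 + (idx[, 2] - c)^2)
      r <- idx[j, 1]; c <- idx[j, 2]
    }
    wdt <- max(2 * .bilinear(dm, r, c) - 1, 0)
    tg <- tangents[i, ] / max(sqrt(sum(tangents[i, ]^2)), 1e-12)
    nv <- c(-tg[2L], tg[1L])
    ray <- 0
    for (s in c(1, -1)) {
      d <- 0
      repeat {
        d <- d + 0.25
        if (!.insideMask(p, r + s * d * nv[1L], c + s * d * nv[2L])) break
        if (d > max(dim(p))) break
      }
      ray <- ray + (d - 0.25) + 0.125   # half a step to the boundary
    }
    widths[i] <- if (abs(ray - wdt) > 0.2 * max(ray, wdt)) ray else wdt
  }
  if (outside > 0L)
    message("measureWidths: ", outside,
            " skeleton point(s) outside mask; used nearest interior pixel")
  skeleton@widths <- widths
  skeleton
}

#' Scalar morphometry of one worm mask
#'
#' Area is the true-pixel count; perimeter the Euclidean length of the
#' boundary contour polygon; length the skeleton pixel length; width
#' statistics come from the skeleton's width profile.
#'
#' @param mask single-component worm mask.
#' @param skeleton the matching \linkS4class{WormSkeleton} (with widths).
#' @return list with \code{area_px}, \code{perimeter_px}, \code{length_px},
#'   \code{mean_width_px}, \code{max_width_px}, \code{widths}.
#' @export
measureMorphometry <- function(mask, skeleton) {
  p <- .pix(mask)
  area <- sum(p)
  oc <- EBImage::ocontour(matrix(as.integer(p), nrow(p), ncol(p)))
  perim <- if (length(oc)) {
    ctr <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
    closed <- rbind(ctr, ctr[1L, ])
    sum(sqrt(rowSums((closed[-1L, , drop = FALSE] -
                      closed[-nrow(closed), , drop = FALSE])^2)))
  } else 0
  widths <- skelWidths(skeleton)
  list(
    area_px = area,
    perimeter_px = perim,
    length_px = pixelLength(skeleton),
    mean_width_px = mean(widths),
    max_width_px = max(widths),
    widths = widths
  )
}

#' Write skeletons as CSV (frame, point_index, row, col, width)
#'
#' @param skeletons list of \linkS4class{WormSkeleton}.
#' @param path output CSV path.
#' @export
writeSkeletonCSV <- function(skeletons, path) {
  rows <- do.call(rbind, lapply(skeletons, function(s) {
    p <- skelPoints(s)
    data.frame(frame = frameIndex(s), point_index = seq_len(nrow(p)) - 1L,
               row = p[, 1L], col = p[, 2L], width = skelWidths(s))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
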