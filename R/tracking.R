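# Temporal analysis of crawling recordings: head/tail identity, head-bend
# angle, smoothed centroid path, movement states, bouts and path metrics.

.endpointsOf <- function(skel) {
  p <- skelPoints(skel)
  rbind(p[1L, ], p[nrow(p), ])
}

#' Assign head and tail across a skeleton sequence
#'
#' Endpoint identity is first made temporally consistent by solving, frame
#' to frame, the minimum-total-distance assignment between the current and
#' previous endpoint pairs (the optimal 2x2 assignment). Within each
#' sliding window the endpoint group with the larger cumulative
#' displacement is the head (worms lead with the head and it oscillates);
#' per-frame votes from all windows covering a frame are aggregated by
#' majority. Output skeletons are ordered head first.
#'
#' Brightness is deliberately not used: at wide-field resolution the head
#' is not distinguishable by intensity.
#'
#' @param skeletons list of \linkS4class{WormSkeleton}, one per frame.
#' @param window sliding window length in frames (default 5).
#' @return list of oriented skeletons with attributes \code{headGroup}
#'   (which chained endpoint group won) and \code{votes}.
#' @export
assignHeadTail <- function(skeletons, window = 5L) {
  nF <- length(skeletons)
  if (nF < window)
    stop("need at least ", window, " frames for head-tail assignment")
  # chain endpoint identity: groupA[t] / groupB[t] are temporally consistent
  A <- matrix(0, nF, 2L); B <- matrix(0, nF, 2L)
  swapped <- logical(nF)
  e <- .endpointsOf(skeletons[[1L]])
  A[1L, ] <- e[1L, ]; B[1L, ] <- e[2L, ]
  for (t in 2L:nF) {
    e <- .endpointsOf(skeletons[[t]])
    keep <- sqrt(sum((e[1L, ] - A[t - 1L, ])^2)) +
            sqrt(sum((e[2L, ] - B[t - 1L, ])^2))
    swap <- sqrt(sum((e[1L, ] - B[t - 1L, ])^2)) +
            sqrt(sum((e[2L, ] - A[t - 1L, ])^2))
    if (swap < keep) {
      A[t, ] <- e[2L, ]; B[t, ] <- e[1L, ]; swapped[t] <- TRUE
    } else {
      A[t, ] <- e[1L, ]; B[t, ] <- e[2L, ]
    }
  }
  dispA <- c(0, sqrt(rowSums((A[-1L, , drop = FALSE] - A[-nF, , drop = FALSE])^2)))
  dispB <- c(0, sqrt(rowSums((B[-1L, , drop = FALSE] - B[-nF, , drop = FALSE])^2)))
  votesA <- numeric(nF); votesB <- numeric(nF)
  lastCall <- "A"  # tie persistence: a static worm keeps its assignment
  for (s0 in seq_len(nF - window + 1L)) {
    idx <- s0:(s0 + window - 1L)
    da <- sum(dispA[idx[-1L]]); db <- sum(dispB[idx[-1L]])
    call <- if (da > db) "A" else if (db > da) "B" else lastCall
    lastCall <- call
    if (call == "A") votesA[idx] <- votesA[idx] + 1
    else votesB[idx] <- votesB[idx] + 1
  }
  headIsA <- votesA >= votesB
  out <- vector("list", nF)
  for (t in seq_len(nF)) {
    sk <- skeletons[[t]]
    p <- skelPoints(sk)
    firstIsA <- !swapped[t]
    headFirst <- (headIsA[t] && firstIsA) || (!headIsA[t] && !firstIsA)
    if (!headFirst) {
      sk@points <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      if (length(sk@widths)) sk@widths <- rev(sk@widths)
    }
    out[[t]] <- sk
  }
  attr(out, "headGroup") <- ifelse(headIsA, "A", "B")
  attr(out, "votes") <- cbind(A = votesA, B = votesB)
  out
}

#' Repair sudden head jumps
#'
#' A head position jumping more than \code{factor} times the median
#' inter-frame head displacement of the trailing history, in a way a
#' head/tail swap would undo (the head lands where the tail was and vice
#' versa), indicates a single-frame swap; that frame is flipped. A
#' consistency re-check runs after the pass. Genuine fast maneuvers
#' (omega turns) move the head somewhere new and are untouched.
#'
#' @param skeletons oriented skeleton list from \code{\link{assignHeadTail}}.
#' @param history trailing history length in frames (default 5).
#' @param factor jump threshold multiple (default 3).
#' @param floorPx lower bound on the history displacement scale so a
#'   near-static history does not flag every micro-move (default 0.5 px).
#' @return oriented skeleton list; corrected frames in
#'   \code{attr(, "corrected")}.
#' @export
correctHeadJumps <- function(skeletons, history = 5L, factor = 3,
                             floorPx = 0.5) {
  nF <- length(skeletons)
  corrected <- integer(0)
  for (pass in 1:2) {
    heads <- t(vapply(skeletons, function(s) skelPoints(s)[1L, ], numeric(2)))
    tails <- t(vapply(skeletons, function(s) {
      p <- skelPoints(s); p[nrow(p), ]
    }, numeric(2)))
    changed <- FALSE
    for (t in (history + 1L):nF) {
      hist <- (t - history):(t - 1L)
      hd <- sqrt(rowSums((heads[hist[-1L], , drop = FALSE] -
                          heads[hist[-length(hist)], , drop = FALSE])^2))
      scale <- max(median(hd), floorPx)
      jumpH <- sqrt(sum((heads[t, ] - heads[t - 1L, ])^2))
      jumpT <- sqrt(sum((tails[t, ] - tails[t - 1L, ])^2))
      costKeep <- jumpH + jumpT
      costSwap <- sqrt(sum((heads[t, ] - tails[t - 1L, ])^2)) +
                  sqrt(sum((tails[t, ] - heads[t - 1L, ])^2))
      if (jumpH > factor * scale && costSwap < costKeep) {
        # head leapt to where the tail was (and vice versa): swapped frame.
        # a genuine fast maneuver moves the head but not onto the tail,
        # so swapping would not reduce the discontinuity
        sk <- skeletons[[t]]
        p <- skelPoints(sk)
        sk@points <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        if (length(sk@widths)) sk@widths <- rev(sk@widths)
        skeletons[[t]] <- sk
        heads[t, ] <- skelPoints(sk)[1L, ]
        tails[t, ] <- skelPoints(sk)[nrow(skelPoints(sk)), ]
        corrected <- c(corrected, t)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(skeletons, "corrected") <- unique(corrected)
  skeletons
}

#' Head-bend angle of one oriented skeleton
#'
#' The main body axis is the total-least-squares line through the
#' posterior \code{1 - headFraction} of skeleton points, oriented towards
#' the anterior. The head vector runs from the head-region base to the
#' head endpoint. The signed angle between them, in degrees in
#' (-180, 180], is the head bend; 0 means a straight head. Sign encodes
#' the bend side; dorsal/ventral is not resolved here.
#'
#' @param skeleton oriented \linkS4class{WormSkeleton} (head first).
#' @param headFraction fraction of points forming the head region
#'   (default 0.15).
#' @return signed angle in degrees, or NA for a degenerate posterior.
#' @export
headBendAngle <- function(skeleton, headFraction = 0.15) {
  p <- skelPoints(skeleton)
  n <- nrow(p)
  nb <- max(2L, ceiling(headFraction * n))     # head-region base index
  post <- p[nb:n, , drop = FALSE]
  if (max(apply(post, 2L, function(x) diff(range(x)))) < 1e-6) return(NA_real_)
  pc <- prcomp(post)
  ax <- pc$rotation[, 1L]
  # orient the axis anteriorly (towards the head-region base)
  if (sum(ax * (p[nb, ] - p[n, ])) < 0) ax <- -ax
  hv <- p[1L, ] - p[nb, ]
  ang <- atan2(ax[1L] * hv[2L] - ax[2L] * hv[1L], sum(ax * hv)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Smooth a centroid trajectory (Savitzky-Golay)
#'
#' Polynomial least-squares smoothing per coordinate preserves the
#' underlying movement while removing the frame-to-frame jitter that
#' body-shape changes impose on the center of mass.
#'
#' @param centroids n x 2 matrix (row, col) per frame.
#' @param window odd filter window (default 11).
#' @param polyorder polynomial order (default 3, < window).
#' @return smoothed n x 2 matrix.
#' @export
smoothCentroid <- function(centroids, window = 11L, polyorder = 3L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < window) {
    window <- max(polyorder + 1L + (polyorder %% 2L == 0L), n - (1 - n %% 2L))
    if (window %% 2L == 0L) window <- window - 1L
    message("smoothCentroid: window shrunk to ", window, " for short series")
  }
  if (window <= polyorder) return(centroids)
  apply(centroids, 2L, function(y) signal::sgolayfilt(y, p = polyorder,
                                                      n = window))
}

#' Classify per-frame movement state
#'
#' Velocity is the smoothed-centroid difference between consecutive
#' frames. Speeds below \code{stationaryThreshold} are stationary;
#' otherwise the sign of the velocity's scalar projection on the
#' centroid-to-head unit vector separates forward (towards the head) from
#' backward. An exactly perpendicular velocity (zero projection) counts as
#' stationary for determinism. The first frame inherits the second
#' frame's label.
#'
#' @param centroids smoothed n x 2 centroid matrix.
#' @param heads n x 2 head-position matrix.
#' @param stationaryThreshold speed threshold in px/frame (default 0.5).
#' @return character vector of "forward"/"backward"/"stationary".
#' @export
classifyMotion <- function(centroids, heads, stationaryThreshold = 0.5) {
  n <- nrow(centroids)
  lab <- character(n)
  for (t in 2L:n) {
    v <- centroids[t, ] - centroids[t - 1L, ]
    sp <- sqrt(sum(v^2))
    if (sp < stationaryThreshold) {
      lab[t] <- "stationary"
    } else {
      ax <- heads[t, ] - centroids[t, ]
      nax <- sqrt(sum(ax^2))
      proj <- if (nax > 0) sum(v * ax) / nax else 0
      lab[t] <- if (proj > 0) "forward" else if (proj < 0) "backward"
                else "stationary"
    }
  }
  lab[1L] <- lab[2L]
  lab
}

#' Correct motion labels against temporal context
#'
#' Isolated runs shorter than \code{minRun} frames flanked on both sides
#' by one common state whose runs are jointly credible (combined length
#' at least \code{minRun}) are relabeled to that state, iterated to a
#' fixpoint. Rapid alternations with no credible flanking majority are
#' left unchanged.
#'
#' @param labels character vector of motion labels.
#' @param minRun minimum credible run length (default 3).
#' @return corrected label vector.
#' @export
correctMotionLabels <- function(labels, minRun = 3L) {
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k < 3L) return(labels)
    changed <- FALSE
    for (i in 2L:(k - 1L)) {
      if (r$lengths[i] < minRun && r$values[i - 1L] == r$values[i + 1L] &&
          r$values[i] != r$values[i - 1L] &&
          r$lengths[i - 1L] + r$lengths[i + 1L] >= minRun) {
        r$values[i] <- r$values[i - 1L]
        changed <- TRUE
      }
    }
    if (!changed) return(labels)
    labels <- inverse.rle(r)
  }
}

#' Extract behavioral bouts
#'
#' Maximal runs of one movement state become bouts with their temporal
#' duration and spatial extent (summed inter-frame centroid distance
#' within the bout).
#'
#' @param labels per-frame motion labels.
#' @param centroids n x 2 centroid matrix (smoothed).
#' @return data.frame: motion, start_frame, end_frame, duration_frames,
#'   distance_px (frame indices 0-based).
#' @export
extractBouts <- function(labels, centroids) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dist <- vapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    if (length(idx) < 2L) return(0)
    sum(sqrt(rowSums((centroids[idx[-1L], , drop = FALSE] -
                      centroids[idx[-length(idx)], , drop = FALSE])^2)))
  }, numeric(1))
  data.frame(motion = r$values, start_frame = starts - 1L,
             end_frame = ends - 1L, duration_frames = r$lengths,
             distance_px = dist)
}

#' Summarize a tracked path
#'
#' @param labels per-frame motion labels.
#' @param centroids n x 2 centroid matrix.
#' @param bouts bout table from \code{\link{extractBouts}}.
#' @return list: total_path_length_px, max_displacement_px,
#'   fraction_forward, fraction_backward, fraction_stationary,
#'   mean_forward_bout_frames, mean_backward_bout_frames.
#' @export
summarizePath <- function(labels, centroids, bouts = extractBouts(labels, centroids)) {
  n <- length(labels)
  steps <- sqrt(rowSums((centroids[-1L, , drop = FALSE] -
                         centroids[-n, , drop = FALSE])^2))
  disp <- sqrt(rowSums(sweep(centroids, 2L, centroids[1L, ])^2))
  mb <- function(state) {
    d <- bouts$duration_frames[bouts$motion == state]
    if (length(d)) mean(d) else NA_real_
  }
  list(
    total_path_length_px = sum(steps),
    max_displacement_px = max(disp),
    fraction_forward = sum(labels == "forward") / n,
    fraction_backward = sum(labels == "backward") / n,
    fraction_stationary = sum(labels == "stationary") / n,
    mean_forward_bout_frames = mb("forward"),
    mean_backward_bout_frames = mb("backward")
  )
}
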