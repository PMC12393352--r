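# Shared fixtures, built in code and cached for the duration of one test run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# one rendered exemplar per shape class, with its recovered skeleton
shapeExemplars <- function() fixture("shapeExemplars", function() {
  specs <- list(
    straight  = wormSpec("straight", lengthPx = 300, maxWidth = 12,
                         frameDim = c(400L, 400L)),
    mild_s    = wormSpec("sine", lengthPx = 300, maxWidth = 12,
                         amplitude = 12, periods = 1.5, frameDim = c(400L, 400L)),
    s_shape   = wormSpec("sine", lengthPx = 300, maxWidth = 12,
                         amplitude = 25, periods = 1.5, frameDim = c(400L, 400L)),
    c_shape   = wormSpec("c_shape", lengthPx = 300, maxWidth = 12,
                         frameDim = c(400L, 400L)),
    u_shape   = wormSpec("u_shape", lengthPx = 300, maxWidth = 12,
                         frameDim = c(400L, 400L)),
    o_shape   = wormSpec("o_gap", lengthPx = 300, maxWidth = 12,
                         gapAngleDeg = 60, frameDim = c(400L, 400L)),
    six_shape = wormSpec("six_shape", lengthPx = 300, maxWidth = 12,
                         frameDim = c(400L, 400L))
  )
  lapply(specs, function(sp) {
    w <- suppressMessages(renderWorm(sp))
    ws <- suppressMessages(maskToSkeleton(w$mask))
    curv <- gaussianCurvatureProfile(ws)
    amp <- amplitudeProfile(ws)
    list(spec = sp, mask = w$mask, truth = w$truth, skeleton = ws,
         curvature = curv, amplitude = amp, length = pixelLength(ws))
  })
})

# arc-family worms used by the geometry oracles
arcFamily <- function() fixture("arcFamily", function() {
  lapply(c(30, 50, 80, 120), function(R) {
    L <- 2.5 * R
    wd <- min(8, round(R / 5))
    w <- suppressMessages(renderWorm(
      wormSpec("arc", lengthPx = L, maxWidth = wd, taper = 0.35, radius = R,
               frameDim = c(6L * R, 6L * R))))
    ws <- suppressMessages(maskToSkeleton(w$mask))
    list(R = R, L = L, skeleton = ws,
         curvature = gaussianCurvatureProfile(ws))
  })
})

# crawl sequence (centerline truth only; no mask rendering) with a reversal
crawlSequence <- function() fixture("crawlSequence", function() {
  sq <- sequenceSpec(
    motionProgram = data.frame(
      state = c("forward", "backward", "forward"),
      duration = c(40L, 15L, 45L), speed = c(2, 2, 2)),
    seed = 11L)
  renderSequence(sq, renderMasks = FALSE)
})

skeletonsFromCenterlines <- function(seqOut) {
  lapply(seq_along(seqOut$centerlines), function(t)
    WormSkeleton(seqOut$centerlines[[t]], frameIndex = t - 1L))
}

# brute-force connected-component overlap oracle: all-pairs intersection
# plus union-find, independent of the igraph-based implementation
bruteForceOverlapKeep <- function(pixList, areas) {
  n <- length(pixList)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (any(pixList[[i]] & pixList[[j]])) {
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  keep <- vapply(unique(roots), function(r) {
    idx <- which(roots == r)
    idx[which.max(areas[idx])]
  }, integer(1))
  sort(keep)
}

# grow a random pixel tree (acyclic in the skeleton-graph sense) on a grid.
# a candidate pixel is accepted only if it 8-touches exactly one pixel of
# the current set; such a pixel adds exactly one edge to the skeleton
# graph, so the growth provably stays a tree
randomPixelTree <- function(nPix, gridDim = c(64L, 64L)) {
  start <- c(sample(5:(gridDim[1] - 5), 1), sample(5:(gridDim[2] - 5), 1))
  coords <- matrix(start, 1, 2)
  occupied <- matrix(FALSE, gridDim[1], gridDim[2])
  occupied[start[1], start[2]] <- TRUE
  nTouch <- function(r, c) {
    sum(occupied[max(1, r - 1):min(gridDim[1], r + 1),
                 max(1, c - 1):min(gridDim[2], c + 1)]) -
      occupied[r, c]
  }
  tries <- 0L
  while (nrow(coords) < nPix && tries < nPix * 40L) {
    tries <- tries + 1L
    base <- coords[sample(nrow(coords), 1), ]
    off <- c(sample(-1:1, 1), sample(-1:1, 1))
    cand <- base + off
    if (all(off == 0)) next
    if (any(cand < 2) || cand[1] > gridDim[1] - 1 || cand[2] > gridDim[2] - 1) next
    if (occupied[cand[1], cand[2]]) next
    if (nTouch(cand[1], cand[2]) != 1L) next
    coords <- rbind(coords, cand)
    occupied[cand[1], cand[2]] <- TRUE
  }
  coords
}

# exhaustive endpoint-pair longest path on a tree, via DFS independent of
# igraph shortest paths
bruteForceLongestEndpointPath <- function(coords) {
  n <- nrow(coords)
  adj <- vector("list", n)
  wts <- vector("list", n)
  key <- paste(coords[, 1], coords[, 2], sep = ",")
  idx <- seq_len(n); names(idx) <- key
  look <- function(r, c) {
    v <- idx[paste(r, c, sep = ",")]
    if (is.na(v)) 0L else v
  }
  for (i in seq_len(n)) {
    for (o in list(c(0, 1), c(1, 0))) {
      j <- look(coords[i, 1] + o[1], coords[i, 2] + o[2])
      if (j > 0) {
        adj[[i]] <- c(adj[[i]], j); wts[[i]] <- c(wts[[i]], 1)
        adj[[j]] <- c(adj[[j]], i); wts[[j]] <- c(wts[[j]], 1)
      }
    }
    for (o in list(c(1, 1), c(1, -1))) {
      j <- look(coords[i, 1] + o[1], coords[i, 2] + o[2])
      sh1 <- look(coords[i, 1] + o[1], coords[i, 2]) > 0
      sh2 <- look(coords[i, 1], coords[i, 2] + o[2]) > 0
      if (j > 0 && !sh1 && !sh2) {
        adj[[i]] <- c(adj[[i]], j); wts[[i]] <- c(wts[[i]], sqrt(2))
        adj[[j]] <- c(adj[[j]], i); wts[[j]] <- c(wts[[j]], sqrt(2))
      }
    }
  }
  deg <- lengths(adj)
  eps <- which(deg == 1)
  if (length(eps) < 2) return(NA_real_)
  best <- 0
  dfs <- function(v, target, visited, acc) {
    if (v == target) return(acc)
    for (k in seq_along(adj[[v]])) {
      u <- adj[[v]][k]
      if (!visited[u]) {
        r <- dfs(u, target, `[<-`(visited, u, TRUE), acc + wts[[v]][k])
        if (!is.na(r)) return(r)
      }
    }
    NA_real_
  }
  for (a in seq_along(eps)) for (b in seq_along(eps)) {
    if (b <= a) next
    visited <- rep(FALSE, n); visited[eps[a]] <- TRUE
    r <- dfs(eps[a], eps[b], visited, 0)
    if (!is.na(r) && r > best) best <- r
  }
  best
}

pathLengthOf <- function(path) {
  sum(sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2)))
}

rotatePts <- function(pts, thetaDeg, center = c(0, 0)) {
  th <- thetaDeg * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  sweep(sweep(pts, 2, center) %*% t(Rm), 2, center, `+`)
}
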