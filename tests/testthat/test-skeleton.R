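test_that("thinning reduces a bar to a line and a disk to its center", {
  bar <- matrix(FALSE, 20, 60)
  bar[8:12, 10:49] <- TRUE
  sk <- skeletonizeMask(bar)
  px <- which(sk, arr.ind = TRUE)
  expect_true(all(px[, 1] == 10))            # symmetric bar: center row
  expect_gte(nrow(px), 30)
  disk <- matrix(FALSE, 40, 40)
  disk[(row(disk) - 20)^2 + (col(disk) - 20)^2 <= 10^2] <- TRUE
  skd <- skeletonizeMask(disk)
  pd <- which(skd, arr.ind = TRUE)
  expect_true(all(sqrt((pd[, 1] - 20)^2 + (pd[, 2] - 20)^2) <= 1 + 1e-9))
  # multi-component mask refused with a pointer to the cleanup step
  two <- bar; two[2, 2] <- TRUE
  expect_error(skeletonizeMask(two), "cleanSmallParticles")
})

test_that("thinned sinusoidal worm stays within 1 px Hausdorff of the truth", {
  w <- suppressMessages(renderWorm(
    wormSpec("sine", lengthPx = 200, maxWidth = 10, amplitude = 20,
             periods = 1, frameDim = c(300L, 300L))))
  sk <- skeletonizeMask(w$mask)
  px <- which(sk, arr.ind = TRUE)
  tp <- w$truth$points
  d <- sqrt(outer(px[, 1], tp[, 1], `-`)^2 + outer(px[, 2], tp[, 2], `-`)^2)
  expect_lt(max(apply(d, 1, min)), 1.5)      # skeleton close to centerline
})

test_that("medial path equals exhaustive longest-endpoint-path search on random trees", {
  set.seed(23)
  for (rep in 1:40) {
    coords <- randomPixelTree(sample(15:60, 1))
    if (nrow(coords) < 5) next
    ref <- bruteForceLongestEndpointPath(coords)
    if (is.na(ref)) next
    path <- extractMedialPath(coords)
    expect_equal(pathLengthOf(path), ref, tolerance = 1e-9)
  }
})

test_that("medial path on simple shapes: identity, T-shape, deterministic ties", {
  # branchless open curve comes back endpoint to endpoint
  coords <- cbind(10, 5:25)
  p <- extractMedialPath(coords)
  expect_equal(nrow(p), 21L)
  expect_setequal(c(p[1, 2], p[nrow(p), 2]), c(5, 25))
  # T-shape: arms 30/25/10 -> path through the two longest arms
  tshape <- rbind(cbind(20, 10:40),    # horizontal bar through (20,10)-(20,40)
                  cbind(21:31, 25))    # stem of 11 below the bar
  pt <- extractMedialPath(tshape)
  expect_equal(pathLengthOf(pt), 30)   # 10..40 is the longest endpoint pair
  # Y with equal arms: deterministic lexicographic tie-break
  y1 <- extractMedialPath(rbind(cbind(10:20, 10), cbind(9 - (0:5), 10 + (0:5) * 0)))
  y2 <- extractMedialPath(rbind(cbind(10:20, 10), cbind(9 - (0:5), 10 + (0:5) * 0)))
  expect_identical(y1, y2)
  # cyclic input refused
  ring <- matrix(FALSE, 20, 20)
  ring[(row(ring) - 10)^2 + (col(ring) - 10)^2 <= 36 &
       (row(ring) - 10)^2 + (col(ring) - 10)^2 >= 16] <- TRUE
  ringSk <- skeletonizeMask(ring)
  expect_error(extractMedialPath(ringSk), "correctSelfTouching")
})

test_that("self-touch correction opens loops into branchless acyclic paths", {
  exs <- shapeExemplars()
  for (nm in c("six_shape", "o_shape")) {
    raw <- skeletonizeMask(exs[[nm]]$mask)
    g <- nemaquant:::.skeletonGraph(which(raw, arr.ind = TRUE))
    path <- correctSelfTouching(raw, exs[[nm]]$mask)
    # branchless and acyclic: a path visits distinct pixels in order
    expect_equal(anyDuplicated(paste(path[, 1], path[, 2])), 0L)
    steps <- sqrt(rowSums(diff(path)^2))
    expect_true(all(steps <= sqrt(2) + 1e-9))
    # covers at least the longest endpoint-to-endpoint path of the raw graph
    expect_gte(pathLengthOf(path) + 1e-9, nemaquant:::.maxEndpointDist(g))
  }
  # branchless input is returned unchanged (as a path)
  line <- cbind(5, 5:20)
  expect_equal(pathLengthOf(correctSelfTouching(line)), 15)
  expect_error(correctSelfTouching(cbind(5, 5)), "degenerate")
})

test_that("six-shape raw skeleton contains a cycle that correction removes", {
  ex <- shapeExemplars()$six_shape
  raw <- skeletonizeMask(ex$mask)
  g <- nemaquant:::.skeletonGraph(which(raw, arr.ind = TRUE))
  expect_gte(igraph::ecount(g), igraph::vcount(g))   # cyclic
  # correction yields an open simple path traversing stem and loop once:
  # distinct pixels, unit-or-diagonal steps, endpoints well apart
  path <- correctSelfTouching(raw, ex$mask)
  expect_equal(anyDuplicated(paste(path[, 1], path[, 2])), 0L)
  expect_true(all(sqrt(rowSums(diff(path)^2)) <= sqrt(2) + 1e-9))
  expect_gt(pathLengthOf(path), 0.85 * ex$truth$length)
})

test_that("full-ring skeleton opens into a path at least as long as cycle minus an arc", {
  # exhaustive check on a 40-node rectangular pixel ring (pure cycle)
  coords <- rbind(cbind(5, 5:15), cbind(6:14, 15), cbind(15, 15:5),
                  cbind(14:6, 5))
  coords <- unique(coords)
  g <- nemaquant:::.skeletonGraph(coords)
  expect_equal(igraph::ecount(g), igraph::vcount(g))   # one cycle
  path <- correctSelfTouching(coords)
  cyc <- sum(igraph::E(g)$weight)
  maxW <- max(igraph::E(g)$weight)
  # opening the ring at any single edge leaves cycle length minus that edge;
  # exhaustive edge-removal search gives the same optimum
  best <- max(vapply(seq_len(igraph::ecount(g)), function(e) {
    g2 <- igraph::delete_edges(g, e)
    nemaquant:::.maxEndpointDist(g2)
  }, numeric(1)))
  expect_gte(pathLengthOf(path) + 1e-9, cyc - maxW)
  expect_equal(pathLengthOf(path), best, tolerance = 1e-9)
})

test_that("spline resampling: straight paths, quarter circles, degenerate input", {
  p <- resampleSpline(cbind(50, 10:210), nPoints = 100L)
  pts <- skelPoints(p)
  expect_equal(nrow(pts), 100L)
  expect_lt(max(abs(pts[, 1] - 50)), 1e-6)
  expect_lt(max(abs(diff(diff(pts[, 2])))), 1e-6)  # equally spaced
  expect_equal(pixelLength(p), 200, tolerance = 0.01)
  # quarter circle radius 50: arc length within 2% of 25*pi
  th <- seq(0, pi / 2, length.out = 200)
  qc <- unique(round(cbind(60 - 50 * cos(th), 10 + 50 * sin(th))))
  ws <- resampleSpline(qc)
  expect_equal(pixelLength(ws), 25 * pi, tolerance = 0.02)
  expect_equal(nPoints(ws), 100L)   # default resolution
  expect_error(resampleSpline(cbind(1:3, 1:3)), "degenerate")
})

test_that("width profiles: uniform bar, linear taper, area consistency", {
  bar <- matrix(FALSE, 31, 120)
  bar[11:19, 10:109] <- TRUE                  # height 9 bar
  ws <- suppressMessages(maskToSkeleton(bar))
  wmid <- skelWidths(ws)[10:90]
  expect_true(all(abs(wmid - 9) <= 1.2))
  # tapered synthetic worm: monotone-ish profile tracking the truth
  w <- suppressMessages(renderWorm(
    wormSpec("straight", lengthPx = 200, maxWidth = 10, taper = 0.5,
             frameDim = c(300L, 300L))))
  wst <- suppressMessages(maskToSkeleton(w$mask))
  prof <- skelWidths(wst)
  truthW <- w$truth$widths
  expect_lt(mean(abs(prof[10:90] - truthW[10:90])), 1.5)
  expect_gt(cor(prof[5:95], truthW[5:95]), 0.9)
  # integral consistency: mean width x length ~ area within 10%
  expect_equal(mean(skelWidths(ws)) * pixelLength(ws), sum(bar),
               tolerance = 0.1)
})

test_that("constant-width worms have width CV below 10% away from the tips", {
  w <- suppressMessages(renderWorm(
    wormSpec("sine", lengthPx = 250, maxWidth = 12, taper = 0,
             amplitude = 20, periods = 1, frameDim = c(350L, 350L))))
  ws <- suppressMessages(maskToSkeleton(w$mask))
  core <- skelWidths(ws)[11:90]
  expect_lt(sd(core) / mean(core), 0.10)
})

test_that("morphometry: rectangle, disk, and power-law scaling across sizes", {
  rect <- matrix(FALSE, 40, 40); rect[11:20, 11:30] <- TRUE
  wsr <- suppressMessages(maskToSkeleton(rect))
  mo <- measureMorphometry(rect, wsr)
  expect_equal(mo$area_px, 200)
  expect_equal(mo$perimeter_px, 60, tolerance = 0.08)
  disk <- matrix(FALSE, 60, 60)
  disk[(row(disk) - 30)^2 + (col(disk) - 30)^2 <= 20^2] <- TRUE
  mod <- measureMorphometry(disk, WormSkeleton(rbind(c(30, 10), c(30, 50))))
  expect_equal(mod$area_px, 400 * pi, tolerance = 0.02)
  expect_equal(mod$perimeter_px, 40 * pi, tolerance = 0.05)
  # scale family: area ~ s^2, length ~ s
  feats <- lapply(c(0.5, 1, 2), function(s) {
    w <- suppressMessages(renderWorm(
      wormSpec("sine", lengthPx = 200 * s, maxWidth = 10 * s, amplitude = 20 * s,
               periods = 1, frameDim = c(round(300 * s + 60), round(300 * s + 60)))))
    ws <- suppressMessages(maskToSkeleton(w$mask))
    mo <- measureMorphometry(w$mask, ws)
    c(area = mo$area_px, len = mo$length_px)
  })
  expect_equal(feats[[3]]["len"] / feats[[1]]["len"], 4, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(feats[[3]]["area"] / feats[[1]]["area"], 16, tolerance = 0.12,
               ignore_attr = TRUE)
  # elongation sanity
  expect_gte(mo$length_px, 0)
})

test_that("resampled skeleton length tracks the generating centerline within 3%", {
  shapes <- list(
    wormSpec("straight", lengthPx = 300, maxWidth = 12, frameDim = c(400L, 400L)),
    wormSpec("sine", lengthPx = 300, maxWidth = 12, amplitude = 25,
             periods = 1.5, frameDim = c(400L, 400L)),
    wormSpec("arc", lengthPx = 200, maxWidth = 10, radius = 80,
             frameDim = c(400L, 400L))
  )
  for (sp in shapes) {
    w <- suppressMessages(renderWorm(sp))
    ws <- suppressMessages(maskToSkeleton(w$mask))
    expect_equal(pixelLength(ws), w$truth$length, tolerance = 0.03)
  }
})

test_that("skeleton CSV export is tidy and complete", {
  ex <- shapeExemplars()$straight
  tf <- tempfile(fileext = ".csv")
  writeSkeletonCSV(list(ex$skeleton), tf)
  df <- read.csv(tf)
  expect_equal(nrow(df), 100L)
  expect_named(df, c("frame", "point_index", "row", "col", "width"))
})
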