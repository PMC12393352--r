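test_that("crop window: arithmetic, symmetric drift, fixed size, clamping", {
  blob <- function(r, c, dim = c(512L, 512L)) {
    m <- matrix(FALSE, dim[1], dim[2]); m[r + (-2:2), c + (-2:2)] <- TRUE; m
  }
  win <- computeCropWindow(list(blob(256, 256)), size = 110)
  expect_equal(range(win$rows), c(201, 310))
  expect_equal(range(win$cols), c(201, 310))
  # symmetric drift averages back to the center
  drift <- lapply(c(-5, 0, 5), function(d) blob(100 + d, 100 - d))
  win2 <- computeCropWindow(drift, size = 40)
  expect_equal(as.numeric(win2$center), c(100, 100), tolerance = 1)
  expect_length(win2$rows, 40L)
  # clamped inside the frame near a border
  win3 <- computeCropWindow(list(blob(10, 10, dim = c(200L, 200L))), size = 110,
                            frameDim = c(200L, 200L))
  expect_gte(min(win3$rows), 1)
  expect_length(win3$rows, 110L)
  expect_error(computeCropWindow(list(matrix(FALSE, 10, 10))), "empty")
})

test_that("background sampling: exact on constant fields, bounded on noisy ones", {
  frame <- matrix(100, 200, 200)
  obj <- matrix(FALSE, 200, 200); obj[90:110, 90:110] <- TRUE
  frame[obj] <- 4000
  bg <- sampleBackground(frame, obj)
  expect_equal(as.numeric(bg), 100)
  expect_equal(attr(bg, "nUsed"), 100L)
  # gaussian noise: estimate within 3 standard errors
  set.seed(13)
  noisy <- matrix(100 + rnorm(200 * 200, 0, 5), 200, 200)
  noisy[obj] <- 4000
  bg2 <- sampleBackground(noisy, obj, seed = 21)
  expect_lt(abs(as.numeric(bg2) - 100), 3 * 5 / sqrt(100))
})

test_that("eligible background pixels match a brute-force distance check", {
  obj <- matrix(FALSE, 128, 128)
  obj[30:40, 30:40] <- TRUE; obj[90:95, 100:110] <- TRUE
  free <- matrix(as.numeric(!obj), 128, 128)
  dt <- EBImage::distmap(free)
  idx <- which(obj, arr.ind = TRUE)
  allPix <- expand.grid(r = 1:128, c = 1:128)
  bruteD <- sqrt(outer(allPix$r, idx[, 1], `-`)^2 +
                 outer(allPix$c, idx[, 2], `-`)^2)
  bruteMin <- matrix(apply(bruteD, 1, min), 128, 128)
  eligibleRef <- which(bruteMin >= 40 & !obj)
  eligibleGot <- which(dt >= 40 & !obj)
  # distance-to-pixel-center conventions may differ fractionally; the sets
  # must agree except possibly at the exact threshold boundary
  expect_gt(length(eligibleGot), 0)
  expect_lte(length(setdiff(eligibleGot, which(bruteMin >= 39 & !obj))), 0)
  expect_lte(length(setdiff(which(bruteMin >= 41 & !obj), eligibleGot)), 0)
  expect_gte(length(intersect(eligibleGot, eligibleRef)) /
             length(union(eligibleGot, eligibleRef)), 0.98)
})

test_that("background sampling degrades gracefully when few pixels qualify", {
  frame <- matrix(50, 60, 60)
  obj <- matrix(FALSE, 60, 60); obj[30, 30] <- TRUE
  bg <- suppressMessages(sampleBackground(frame, obj, nRegions = 100,
                                          minDistance = 25))
  expect_equal(as.numeric(bg), 50)
  # no pixel 100 px away in a 60x60 frame: distance requirement relaxes
  bg2 <- suppressMessages(sampleBackground(frame, obj, nRegions = 10,
                                           minDistance = 100))
  expect_false(is.null(attr(bg2, "relaxedTo")))
})

test_that("brightness extraction recovers programs, steps and flags overlaps", {
  prog <- cbind(nrD = rep(c(2000, 3000), each = 30),
                nrV = seq(1500, 2500, length.out = 60),
                loop = rep(1800, 60))
  fl <- renderFluorescence(prog, noiseSd = 0, background = 100, seed = 1)
  cm <- lapply(fl$masks, function(m) lapply(1:60, function(t) m))
  tr <- extractBrightness(fl$frames, cm)
  expect_s4_class(tr, "CompartmentTraces")
  expect_equal(correctedBrightness(tr), prog - 100, tolerance = 1e-9,
               ignore_attr = TRUE)
  # step preserved at the right frame, no flattening
  d <- diff(correctedBrightness(tr)[, "nrD"])
  expect_equal(which(abs(d) > 500), 30L)
  expect_equal(max(abs(d[-30])), 0, tolerance = 1e-9)
  # overlapping compartments are QC-flagged but still measured
  ov <- fl$masks
  ov$nrV <- ov$nrD
  qc <- qcMaskStream(lapply(1:60, function(t) ov$nrD),
                     siblingMasks = lapply(1:60, function(t) ov$nrV))
  expect_true(all(qc$overlapping))
  cm2 <- lapply(ov, function(m) lapply(1:60, function(t) m))
  tr2 <- extractBrightness(fl$frames, cm2)
  expect_false(anyNA(rawBrightness(tr2)))
})

test_that("noisy recovery stays within 3 sigma over root mask area", {
  prog <- cbind(nrD = 1500 + 500 * sin(2 * pi * (0:59) / 20),
                nrV = rep(2000, 60),
                loop = 1200 + 300 * cos(2 * pi * (0:59) / 15))
  sigma <- 5
  fl <- renderFluorescence(prog, noiseSd = sigma, background = 100, seed = 8)
  cm <- lapply(fl$masks, function(m) lapply(1:60, function(t) m))
  tr <- extractBrightness(fl$frames, cm, backgroundMode = "recording")
  err <- abs(correctedBrightness(tr) - (prog - 100))
  areas <- vapply(fl$masks, sum, numeric(1))
  bound <- 3 * sigma / sqrt(areas)
  okFrac <- mean(sweep(err, 2, bound, `<=`))
  expect_gte(okFrac, 0.99)
})

test_that("trace normalization: min-max, affine invariance, deltaF/F, constants", {
  expect_equal(normalizeTrace(c(100, 150, 200)), c(0, 0.5, 1))
  x <- c(3, 9, 4, 7, 1)
  expect_equal(normalizeTrace(2.5 * x + 11), normalizeTrace(x))
  expect_equal(as.numeric(normalizeTrace(c(100, 110, 120), method = "dff",
                                         f0Quantile = 0)), c(0, 0.1, 0.2))
  expect_warning(out <- normalizeTrace(rep(5, 10)), "constant")
  expect_true(all(out == 0))
})

test_that("mean absolute difference from mean: hand arithmetic and flattening", {
  expect_equal(meanAbsDiffFromMean(rep(7, 10)), 0)
  expect_equal(meanAbsDiffFromMean(c(1, 3)), 1)
  expect_equal(meanAbsDiffFromMean(c(0, 0, 4)), 16 / 9)
  # flattening excursions to baseline strictly lowers the statistic
  set.seed(19)
  baseline <- 100
  trace <- baseline + pmax(0, 80 * sin(2 * pi * (0:199) / 50)) + rnorm(200)
  flattened <- trace
  flattened[trace > baseline + 20] <- baseline
  expect_lt(meanAbsDiffFromMean(flattened), meanAbsDiffFromMean(trace))
})

test_that("head angle from body: straight zero, constructed 60 degrees, smoothing", {
  n <- 100
  straight <- WormSkeleton(cbind(0, seq(200, 1, length.out = n)))
  expect_equal(headAngleFromBody(list(straight, straight, straight)),
               rep(0, 3), tolerance = 1e-9)
  # anterior 30% rotated by 60 degrees
  na <- 30
  body <- cbind(0, seq(200, 1, length.out = n))
  bent <- body
  bent[1:(na - 1), ] <- rotatePts(body[1:(na - 1), , drop = FALSE], 60, body[na, ])
  a <- headAngleFromBody(list(WormSkeleton(bent)), smoothWindow = 1)
  expect_equal(abs(a), 60, tolerance = 3)
  # 3-frame moving average: [10, 40, 10] -> middle becomes 20
  mkAngled <- function(deg) {
    b <- body
    b[1:(na - 1), ] <- rotatePts(body[1:(na - 1), , drop = FALSE], deg, body[na, ])
    WormSkeleton(b)
  }
  sgn <- sign(headAngleFromBody(list(mkAngled(10)), smoothWindow = 1))
  sm <- headAngleFromBody(list(mkAngled(10), mkAngled(40), mkAngled(10)))
  expect_equal(sm[2], sgn * 20, tolerance = 1.5)
})

test_that("head angles are equivariant under global rotation", {
  seq1 <- crawlSequence()
  skels <- skeletonsFromCenterlines(seq1)[1:20]
  a1 <- headAngleFromBody(skels)
  rot <- lapply(skels, function(s)
    WormSkeleton(rotatePts(skelPoints(s), 73, c(50, 50))))
  a2 <- headAngleFromBody(rot)
  expect_equal(a2, a1, tolerance = 1e-6)
})

test_that("dorsoventral resolution: both mounting sides and mirror symmetry", {
  mkMask <- function(r, c) {
    m <- matrix(FALSE, 100, 100); m[r + (-1:1), c + (-1:1)] <- TRUE; m
  }
  angles <- c(10, -20, 15)
  axes <- matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE)  # anterior along +col
  # loop below nrD (larger row): cross(v, ax) with v = (dr>0, 0) -> dr*1 > 0
  loopA <- list(mkMask(60, 50), mkMask(60, 50), mkMask(60, 50))
  nrdA <- list(mkMask(40, 50), mkMask(40, 50), mkMask(40, 50))
  resA <- resolveDorsoventralSign(angles, loopA, nrdA, axes)
  # mirrored scene (loop above nrD): opposite side, negated angles
  resB <- resolveDorsoventralSign(angles, nrdA, loopA, axes)
  expect_false(resA$side == resB$side)
  expect_equal(resA$angles, -resB$angles)
  # single-frame evidence decides like the majority
  res1 <- resolveDorsoventralSign(angles, loopA[1], nrdA[1],
                                  axes[1, , drop = FALSE])
  expect_equal(res1$side, resA$side)
  # collinear centroids: indeterminate, flagged
  expect_warning(
    resC <- resolveDorsoventralSign(angles, list(mkMask(50, 70)),
                                    list(mkMask(50, 30)),
                                    matrix(c(0, 1), 1, 2)),
    "indeterminate")
  expect_true(is.na(resC$side))
})

test_that("ellipse estimates map linearly onto degrees and invert cleanly", {
  expect_equal(ellipseToDegrees(0), 0)
  expect_equal(ellipseToDegrees(1), 90)
  expect_equal(ellipseToDegrees(-1), -90)
  expect_equal(ellipseToDegrees(0.5), 45)
  v <- seq(-90, 90, by = 7.5)
  expect_equal(ellipseToDegrees(v / 90), v)
  expect_message(out <- ellipseToDegrees(c(1.2, -3)), "clamped")
  expect_equal(out, c(90, -90))
})

test_that("background estimator is unbiased across random layouts (Monte Carlo)", {
  errs <- vapply(1:50, function(i) {
    set.seed(100 + i)
    frame <- matrix(80, 150, 150)
    obj <- matrix(FALSE, 150, 150)
    for (k in 1:sample(1:3, 1)) {
      r <- sample(20:130, 1); c <- sample(20:130, 1)
      obj[r + (-4:4), c + (-4:4)] <- TRUE
    }
    frame[obj] <- 3000
    as.numeric(sampleBackground(frame, obj, seed = i)) - 80
  }, numeric(1))
  expect_equal(max(abs(errs)), 0)   # constant field: exact for every layout
})
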