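test_that("head assignment follows the mobile end through forward and backward bouts", {
  seq1 <- crawlSequence()
  skels <- skeletonsFromCenterlines(seq1)
  oriented <- assignHeadTail(skels)
  heads <- t(vapply(oriented, function(s) skelPoints(s)[1, ], numeric(2)))
  trueHeads <- cbind(seq1$truth$head_row, seq1$truth$head_col)
  acc <- mean(sqrt(rowSums((heads - trueHeads)^2)) < 10)
  expect_gte(acc, 0.95)
})

test_that("a static worm keeps a stable head assignment (no flips)", {
  sq <- sequenceSpec(motionProgram = data.frame(state = "stationary",
                                                duration = 30L, speed = 0),
                     headOscAmpDeg = 0, seed = 3L)
  seq0 <- renderSequence(sq, renderMasks = FALSE)
  skels <- skeletonsFromCenterlines(seq0)
  oriented <- assignHeadTail(skels)
  firstPts <- t(vapply(oriented, function(s) skelPoints(s)[1, ], numeric(2)))
  jumps <- sqrt(rowSums(diff(firstPts)^2))
  expect_lt(max(jumps), 1)    # never swaps end identity
})

test_that("an injected endpoint-order swap does not disturb orientation", {
  seq1 <- crawlSequence()
  skels <- skeletonsFromCenterlines(seq1)
  k <- 50L
  pts <- skelPoints(skels[[k]])
  skels[[k]] <- WormSkeleton(pts[nrow(pts):1, ], frameIndex = k - 1L)
  oriented <- correctHeadJumps(assignHeadTail(skels))
  heads <- t(vapply(oriented, function(s) skelPoints(s)[1, ], numeric(2)))
  trueHeads <- cbind(seq1$truth$head_row, seq1$truth$head_col)
  expect_gte(mean(sqrt(rowSums((heads - trueHeads)^2)) < 10), 0.95)
})

test_that("jump repair: identity without jumps, repairs a flip, spares omega turns", {
  seq1 <- crawlSequence()
  skels <- skeletonsFromCenterlines(seq1)
  oriented <- assignHeadTail(skels)
  expect_identical(lapply(correctHeadJumps(oriented), skelPoints),
                   lapply(oriented, skelPoints))
  # single-frame flip injected after orientation -> repaired
  flipped <- oriented
  k <- 60L
  pts <- skelPoints(flipped[[k]])
  flipped[[k]] <- WormSkeleton(pts[nrow(pts):1, ], frameIndex = k - 1L)
  repaired <- correctHeadJumps(flipped)
  expect_true(k %in% attr(repaired, "corrected"))
  expect_equal(skelPoints(repaired[[k]]), skelPoints(oriented[[k]]))
  # fast but continuous head path (omega-like sweep) is not falsely swapped
  sq <- sequenceSpec(motionProgram = data.frame(state = "forward",
                                                duration = 40L, speed = 2),
                     headOscAmpDeg = 65, headOscFreqHz = 1.5, seed = 5L)
  seqO <- renderSequence(sq, renderMasks = FALSE)
  orO <- assignHeadTail(skeletonsFromCenterlines(seqO))
  repO <- correctHeadJumps(orO)
  expect_length(attr(repO, "corrected"), 0L)
})

test_that("head-bend angle: straight zero, constructed 45 degrees, mirror antisymmetry", {
  straight <- WormSkeleton(cbind(50, seq(200, 10, length.out = 100)))
  expect_equal(headBendAngle(straight), 0, tolerance = 1e-6)
  # anterior 15% rotated by 45 degrees off a straight body
  n <- 100; nb <- 15
  body <- cbind(0, seq(170, 0, length.out = n))   # head at index 1
  base <- body[nb, ]
  bent <- body
  bent[1:(nb - 1), ] <- rotatePts(body[1:(nb - 1), , drop = FALSE], 45, base)
  a <- headBendAngle(WormSkeleton(bent))
  expect_equal(abs(a), 45, tolerance = 3)
  mirror <- bent %*% diag(c(-1, 1))
  am <- headBendAngle(WormSkeleton(mirror))
  expect_equal(am, -a, tolerance = 1e-6)
})

test_that("Savitzky-Golay smoothing: lines exact, noise halved, constants fixed", {
  n <- 80
  lin <- cbind(0.7 * (1:n) + 3, -0.2 * (1:n) + 50)
  expect_equal(smoothCentroid(lin), lin, tolerance = 1e-9, ignore_attr = TRUE)
  const <- cbind(rep(5, n), rep(9, n))
  expect_equal(smoothCentroid(const), const, tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(41)
  noisy <- lin + matrix(rnorm(2 * n), n, 2)
  sm <- smoothCentroid(noisy)
  rmsBefore <- sqrt(mean((noisy - lin)^2))
  rmsAfter <- sqrt(mean((sm - lin)^2))
  expect_lte(rmsAfter, 0.5 * rmsBefore)
  # short series shrinks the window instead of failing
  short <- lin[1:7, ]
  expect_silent(suppressMessages(smoothCentroid(short)))
})

test_that("motion classification: direction, threshold, perpendicular ties", {
  n <- 20
  cents <- cbind(rep(10, n), 10 + (0:(n - 1)) * 1)     # +1 px/frame along cols
  headsF <- cbind(rep(10, n), cents[, 2] + 30)         # head ahead
  expect_true(all(classifyMotion(cents, headsF) == "forward"))
  headsB <- cbind(rep(10, n), cents[, 2] - 30)         # head behind
  expect_true(all(classifyMotion(cents, headsB) == "backward"))
  slow <- cbind(rep(10, n), 10 + (0:(n - 1)) * 0.3)
  expect_true(all(classifyMotion(slow, headsF) == "stationary"))
  # velocity exactly perpendicular to the body axis -> stationary tie
  perp <- cbind(10 + (0:(n - 1)) * 1, rep(10, n))      # moving along rows
  headsP <- cbind(perp[, 1], perp[, 2] + 30)           # head along cols
  expect_true(all(classifyMotion(perp, headsP) == "stationary"))
})

test_that("context correction relabels blips and reaches a fixpoint", {
  expect_equal(correctMotionLabels(c("F", "F", "B", "F", "F")),
               rep("F", 5))
  alt <- rep(c("F", "B"), 10)
  expect_equal(correctMotionLabels(alt), alt)   # no flanking majority
  uni <- rep("S", 12)
  expect_identical(correctMotionLabels(uni), uni)
  # iterates to fixpoint across nested blips
  lab <- c(rep("F", 6), "B", "F", "B", rep("F", 6))
  expect_true(all(correctMotionLabels(lab) == "F"))
})

test_that("bouts and path summary satisfy the conservation identities", {
  labels <- c(rep("forward", 30), rep("stationary", 20),
              rep("backward", 10), rep("forward", 40))
  set.seed(2)
  cents <- cbind(cumsum(rnorm(100)), cumsum(rnorm(100)))
  bouts <- extractBouts(labels, cents)
  expect_equal(nrow(bouts), 4L)
  expect_equal(sum(bouts$duration_frames), 100L)
  expect_equal(bouts$duration_frames,
               bouts$end_frame - bouts$start_frame + 1L)
  expect_true(all(bouts$motion[-1] != bouts$motion[-nrow(bouts)]))
  summ <- summarizePath(labels, cents, bouts)
  expect_equal(summ$fraction_forward, 0.7)
  expect_equal(summ$fraction_forward + summ$fraction_backward +
               summ$fraction_stationary, 1, tolerance = 1e-12)
  expect_lte(summ$max_displacement_px, summ$total_path_length_px)
  expect_equal(summ$mean_forward_bout_frames, 35)
  expect_equal(summ$mean_backward_bout_frames, 10)
  # closed square path: total length 400, final displacement zero
  sq <- rbind(cbind(0:100, 0), cbind(100, 0:100), cbind(100:0, 100),
              cbind(0, 100:0))
  lab2 <- rep("forward", nrow(sq))
  s2 <- summarizePath(lab2, sq)
  expect_equal(s2$total_path_length_px, 400)
  expect_equal(s2$max_displacement_px, 100 * sqrt(2))
})

test_that("single-worm bout arithmetic: 100 forward frames give one bout", {
  cents <- cbind(1:100, rep(0, 100))
  b <- extractBouts(rep("forward", 100), cents)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_frames, 100L)
  expect_equal(b$distance_px, 99)
})

test_that("tracking outputs are invariant to global rotation and translation", {
  seq1 <- crawlSequence()
  skels <- skeletonsFromCenterlines(seq1)
  rotskels <- lapply(skels, function(s)
    WormSkeleton(rotatePts(skelPoints(s), 30, c(100, 100)) + 50,
                 frameIndex = frameIndex(s)))
  o1 <- correctHeadJumps(assignHeadTail(skels))
  o2 <- correctHeadJumps(assignHeadTail(rotskels))
  b1 <- vapply(o1, headBendAngle, numeric(1))
  b2 <- vapply(o2, headBendAngle, numeric(1))
  expect_equal(b2, b1, tolerance = 1e-6)
  c1 <- t(vapply(o1, function(s) colMeans(skelPoints(s)), numeric(2)))
  c2 <- t(vapply(o2, function(s) colMeans(skelPoints(s)), numeric(2)))
  d1 <- sqrt(rowSums(diff(c1)^2)); d2 <- sqrt(rowSums(diff(c2)^2))
  expect_equal(d2, d1, tolerance = 1e-6)
})
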