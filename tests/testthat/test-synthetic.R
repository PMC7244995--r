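# Synthetic finger-to-nose generator: determinism, severity monotonicity,
# rendering contracts, rater simulation.

test_that("a grade-0 trajectory is the exact straight-line interpolation", {
  spec <- trajectoryForGrade(0, nFrames = 20, startPoint = c(30, 58),
                             endPoint = c(18, 20))
  pts <- simulateTrajectory(spec, seed = 123)
  u <- seq(0, 1, length.out = 20)
  expected <- cbind(30 + u * (18 - 30), 58 + u * (20 - 58))
  expect_equal(pts, expected, tolerance = 1e-12)
  expect_equal(pts[20, ], c(18, 20)) # final point exactly at the nose
})

test_that("trajectories are pure functions of spec and seed", {
  spec <- trajectoryForGrade(3, nFrames = 25, startPoint = c(30, 58),
                             endPoint = c(18, 20))
  expect_identical(simulateTrajectory(spec, seed = 5),
                   simulateTrajectory(spec, seed = 5))
  expect_false(identical(simulateTrajectory(spec, seed = 5),
                         simulateTrajectory(spec, seed = 6)))
  expect_error(trajectorySpec(1, c(0, 0), c(1, 1)), "nFrames")
})

test_that("mean perpendicular path deviation increases strictly with grade", {
  start <- c(30, 58); end <- c(18, 20)
  devs <- sapply(0:4, function(g) {
    spec <- trajectoryForGrade(g, nFrames = 30, startPoint = start,
                               endPoint = end)
    mean(sapply(1:150, function(s)
      pathDeviation(simulateTrajectory(spec, seed = s), start, end)))
  })
  expect_equal(devs[1], 0)
  expect_true(all(diff(devs) > 0))
  # grade 4 clearly exceeds grade 1 on the same seeds
  expect_gt(devs[5], devs[2])
})

test_that("rendered frames satisfy the shape, range and controlled-difference contracts", {
  subj <- randomSubject("A", resolution = 32, seed = 1)
  f3 <- renderFrame(subj, c(20, 20), resolution = 32, channels = 3)
  f4 <- renderFrame(subj, c(20, 20), resolution = 32, channels = 4)
  expect_identical(dim(f3), c(32L, 32L, 3L))
  expect_identical(dim(f4), c(32L, 32L, 4L))
  # RGB planes identical; the 4th channel is the synthetic depth map
  expect_equal(f4[, , 1:3], f3[, , 1:3], tolerance = 1e-15,
               ignore_attr = TRUE)

  set.seed(2)
  for (i in 1:30) {
    s <- randomSubject(paste0("S", i), 32, seed = i)
    f <- renderFrame(s, runif(2, 0, 31), 32, sample(c(3, 4), 1))
    expect_true(all(f >= 0 & f <= 1))
  }

  # same fingertip, different background seed: only background pixels differ
  subj2 <- subj
  subj2@backgroundPatternSeed <- subj@backgroundPatternSeed + 1L
  g1 <- renderFrame(subj, c(20, 20), 32, 3)
  g2 <- renderFrame(subj2, c(20, 20), 32, 3)
  fg <- attr(g1, "foreground")
  expect_identical(attr(g2, "foreground"), fg)
  for (ch in 1:3) {
    expect_equal(g1[, , ch][fg], g2[, , ch][fg])
    expect_false(isTRUE(all.equal(g1[, , ch][!fg], g2[, , ch][!fg])))
  }

  expect_warning(renderFrame(subj, c(40, 40), 32, 3), "clipped")
})

test_that("videos are bitwise reproducible and carry their declared geometry", {
  spec <- syntheticVideoSpec("S1", grade = 2, resolution = 32, channels = 4,
                             nFrames = 6, seed = 77)
  v1 <- simulateVideo(spec)
  v2 <- simulateVideo(spec)
  expect_identical(v1$frames, v2$frames)
  expect_identical(dim(v1$frames), c(32L, 32L, 4L, 6L))
  expect_true(all(v1$frames >= 0 & v1$frames <= 1))
})

test_that("changing only the subject identity leaves the fingertip path unchanged", {
  base <- syntheticVideoSpec("S1", grade = 2, resolution = 32, nFrames = 8,
                             seed = 5)
  other_subj <- randomSubject("S2", 32, seed = 999)
  other_subj@noseTarget <- base@subject@noseTarget # same motion target
  modified <- base
  modified@subject <- other_subj
  p1 <- simulateTrajectory(base@trajectory, seed = base@seed)
  p2 <- simulateTrajectory(modified@trajectory, seed = modified@seed)
  expect_identical(p1, p2)
})

test_that("per-grade mean path deviation recomputed from stored specs is monotone", {
  ds <- simulateDataset(20, grades = 0:4, resolution = 32, nFrames = 10,
                        seed = 31)
  dev <- sapply(ds, function(v) {
    tr <- v$spec@trajectory
    pathDeviation(simulateTrajectory(tr, seed = v$spec@seed),
                  tr@startPoint, tr@endPoint)
  })
  grade <- sapply(ds, function(v) v$spec@grade)
  m <- tapply(dev, grade, mean)
  expect_true(all(diff(m) >= 0))
  expect_equal(unname(m[["0"]]), 0)
})

test_that("simulated raters reproduce the noiseless, boundary and perfect-agreement cases", {
  grades <- c(0L, 1L, 2L, 3L, 4L, 2L, 1L)
  clean <- lapply(1:2, function(j) raterModel(seed = j))
  tab <- simulateRatings(grades, clean)
  expect_identical(dim(ratings(tab)), c(7L, 2L))
  expect_equal(unname(ratings(tab)[, 1]), grades)
  expect_equal(unname(ratings(tab)[, 2]), grades)
  # two noiseless raters agree perfectly downstream
  k <- weightedKappa(ratings(tab)[, 1], ratings(tab)[, 2])
  expect_equal(kappaValue(k), 1)

  nr <- simulateRatings(grades, list(raterModel(notRatableProb = 1, seed = 1)))
  expect_true(all(is.na(ratings(nr))))

  noisy <- simulateRatings(grades, list(raterModel(miscodeSd = 2, seed = 3)))
  vals <- ratings(noisy)[!is.na(ratings(noisy))]
  expect_true(all(vals %in% 0:4)) # clipped to the grade range

  expect_error(simulateRatings(integer(), clean), "at least one")
  expect_error(simulateRatings(grades, list()), "at least one")
})

test_that("rating tables validate their contents", {
  expect_error(new("RatingTable", ratings = matrix(5L, 2, 2),
                   videoIds = c("a", "b"), raterIds = c("r1", "r2"),
                   condition = "original"), "0..4")
  expect_error(new("RatingTable", ratings = matrix(1L, 2, 2),
                   videoIds = c("a", "a"), raterIds = c("r1", "r2"),
                   condition = "original"), "unique")
})
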