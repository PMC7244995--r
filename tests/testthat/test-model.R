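# Architecture contracts, sampling, round trips, cosine distances.

test_that("block output shapes follow the halve-resolution / double-depth ladder", {
  cfg <- modelConfig(inputResolution = 256, inputChannels = 4)
  expect_equal(unname(blockOutputShape(cfg, 1)), c(128, 128, 8))
  expect_equal(unname(blockOutputShape(cfg, 2)), c(64, 64, 16))
  expect_equal(unname(blockOutputShape(cfg, 5)), c(8, 8, 128))
  cfg64 <- modelConfig(inputResolution = 64)
  expect_equal(unname(blockOutputShape(cfg64, 1)), c(32, 32, 8))
  expect_error(blockOutputShape(cfg, 6), "block_index")
  expect_error(blockOutputShape(cfg, 0), "block_index")
})

test_that("realized activation shapes match the ladder and the decoder mirrors it", {
  cfg <- tiny_config(resolution = 32, blocks = 3, filters = 4, code = 8)
  model <- createVAEModel(cfg, seed = 2)
  sh <- activationShapes(model)
  for (i in 1:3)
    expect_equal(as.integer(sh$encoder[[i]]),
                 as.integer(blockOutputShape(cfg, i)))
  # decoder output shapes mirror the encoder ladder in reverse
  expect_equal(sh$decoder[[3]][1:2], c(32L, 32L))
  expect_equal(sh$decoder[[3]][3], 3L)
  for (i in 1:2)
    expect_equal(sh$decoder[[i]][1:2],
                 as.integer(blockOutputShape(cfg, 3 - i))[1:2])
})

test_that("invalid model configurations are rejected", {
  expect_error(modelConfig(inputResolution = 48, nBlocks = 5), "divisible")
  expect_error(modelConfig(kernelSize = 4), "odd")
  expect_error(modelConfig(inputChannels = 2), "3")
})

test_that("encoding is deterministic and strictly per-frame", {
  cfg <- tiny_config()
  model <- createVAEModel(cfg, seed = 3)
  x <- random_frames(5, seed = 4)
  d1 <- encodeFrame(x, model)
  d2 <- encodeFrame(x, model)
  expect_identical(d1@mean, d2@mean)
  expect_identical(d1@logVariance, d2@logVariance)

  # permuting input frames permutes codes identically (no temporal context)
  perm <- c(3, 1, 5, 2, 4)
  cs <- encodeVideo(x, model)
  cs_perm <- encodeVideo(x[, , , perm], model)
  expect_equal(codeMatrix(cs_perm), codeMatrix(cs)[perm, ], tolerance = 1e-12)

  expect_error(encodeFrame(random_frames(1, res = 32), model),
               "does not match")
  expect_error(encodeVideo(list(), model), "empty")
})

test_that("code sampling follows the reparameterization and collapses to the mean", {
  set.seed(5)
  m <- matrix(rnorm(6), 1)
  lv <- matrix(rnorm(6), 1)
  dist <- new("LatentDistribution", mean = m, logVariance = lv)
  expect_equal(sampleCode(dist, deterministic = TRUE), as.numeric(m))
  # degenerate variances: code equals the mean for any seed
  dist0 <- new("LatentDistribution", mean = m,
               logVariance = matrix(-700, 1, 6))
  expect_equal(sampleCode(dist0, seed = 99), as.numeric(m), tolerance = 1e-12)
  # same seed -> same draw; different seed -> different draw
  expect_identical(sampleCode(dist, seed = 7), sampleCode(dist, seed = 7))
  expect_false(identical(sampleCode(dist, seed = 7), sampleCode(dist, seed = 8)))
})

test_that("reparameterized samples have the distribution's moments", {
  n <- 10000
  dist <- new("LatentDistribution", mean = matrix(0, n, 3),
              logVariance = matrix(0, n, 3))
  z <- sampleCode(dist, seed = 42)
  se_mean <- 1 / sqrt(n)
  se_var <- sqrt(2 / (n - 1))
  expect_true(all(abs(colMeans(z)) < 4 * se_mean))
  expect_true(all(abs(apply(z, 2, var) - 1) < 4 * se_var))
})

test_that("decode inverts shapes and enforces code length", {
  cfg <- tiny_config()
  model <- createVAEModel(cfg, seed = 6)
  x <- random_frames(3, seed = 7)
  dist <- encodeFrame(x, model)
  recon <- decodeCode(sampleCode(dist, deterministic = TRUE), model)
  expect_identical(dim(recon), dim(x))
  expect_true(all(recon >= 0 & recon <= 1))
  one <- decodeCode(rnorm(cfg@codeLength), model)
  expect_identical(dim(one), c(16L, 16L, 3L))
  expect_error(decodeCode(rnorm(5), model), "code length")
})

test_that("video round trip preserves counts, shapes and the header contract", {
  cfg <- tiny_config()
  model <- createVAEModel(cfg, seed = 8)
  x <- random_frames(7, seed = 9)
  cs <- encodeVideo(x, model)
  expect_identical(nFrames(cs), 7L)
  h <- codeHeader(cs)
  expect_identical(h$code_length, cfg@codeLength)
  expect_identical(h$model_fingerprint, modelFingerprint(model))
  y <- decodeVideo(cs, model)
  expect_identical(dim(y), dim(x))

  # a different model must refuse to decode these codes
  other <- createVAEModel(cfg, seed = 99)
  expect_error(decodeVideo(cs, other), "fingerprint mismatch")
})

test_that("model fingerprint tracks weights and survives checkpoints", {
  cfg <- tiny_config()
  model <- createVAEModel(cfg, seed = 10)
  fp <- modelFingerprint(model)
  tweaked <- model
  tweaked@params[[1]][1] <- tweaked@params[[1]][1] + 0.5
  expect_false(identical(modelFingerprint(tweaked), fp))

  path <- tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(modelFingerprint(back), fp)
  expect_identical(back@params, model@params)
})

test_that("latent cosine distance matches a direct recomputation and flags zero vectors", {
  set.seed(11)
  a <- rnorm(32)
  expect_equal(latentCosineDistance(a, a), 0, tolerance = 1e-12)
  expect_equal(latentCosineDistance(a, -a), 2, tolerance = 1e-12)
  for (i in 1:20) {
    u <- rnorm(16); v <- rnorm(16)
    expect_equal(latentCosineDistance(u, v),
                 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2)),
                 tolerance = 1e-12)
  }
  expect_error(latentCosineDistance(rep(0, 4), rnorm(4)), "zero vector")
  expect_error(latentCosineDistance(rnorm(3), rnorm(4)), "lengths differ")
})
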