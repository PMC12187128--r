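# WNet3D architecture, training loop, inference and checkpointing.

test_that("encoder emits a per-voxel distribution and the decoder reconstructs the input shape", {
  model <- buildWNet3D(tinyArch(), seed = 1L)
  v <- array(runif(16^3), dim = c(16L, 16L, 16L))
  fw <- forwardWNet3D(model, v)
  expect_identical(dim(fw$probs), c(2L, 16L, 16L, 16L))
  sums <- apply(fw$probs, 2:4, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  expect_identical(dim(fw$reconstruction), dim(v))
  # repeated forward passes are bit-identical
  expect_identical(forwardWNet3D(model, v), fw)
  expect_error(forwardWNet3D(model, array(runif(1000), c(10, 10, 10))),
               class = "wnet3d_bad_shape")
})

test_that("the trimmed 3-level network has fewer weights than a naive 4-level variant", {
  f3 <- c(64, 128, 256)
  n3 <- wnet3d:::unetParamCount(1, f3, 2)
  n4 <- wnet3d:::unetParamCount(1, c(f3, 512), 2)
  expect_lt(n3, n4)
  # the built model agrees with the closed-form count
  arch <- tinyArch()
  model <- buildWNet3D(arch, seed = 0L)
  expect_identical(countParameters(model),
                   wnet3d:::unetParamCount(1, c(8, 16, 32), 2) +
                     wnet3d:::unetParamCount(2, c(8, 16, 32), 1))
})

test_that("the combined loss is the stated weighted sum", {
  expect_equal(combinedLoss(1.0, 0.5, 1.0, 0.5), 1.25)
  expect_equal(combinedLoss(0.8, 123, 1, 0), 0.8)     # pure cuts limit
  expect_equal(combinedLoss(1.1, 0.3, 2, 0.4),
               2 * combinedLoss(1.1, 0.3, 1, 0.2))    # homogeneity
  expect_error(combinedLoss(1, 1, -1, 1), class = "wnet3d_bad_config")
})

test_that("training is deterministic under a fixed seed and reduces the objective", {
  vols <- lapply(1:2, function(s)
    generateNucleiVolume(microSynth(s))$volume)
  cfg <- tinyTrainConfig(epochs = 4L)
  m1 <- trainSelfSupervised(vols, cfg, tinyArch())
  m2 <- trainSelfSupervised(vols, cfg, tinyArch())
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@params, m2@params)
  h <- trainingHistory(m1)
  expect_identical(nrow(h), 4L)
  expect_true(all(is.finite(h$total)))
  expect_lt(h$total[4], h$total[1])
  expect_error(trainSelfSupervised(list(), cfg),
               class = "wnet3d_bad_input")
})

test_that("BCE reconstruction mode trains with finite losses", {
  vols <- list(generateNucleiVolume(microSynth(9L))$volume)
  cfg <- tinyTrainConfig(epochs = 2L)
  cfg@recLoss <- "BCE"
  m <- trainSelfSupervised(vols, cfg, tinyArch())
  expect_true(all(is.finite(trainingHistory(m)$total)))
})

test_that("an overwhelming reconstruction weight still yields finite, reconstruction-driven training", {
  vols <- list(generateNucleiVolume(microSynth(10L))$volume)
  cfg <- tinyTrainConfig(epochs = 4L)
  cfg@wRec <- 1e3
  m <- trainSelfSupervised(vols, cfg, tinyArch())
  h <- trainingHistory(m)
  expect_true(all(is.finite(h$total)))
  expect_lt(h$reconstruction[4], h$reconstruction[1])
})

test_that("sliding-window inference degenerates to a single forward pass and preserves shape", {
  model <- buildWNet3D(tinyArch(), seed = 2L)
  set.seed(77)
  # unit-scale input: the predictor's global min-max remap is then the
  # identity and must agree with a raw forward pass
  v <- remapIntensity(array(runif(16^3), dim = c(16L, 16L, 16L)), 0, 1)
  sw <- slidingWindowPredict(model, v, window = 16L)
  fw <- forwardWNet3D(model, v)
  expect_equal(sw, fw$probs, tolerance = 1e-12)
  # non-divisible volume is padded and cropped back
  v2 <- array(runif(20 * 18 * 25), dim = c(20L, 18L, 25L))
  sw2 <- slidingWindowPredict(model, v2, window = 16L)
  expect_identical(dim(sw2), c(2L, 20L, 18L, 25L))
  sums <- apply(sw2, 2:4, sum)
  expect_lt(max(abs(sums - 1)), 1e-4)
  # constant volume: probabilities nearly constant away from borders
  vc <- array(5, dim = c(16L, 16L, 16L))
  swc <- slidingWindowPredict(model, vc, window = 16L)
  core <- swc[1, 5:12, 5:12, 5:12]
  expect_lt(diff(range(core)), 1e-6)
  expect_error(slidingWindowPredict(model, v, window = 12L),
               class = "wnet3d_bad_shape")
})

test_that("checkpoints round-trip exactly and reject mismatched architectures", {
  dir <- withr::local_tempdir()
  vols <- list(generateNucleiVolume(microSynth(11L))$volume)
  m <- trainSelfSupervised(vols, tinyTrainConfig(epochs = 1L), tinyArch())
  p <- file.path(dir, "model.rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_identical(m2@params, m@params)
  expect_identical(trainingHistory(m2), trainingHistory(m))
  expect_identical(m2@trainConfig@seed, m@trainConfig@seed)
  v <- array(runif(16^3), dim = c(16L, 16L, 16L))
  expect_identical(forwardWNet3D(m2, v), forwardWNet3D(m, v))
  # checkpoint is self-describing: no external config needed, and a
  # conflicting requested architecture is rejected by name
  expect_error(loadModel(p, arch = wnetArchitecture(nClasses = 3L,
                                                    features = c(8L, 16L, 32L))),
               class = "wnet3d_config_mismatch")
  bad <- file.path(dir, "corrupt.rds")
  saveRDS(list(format = "something-else"), bad)
  expect_error(loadModel(bad), class = "wnet3d_corrupt_checkpoint")
  writeLines("junk", file.path(dir, "junk.rds"))
  expect_error(loadModel(file.path(dir, "junk.rds")),
               class = "wnet3d_corrupt_checkpoint")
})

test_that("the foreground class is the one tracking intensity", {
  d <- c(8L, 8L, 8L)
  v <- array(runif(prod(d)), dim = d)
  probs <- array(0, dim = c(2, d))
  probs[1, , , ] <- (1 - v) * 0.9 + 0.05
  probs[2, , , ] <- 1 - probs[1, , , ]
  expect_identical(selectForegroundClass(probs, v), 2L)
})
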