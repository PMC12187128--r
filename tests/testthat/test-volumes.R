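# Volume I/O, normalization, patching and augmentation.

test_that("TIFF round-trips are exact for integer data and shapes follow the (Z,Y,X) convention", {
  dir <- withr::local_tempdir()
  lab <- array(sample(0:300, 5 * 16 * 16, replace = TRUE),
               dim = c(5L, 16L, 16L))
  p <- file.path(dir, "lab.tif")
  writeVolume(lab, p)
  back <- readVolume(p)
  expect_identical(dim(back), dim(lab))
  expect_true(all(back == lab))
  expect_gte(max(back), 256)          # needed >= 16-bit samples

  # single page promotes to (1, Y, X)
  one <- array(seq_len(12), dim = c(1L, 3L, 4L))
  p1 <- file.path(dir, "one.tif")
  writeVolume(one, p1)
  expect_identical(dim(readVolume(p1)), c(1L, 3L, 4L))

  # float volumes on the [0,1] disk scale round-trip to float32 precision
  v <- array(runif(4 * 8 * 8), dim = c(4L, 8L, 8L))
  pf <- file.path(dir, "f.tif")
  writeVolume(v, pf)
  expect_lt(max(abs(readVolume(pf) - v)), 1e-6)
})

test_that("I/O failures raise distinct named conditions", {
  dir <- withr::local_tempdir()
  expect_error(readVolume(file.path(dir, "nope.tif")),
               class = "wnet3d_missing_file")
  txt <- file.path(dir, "not_an_image.tif")
  writeLines("plain text", txt)
  expect_error(readVolume(txt), class = "wnet3d_not_an_image")
  rgb <- file.path(dir, "rgb.tif")
  tiff::writeTIFF(array(runif(48), dim = c(4, 4, 3)), rgb)
  expect_error(readVolume(rgb), class = "wnet3d_multichannel")
  expect_error(writeVolume(array(1, c(2, 2, 2)),
                           file.path(dir, "no/such/dir/x.tif")),
               class = "wnet3d_unwritable")
  expect_error(writeVolume(array(numeric(0), c(0, 2, 2)),
                           file.path(dir, "empty.tif")),
               class = "wnet3d_bad_volume")
  expect_error(writeVolume(array(runif(8) * 10, c(2, 2, 2)),
                           file.path(dir, "range.tif")),
               class = "wnet3d_float_range")
})

test_that("remapIntensity maps extremes exactly and is the stated affine formula", {
  v <- array(runif(60, 10, 20), dim = c(3, 4, 5))
  r <- remapIntensity(v)
  expect_equal(min(r), 0, tolerance = 1e-12)
  expect_equal(max(r), 100, tolerance = 1e-12)
  expect_equal(r, (v - min(v)) * 100 / diff(range(v)), tolerance = 1e-12)
  # constant volume maps to all-lo
  expect_true(all(remapIntensity(array(7, c(2, 2, 2))) == 0))
  expect_error(remapIntensity(v, 5, 5), class = "wnet3d_bad_range")
  v[1] <- NA
  expect_error(remapIntensity(v), class = "wnet3d_nonfinite")
})

test_that("percentileClipNormalize clips exactly at interpolated order statistics", {
  ramp <- array(0:99, dim = c(100, 1, 1))
  out <- percentileClipNormalize(ramp, 1, 99)
  q <- quantile(0:99, c(0.01, 0.99), names = FALSE)   # brute oracle
  expect_equal(min(out), q[1])
  expect_equal(max(out), q[2])
  inside <- ramp > q[1] & ramp < q[2]
  expect_equal(out[inside], ramp[inside])
  # already-inside volume unchanged
  v <- array(runif(1000, 0.4, 0.6), dim = c(10, 10, 10))
  expect_equal(percentileClipNormalize(v, 0, 100), v)
  # one extreme outlier is pulled to the upper percentile value
  v2 <- array(runif(100), dim = c(100, 1, 1))
  v2[50] <- 1e6
  out2 <- percentileClipNormalize(v2)
  expect_equal(max(out2), quantile(v2, 0.99, names = FALSE))
})

test_that("extractPatches tiles exactly and covers every voxel", {
  v <- array(runif(128^2 * 8) , dim = c(8L, 128L, 128L))
  expect_error(extractPatches(v, 64),
               class = "wnet3d_bad_patch")       # Z too small, no padding
  v <- array(seq_len(64^3) %% 97, dim = c(64L, 64L, 64L))
  p <- extractPatches(v, 64L)
  expect_length(p, 1L)
  expect_identical(p[[1]]$volume, v)
  v2 <- array(runif(128^3 / 8), dim = c(64L, 64L, 64L))
  dim(v2) <- c(64L, 64L, 64L)
  big <- array(runif(100^3), dim = c(100L, 100L, 100L))
  patches <- extractPatches(big, 64L)
  expect_length(patches, 8L)                     # 2 windows per axis
  visit <- array(0L, dim = dim(big))
  for (pp in patches) {
    expect_identical(dim(pp$volume), c(64L, 64L, 64L))
    o <- pp$origin
    visit[o[1]:(o[1] + 63), o[2]:(o[2] + 63), o[3]:(o[3] + 63)] <-
      visit[o[1]:(o[1] + 63), o[2]:(o[2] + 63), o[3]:(o[3] + 63)] + 1L
    expect_identical(pp$volume,
                     big[o[1]:(o[1] + 63), o[2]:(o[2] + 63),
                         o[3]:(o[3] + 63)])
  }
  expect_true(all(visit >= 1L))
  # paired labels are cut at identical coordinates
  lab <- array(sample(0:5, 100^3, TRUE), dim = dim(big))
  pl <- extractPatches(big, 64L, labels = lab)
  o <- pl[[3]]$origin
  expect_identical(pl[[3]]$labels,
                   lab[o[1]:(o[1] + 63), o[2]:(o[2] + 63),
                       o[3]:(o[3] + 63)])
})

test_that("self-supervised augmentation is seeded, histogram-preserving and flips are involutions", {
  v <- array(runif(16^3), dim = c(16L, 16L, 16L))
  lab <- array(sample(0:3, 16^3, TRUE), dim = dim(v))
  a1 <- augmentVolume(v, lab, mode = "selfsup", seed = 11L)
  a2 <- augmentVolume(v, lab, mode = "selfsup", seed = 11L)
  expect_identical(a1, a2)
  # voxel-value multiset preserved exactly
  expect_identical(sort(as.numeric(a1$volume)), sort(as.numeric(v)))
  expect_identical(sort(as.integer(a1$labels)), sort(as.integer(lab)))
  expect_true(all(a1$labels == round(a1$labels)))
  # geometric transform applied identically to volume and labels:
  # voxel-wise pairing between intensity and label is preserved
  key <- function(vol, l) paste(round(vol, 10), l)
  expect_setequal(unique(key(a1$volume, a1$labels)), unique(key(v, lab)))
  # a flip applied twice is the identity
  f <- wnet3d:::flipAxis
  for (ax in 1:3) expect_identical(f(f(v, ax), ax), v)
})

test_that("supervised augmentation keeps labels integral and changes intensities", {
  v <- array(runif(16^3), dim = c(16L, 16L, 16L))
  lab <- array(sample(0:3, 16^3, TRUE), dim = dim(v))
  a <- augmentVolume(v, lab, mode = "supervised", seed = 5L)
  expect_identical(dim(a$volume), dim(v))
  expect_true(all(a$labels == round(a$labels)))
  expect_false(identical(a$volume, v))   # warp + intensity shift applied
})
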