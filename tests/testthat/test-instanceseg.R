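# Thresholding, labelling methods and post-processing operators.

test_that("probability thresholding is strict, monotone and validated", {
  set.seed(8)
  d <- c(6L, 6L, 6L)
  probs <- randomProbs(d)
  expect_identical(thresholdProbabilities(probs, 2, 0),
                   array(probs[2, , , ] > 0, dim = d))
  expect_false(any(thresholdProbabilities(probs, 2, 1)))
  t1 <- thresholdProbabilities(probs, 2, 0.3)
  t2 <- thresholdProbabilities(probs, 2, 0.7)
  expect_true(all(t1[t2]))                     # mask(t2) subset mask(t1)
  expect_error(thresholdProbabilities(probs, 3, 0.5),
               class = "wnet3d_bad_class")
})

test_that("Otsu equals the exhaustive 256-bin search and transforms affinely", {
  set.seed(13)
  for (rep in 1:5) {
    v <- array(c(rnorm(400, 25, 6), rnorm(600, 70, 9)),
               dim = c(10, 10, 10))
    expect_equal(otsuThreshold(v), bfOtsu(v), tolerance = 1e-9)
    # affine invariance up to the same rescaling
    expect_equal(otsuThreshold(v * 3 + 11), otsuThreshold(v) * 3 + 11,
                 tolerance = 1e-6)
  }
  bi <- array(rep(c(0, 100), each = 500), dim = c(10, 10, 10))
  t <- otsuThreshold(bi)
  expect_gt(t, 0); expect_lt(t, 100)
  expect_error(otsuThreshold(array(5, c(3, 3, 3))),
               class = "wnet3d_constant_volume")
})

test_that("Voronoi-Otsu separates well-separated nuclei and handles degenerate input", {
  gv <- generateNucleiVolume(synthConfig(seed = 5L))   # 30 nuclei
  inst <- voronoiOtsuLabel(gv$volume, 0.65, 0.65)
  expect_true(abs(max(inst) - 30) <= 1)
  # each true nucleus core is covered by exactly one predicted label
  m <- matchAtThreshold(iouMatrix(inst, gv$labels), 0.1)
  expect_gte(m@tp, 29L)
  # two isolated bright spheres -> exactly two labels
  d <- c(24L, 24L, 24L)
  v <- array(0.05, dim = d)
  v[sphereMask(d, c(7, 7, 7), 3)] <- 0.9
  v[sphereMask(d, c(17, 17, 17), 3)] <- 0.9
  expect_identical(max(voronoiOtsuLabel(v, 1, 1)), 2L)
  # all-dark volume with one faint flat region: no seeds above the mask
  flat <- array(0, dim = d); flat[1:3, 1:3, 1:3] <- 1e-4
  expect_true(all(voronoiOtsuLabel(flat, 1, 1) %in% 0:1))
  # seed count is non-increasing in spot sigma
  nSeeds <- vapply(c(0.5, 1, 2, 4), function(s)
    max(voronoiOtsuLabel(gv$volume, s, 0.65)), integer(1))
  expect_true(all(diff(nSeeds) <= 0))
})

test_that("connected components agree with brute-force flood fill under 26-connectivity", {
  set.seed(17)
  for (rep in 1:8) {
    mask <- array(runif(1000) < 0.2, dim = c(10, 10, 10))
    expect_identical(max(connectedComponentsLabel(mask)),
                     bfComponentCount(mask))
  }
  # diagonal-touching voxels are one component
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_identical(max(connectedComponentsLabel(m)), 1L)
  # two disjoint cubes
  m2 <- array(FALSE, c(8, 8, 8))
  m2[1:2, 1:2, 1:2] <- TRUE; m2[6:8, 6:8, 6:8] <- TRUE
  expect_identical(max(connectedComponentsLabel(m2)), 2L)
})

test_that("watershed splits a dumbbell and exactly partitions the mask", {
  d <- c(20L, 20L, 40L)
  mask <- sphereMask(d, c(10, 10, 14), 6) | sphereMask(d, c(10, 10, 26), 6)
  ws <- watershedLabel(mask)
  expect_identical(max(ws), 2L)
  expect_identical(ws > 0, mask)               # union = mask
  # split near the neck: the two spheres' centres get different labels
  expect_false(ws[10, 10, 14] == ws[10, 10, 26])
  # single sphere -> one label
  one <- watershedLabel(sphereMask(d, c(10, 10, 20), 5))
  expect_identical(max(one), 1L)
  expect_identical(max(watershedLabel(array(FALSE, c(4, 4, 4)))), 0L)
})

test_that("ball closing matches the dilate-then-erode oracle and fills holes", {
  cube <- array(FALSE, c(12L, 12L, 12L))
  cube[3:10, 3:10, 3:10] <- TRUE
  cube[6, 6, 6] <- FALSE
  cl <- morphologicalClosing(cube, 2)
  expect_true(cl[6, 6, 6])
  expect_identical(morphologicalClosing(cube, 0), cube)
  set.seed(23)
  for (rep in 1:3) {
    m <- array(runif(512) < 0.3, dim = c(8L, 8L, 8L))
    for (r in 1:2)
      expect_identical(morphologicalClosing(m, r),
                       bfBallErode(bfBallDilate(m, r), r))
  }
})

test_that("border-intensity merging follows the [lo,hi] rule, adjacency and transitivity", {
  d <- c(4L, 12L, 4L)
  lab <- array(0L, dim = d)
  lab[, 1:4, ] <- 1L; lab[, 5:8, ] <- 2L; lab[, 9:12, ] <- 3L
  volHi <- array(50, dim = d)
  merged <- mergeLabelsByBorderIntensity(lab, volHi)
  expect_identical(max(merged), 1L)           # transitive merge of 1-2-3
  expect_identical(merged > 0, lab > 0)       # support unchanged
  volLo <- array(10, dim = d)
  expect_identical(mergeLabelsByBorderIntensity(lab, volLo), lab)
  # mixed: only the 1|2 border is in range
  volMix <- array(10, dim = d)
  volMix[, 4:5, ] <- 60
  m2 <- mergeLabelsByBorderIntensity(lab, volMix)
  expect_identical(max(m2), 2L)
  expect_identical(unique(as.integer(m2[, 1:8, ])), 1L)
  # non-touching labels never merge
  gap <- array(0L, dim = d)
  gap[, 1:3, ] <- 1L; gap[, 9:12, ] <- 2L
  expect_identical(mergeLabelsByBorderIntensity(gap, volHi), gap)
  expect_error(mergeLabelsByBorderIntensity(lab, volHi[, 1:6, ]),
               class = "wnet3d_shape_mismatch")
})

test_that("size filtering removes out-of-range labels and matches histogram counting", {
  d <- c(10L, 10L, 10L)
  lab <- array(0L, dim = d)
  lab[1:2, 1:2, 1] <- 1L                       # 4-voxel speck
  lab[5:9, 5:9, 5:9] <- 2L                     # 125-voxel object
  f <- filterByVolume(lab, minVoxels = 10)
  expect_false(any(f == lab & lab == 1L & f > 0))
  expect_identical(sort(unique(as.integer(f))), c(0L, 1L))
  expect_identical(filterByVolume(lab, 0, Inf), lab)
  set.seed(31)
  for (rep in 1:5) {
    rl <- connectedComponentsLabel(array(runif(1000) < 0.25,
                                         dim = c(10, 10, 10)))
    counts <- tabulate(rl[rl > 0])
    expected <- sum(counts >= 3 & counts <= 20)
    out <- filterByVolume(rl, 3, 20)
    expect_identical(max(out), expected)
  }
  expect_error(filterByVolume(lab, 5, 2), class = "wnet3d_bad_config")
})

test_that("labelling output support never exceeds the input foreground", {
  gv <- generateNucleiVolume(tinySynth(3L))
  inst <- voronoiOtsuLabel(gv$volume, 0.65, 0.65)
  smoothed <- gaussianSmooth3D(gv$volume, 0.65)
  expect_true(all(smoothed[inst > 0] > otsuThreshold(smoothed)))
  mask <- gv$volume > otsuThreshold(gv$volume)
  expect_true(all(mask[connectedComponentsLabel(mask) > 0]))
  expect_true(all(mask[watershedLabel(mask) > 0]))
})
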