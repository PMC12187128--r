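# Instance matching and the metric suite.

twoBlobMaps <- function() {
  d <- c(10L, 10L, 10L)
  gt <- array(0L, dim = d)
  gt[2:4, 2:4, 2:4] <- 1L
  gt[6:9, 6:9, 6:9] <- 2L
  pred <- array(0L, dim = d)
  pred[2:4, 2:4, 2:4] <- 5L         # non-consecutive labels allowed
  pred[6:9, 6:9, 6:8] <- 9L
  list(pred = pred, gt = gt)
}

test_that("iouMatrix equals brute-force per-pair set computation", {
  set.seed(21)
  for (rep in 1:10) {
    d <- c(8L, 8L, 8L)
    pred <- array(sample(0:4, prod(d), TRUE), dim = d)
    gt <- array(sample(0:4, prod(d), TRUE), dim = d)
    expect_equal(unname(iouMatrix(pred, gt)), bfIoU(pred, gt),
                 tolerance = 1e-12)
  }
  m <- twoBlobMaps()
  iou <- iouMatrix(m$pred, m$gt)
  expect_identical(rownames(iou), c("5", "9"))
  expect_equal(iou["5", "1"], 1)
  expect_error(iouMatrix(m$pred, m$gt[1:5, , ]),
               class = "wnet3d_shape_mismatch")
})

test_that("matchAtThreshold equals exhaustive optimal assignment on random pairs", {
  set.seed(33)
  for (rep in 1:50) {
    np <- sample(1:5, 1); ng <- sample(1:5, 1)
    iou <- matrix(runif(np * ng) * 0.95, np, ng)
    for (tau in c(0.1, 0.5, 0.9)) {
      m <- matchAtThreshold(iou, tau)
      expect_identical(m@tp, bfMatchTP(iou, tau))
      expect_identical(m@fp, np - m@tp)
      expect_identical(m@fn, ng - m@tp)
    }
  }
  # trivial cases
  m <- twoBlobMaps()
  perfect <- matchAtThreshold(iouMatrix(m$gt, m$gt), 0.5)
  expect_identical(c(perfect@tp, perfect@fp, perfect@fn), c(2L, 0L, 0L))
  empty <- matchAtThreshold(iouMatrix(array(0L, dim(m$gt)), m$gt), 0.5)
  expect_identical(c(empty@tp, empty@fp, empty@fn), c(0L, 0L, 2L))
})

test_that("F1/precision/recall formulas and conventions", {
  c1 <- c(tp = 3, fp = 1, fn = 2)
  expect_equal(f1FromCounts(c1), 2 * 3 / (2 * 3 + 1 + 2))
  expect_equal(precisionFromCounts(c1), 0.75)
  expect_equal(recallFromCounts(c1), 0.6)
  expect_equal(f1FromCounts(c(tp = 4, fp = 0, fn = 0)), 1)
  expect_equal(f1FromCounts(c(tp = 0, fp = 2, fn = 1)), 0)
  expect_equal(f1FromCounts(c(tp = 0, fp = 0, fn = 0)), 1)  # both empty
})

test_that("the F1 curve is non-increasing, symmetric up to precision/recall swap, and steps where IoU dictates", {
  set.seed(44)
  for (rep in 1:5) {
    d <- c(12L, 12L, 12L)
    gt <- array(0L, dim = d)
    pred <- array(0L, dim = d)
    for (k in 1:4) {
      c1 <- sample(3:10, 3, TRUE)
      gt[sphereMask(d, c1, 2)] <- k
      pred[sphereMask(d, c1 + sample(-1:1, 3, TRUE), 2)] <- k
    }
    cv <- f1Curve(pred, gt)
    expect_true(all(diff(cv$f1) <= 1e-12))
    sw <- f1Curve(gt, pred)
    expect_equal(sw$f1, cv$f1)
    expect_equal(sw$precision, cv$recall)
    expect_equal(sw$recall, cv$precision)
  }
  # one object with IoU 0.45 counts only below tau = 0.45
  d <- c(6L, 6L, 20L)
  gt <- array(0L, dim = d); gt[2:5, 2:5, 1:10] <- 1L
  pred <- array(0L, dim = d); pred[2:5, 2:5, 4:16] <- 1L
  iou <- iouMatrix(pred, gt)[1, 1]
  expect_equal(iou, 7 / 16, tolerance = 1e-12)   # ~0.44
  cv <- f1Curve(pred, gt)
  expect_true(all(cv$f1[cv$threshold < iou] == 1))
  expect_true(all(cv$f1[cv$threshold >= iou] == 0))
  expect_equal(meanF1(cv), mean(cv$f1))
  # identical maps: all ones
  cv1 <- f1Curve(gt, gt)
  expect_true(all(cv1$f1 == 1))
  expect_equal(attr(cv1, "meanF1"), 1)
})

test_that("semantic Dice matches the voxelwise F1 identity and conventions", {
  d <- c(8L, 8L, 8L)
  a <- sphereMask(d, c(4, 4, 4), 3)
  b <- sphereMask(d, c(4, 4, 5), 3)
  tp <- sum(a & b); fp <- sum(!a & b); fn <- sum(a & !b)
  expect_equal(semanticDice(b, a),
               f1FromCounts(c(tp = tp, fp = fp, fn = fn)))
  expect_equal(semanticDice(a, a), 1)
  expect_equal(semanticDice(a, array(FALSE, d)), 0)
  expect_equal(semanticDice(array(FALSE, d), array(FALSE, d)), 1)
  # half-overlapping equal-size boxes
  x <- array(FALSE, d); y <- array(FALSE, d)
  x[1:4, 1:4, 1:4] <- TRUE
  y[1:4, 1:4, 3:6] <- TRUE
  expect_equal(semanticDice(x, y), 0.5)
})

test_that("findBestThreshold returns the grid argmax, lowest on ties, averaged across pairs", {
  d <- c(6L, 6L, 6L)
  ref <- sphereMask(d, c(3, 3, 3), 2)
  # unimodal Dice by construction: probabilities decay with distance
  g <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  p <- array(exp(-rowSums(sweep(g, 2, c(3, 3, 3))^2) / 8), dim = d)
  probs <- array(0, dim = c(2, d))
  probs[2, , , ] <- p; probs[1, , , ] <- 1 - p
  grid <- seq(0, 1, by = 0.05)
  dice <- vapply(grid, function(t) semanticDice(p > t, ref), numeric(1))
  expect_equal(findBestThreshold(probs, ref), grid[which.max(dice)])
  # binary probabilities equal to the labels: Dice is 1 for every
  # threshold below 1, so the tie-break returns the lowest grid point
  pb <- array(0, dim = c(2, d))
  pb[2, , , ] <- as.numeric(ref); pb[1, , , ] <- 1 - as.numeric(ref)
  expect_equal(findBestThreshold(pb, ref), 0)
  # two pairs average their per-pair optima
  expect_equal(findBestThreshold(list(probs, pb), list(ref, ref)),
               mean(c(grid[which.max(dice)], 0)))
  expect_error(findBestThreshold(list(), list()),
               class = "wnet3d_bad_input")
})
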