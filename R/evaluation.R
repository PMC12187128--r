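# Instance-matching evaluation: pairwise IoU, optimal one-to-one
# matching at an IoU threshold, precision/recall/F1, the F1-vs-IoU
# curve, semantic Dice, and Dice-maximizing threshold search.

#' @title Matching counts at an IoU threshold
#'
#' @description True/false positives and false negatives from a
#' one-to-one matching of predicted to ground-truth instances; pairs
#' count as true positives when their IoU is strictly greater than the
#' threshold.
#'
#' @slot tp,fp,fn non-negative integer counts.
#' @slot iouThreshold the threshold used.
#' @slot matchedIoU IoU values of the matched (true positive) pairs.
#' @export
setClass("MatchCounts",
         representation(tp = "integer", fp = "integer", fn = "integer",
                        iouThreshold = "numeric", matchedIoU = "numeric"),
         validity = function(object) {
           if (object@tp < 0 || object@fp < 0 || object@fn < 0)
             "counts must be non-negative" else TRUE
         })

setMethod("show", "MatchCounts", function(object) {
  cat(sprintf("MatchCounts @ IoU > %.2f: TP %d, FP %d, FN %d (F1 %.4f)\n",
              object@iouThreshold, object@tp, object@fp, object@fn,
              f1FromCounts(object)))
})

#' Pairwise IoU table between two instance maps
#'
#' Entry (i, j) is `|pred_i intersect gt_j| / |pred_i union gt_j|` at
#' voxel level; background (label 0) is excluded. Row and column names
#' carry the original label values.
#'
#' @param pred,gt Integer 3D instance maps of identical shape.
#' @return A numeric matrix (rows = predicted labels, columns =
#'   ground-truth labels); 0 x 0 when a side has no instances.
#' @export
iouMatrix <- function(pred, gt) {
  assertInstanceMap(pred, name = "pred")
  assertInstanceMap(gt, name = "gt")
  if (!identical(dim(pred), dim(gt)))
    wnStop("wnet3d_shape_mismatch", "instance map shapes differ")
  pl <- sort(unique(pred[pred > 0]))
  gl <- sort(unique(gt[gt > 0]))
  m <- matrix(0, length(pl), length(gl),
              dimnames = list(as.character(pl), as.character(gl)))
  if (!length(pl) || !length(gl)) return(m)
  sel <- pred > 0 & gt > 0
  inter <- table(factor(pred[sel], levels = pl),
                 factor(gt[sel], levels = gl))
  sizeP <- tabulate(pred[pred > 0], nbins = max(pl))[pl]
  sizeG <- tabulate(gt[gt > 0], nbins = max(gl))[gl]
  un <- outer(sizeP, sizeG, `+`) - inter
  m[] <- as.numeric(inter) / as.numeric(un)
  m
}

#' Optimal one-to-one matching at an IoU threshold
#'
#' Computes the assignment maximizing first the number of pairs with
#' IoU strictly greater than `tau`, then the total IoU, so that no two
#' predictions share a ground-truth instance (and vice versa). Solved
#' as a linear assignment problem.
#'
#' @param ious An IoU matrix from [iouMatrix()] (rows = predictions).
#' @param tau IoU threshold in \[0, 1).
#' @return A [MatchCounts-class].
#' @export
matchAtThreshold <- function(ious, tau) {
  if (tau < 0 || tau >= 1)
    wnStop("wnet3d_bad_config", "tau must be in [0, 1)")
  np <- nrow(ious); ng <- ncol(ious)
  if (np == 0L || ng == 0L)
    return(new("MatchCounts", tp = 0L, fp = np, fn = ng,
               iouThreshold = tau, matchedIoU = numeric()))
  benefit <- (ious > tau) * 1e6 + ious
  flip <- np > ng
  cost <- if (flip) -t(benefit) else -benefit
  assign <- cpp_hungarian(cost)
  pairs <- cbind(seq_along(assign), assign)
  if (flip) pairs <- pairs[, 2:1, drop = FALSE]
  iou <- ious[pairs]
  matched <- iou[iou > tau]
  tp <- length(matched)
  new("MatchCounts", tp = tp, fp = np - tp, fn = ng - tp,
      iouThreshold = tau, matchedIoU = as.numeric(matched))
}

countsOf <- function(c) {
  if (is(c, "MatchCounts")) c(tp = c@tp, fp = c@fp, fn = c@fn)
  else c(tp = c[["tp"]], fp = c[["fp"]], fn = c[["fn"]])
}

#' F1 score, precision and recall from matching counts
#'
#' `F1 = 2TP / (2TP + FP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`. When every count is zero (nothing
#' predicted, nothing annotated) all three are 1 by convention; with
#' `TP = 0` and errors present they are 0.
#'
#' @param c A [MatchCounts-class] or a named vector/list with `tp`,
#'   `fp`, `fn`.
#' @return A scalar in \[0, 1\].
#' @export
f1FromCounts <- function(c) {
  n <- countsOf(c)
  if (sum(n) == 0) return(1)
  unname(2 * n["tp"] / (2 * n["tp"] + n["fp"] + n["fn"]))
}

#' @rdname f1FromCounts
#' @export
precisionFromCounts <- function(c) {
  n <- countsOf(c)
  if (n["tp"] + n["fp"] == 0) return(if (n["fn"] == 0) 1 else 0)
  unname(n["tp"] / (n["tp"] + n["fp"]))
}

#' @rdname f1FromCounts
#' @export
recallFromCounts <- function(c) {
  n <- countsOf(c)
  if (n["tp"] + n["fn"] == 0) return(if (n["fp"] == 0) 1 else 0)
  unname(n["tp"] / (n["tp"] + n["fn"]))
}

#' F1 over IoU thresholds 0.1-0.9
#'
#' The instance-matching F1 score at each threshold (step 0.1 by
#' default) plus their mean — the standard summary of instance
#' segmentation quality. The curve is non-increasing in the threshold.
#'
#' @param pred,gt Integer 3D instance maps of identical shape.
#' @param thresholds IoU thresholds (default `seq(0.1, 0.9, 0.1)`).
#' @return A data.frame with columns `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, and the mean F1 in attribute
#'   `meanF1` (see [meanF1()]).
#' @export
f1Curve <- function(pred, gt, thresholds = seq(0.1, 0.9, by = 0.1)) {
  ious <- iouMatrix(pred, gt)
  rows <- lapply(thresholds, function(tau) {
    m <- matchAtThreshold(ious, tau)
    data.frame(threshold = tau, tp = m@tp, fp = m@fp, fn = m@fn,
               precision = precisionFromCounts(m),
               recall = recallFromCounts(m), f1 = f1FromCounts(m))
  })
  out <- do.call(rbind, rows)
  attr(out, "meanF1") <- mean(out$f1)
  out
}

#' Mean F1 of a threshold curve
#' @param curve A data.frame from [f1Curve()].
#' @return The mean of the `f1` column.
#' @export
meanF1 <- function(curve) mean(curve$f1)

#' Semantic Dice coefficient
#'
#' `2|A and B| / (|A| + |B|)`; equals the F1 score computed on voxelwise
#' true/false positives and negatives, i.e. instance F1 "at IoU >= 0".
#' Two empty masks give 1 by convention.
#'
#' @param a,b Logical 3D arrays of identical shape.
#' @return A scalar in \[0, 1\].
#' @export
semanticDice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    wnStop("wnet3d_shape_mismatch", "mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Dice-maximizing probability threshold
#'
#' For each (probabilities, reference mask) pair the grid threshold
#' maximizing the semantic Dice of `p > t` is found (ties resolve to
#' the lower threshold); the per-pair optima are averaged into the
#' threshold for the fold — the procedure used to fix the probability
#' cutoff on training data before instance segmentation.
#'
#' @param probs A (K, Z, Y, X) array or list of such arrays.
#' @param labels A logical 3D mask or list of masks, paired with
#'   `probs`.
#' @param grid Candidate thresholds (default `seq(0, 1, 0.05)`).
#' @param classIndex Probability channel to threshold (default 2; use
#'   [selectForegroundClass()] to pick it).
#' @return The scalar fold threshold.
#' @export
findBestThreshold <- function(probs, labels, grid = seq(0, 1, by = 0.05),
                              classIndex = 2L) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(labels)) labels <- list(labels)
  if (length(probs) != length(labels) || length(probs) == 0L)
    wnStop("wnet3d_bad_input",
           "need one or more matched probability/label pairs")
  if (!length(grid)) wnStop("wnet3d_bad_input", "empty threshold grid")
  grid <- sort(grid)
  best <- vapply(seq_along(probs), function(i) {
    ref <- array(as.logical(labels[[i]]), dim = dim(labels[[i]]))
    dice <- vapply(grid, function(t)
      semanticDice(thresholdProbabilities(probs[[i]], classIndex, t),
                   ref), numeric(1))
    grid[which.max(dice)]              # which.max takes the lowest tie
  }, numeric(1))
  mean(best)
}
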