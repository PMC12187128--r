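# Independent brute-force oracles. These deliberately share no code
# with the package implementation: plain loops and explicit double sums.

# Full double-sum soft normalized cut, radius-restricted, self-pairs
# included with weight 1.
bfSoftNCuts <- function(probs, vol, sigmaI = 1, sigmaX = 4, radius = 2) {
  d <- dim(vol)
  K <- dim(probs)[1]
  coords <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  n <- nrow(coords)
  I <- vol[coords]
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d2 <- sum((coords[i, ] - coords[j, ])^2)
    if (sqrt(d2) < radius)
      W[i, j] <- exp(-(I[i] - I[j])^2 / sigmaI) * exp(-d2 / sigmaX)
  }
  loss <- 0
  for (k in 1:K) {
    p <- as.numeric(probs[k, , , ][coords])
    num <- 0; den <- 0
    for (i in 1:n) for (j in 1:n) {
      num <- num + p[i] * (1 - p[j]) * W[i, j]
      den <- den + p[i] * W[i, j]
    }
    loss <- loss + num / (den + 1e-8)
  }
  loss
}

# Random valid K=2 soft assignment for a given spatial shape.
randomProbs <- function(d, K = 2L) {
  p1 <- array(runif(prod(d)), dim = d)
  probs <- array(0, dim = c(K, d))
  probs[1, , , ] <- p1
  probs[2, , , ] <- 1 - p1
  if (K > 2) stop("oracle helper supports K = 2")
  probs
}

# All permutations of 1..n (n <= 6).
allPerms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(1:n, function(i)
    cbind(i, sub + (sub >= i))))
}

# Exhaustive optimal one-to-one matching: maximize the number of pairs
# with IoU > tau, then total IoU; returns the TP count.
bfMatchTP <- function(iou, tau) {
  np <- nrow(iou); ng <- ncol(iou)
  n <- max(np, ng)
  M <- matrix(0, n, n)
  M[seq_len(np), seq_len(ng)] <- iou
  P <- allPerms(n)
  best <- -Inf; btp <- 0L
  for (r in seq_len(nrow(P))) {
    sel <- M[cbind(1:n, P[r, ])]
    tp <- sum(sel > tau)
    sc <- tp * 1e6 + sum(sel)
    if (sc > best) { best <- sc; btp <- tp }
  }
  btp
}

# Pairwise IoU by explicit per-pair set computation.
bfIoU <- function(pred, gt) {
  pl <- sort(unique(pred[pred > 0]))
  gl <- sort(unique(gt[gt > 0]))
  m <- matrix(0, length(pl), length(gl))
  for (i in seq_along(pl)) for (j in seq_along(gl)) {
    a <- pred == pl[i]; b <- gt == gl[j]
    m[i, j] <- sum(a & b) / sum(a | b)
  }
  m
}

# Otsu by exhaustive search over the 255 interior boundaries of a
# 256-bin histogram (between-class variance, lowest tie).
bfOtsu <- function(vol) {
  mn <- min(vol); mx <- max(vol)
  nb <- 256L
  bin <- pmin(floor((vol - mn) / (mx - mn) * nb), nb - 1L)
  centers <- mn + (0:(nb - 1) + 0.5) * (mx - mn) / nb
  bestVar <- -Inf; bestK <- NA
  for (k in 1:(nb - 1)) {
    lo <- bin < k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- 1 - w0
    mu0 <- mean(centers[bin[lo] + 1]); mu1 <- mean(centers[bin[hi] + 1])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > bestVar + 1e-12) { bestVar <- v; bestK <- k }
  }
  mn + bestK * (mx - mn) / nb
}

# 26-connected component count by flood fill over an index list.
bfComponentCount <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] > 0) next
    nxt <- nxt + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        q <- cur + c(dz, dy, dx)
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  nxt
}

# Ball dilation/erosion by explicit structuring-element sweep.
bfBallDilate <- function(mask, radius) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dz = -radius:radius, dy = -radius:radius,
                               dx = -radius:radius))
  off <- off[sqrt(rowSums(off^2)) <= radius, , drop = FALSE]
  out <- array(FALSE, dim = d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    pts <- sweep(off, 2, idx[r, ], `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 &
      pts[, 2] <= d[2] & pts[, 3] >= 1 & pts[, 3] <= d[3]
    out[pts[ok, , drop = FALSE]] <- TRUE
  }
  out
}

bfBallErode <- function(mask, radius) {
  !bfBallDilate(!mask, radius)
}
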