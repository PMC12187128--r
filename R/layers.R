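# Internal neural-network primitives operating on flat tensors with
# layout (C, Z, Y, X), column-major, channel fastest. Each forward
# returns list(out, cache); each backward returns the input gradient
# plus parameter gradients. 3x3x3 convolutions run as chunked
# im2col + GEMM through the installed BLAS.

COL_CHUNK_ELEMS <- 2e7  # max doubles per im2col chunk (~160 MB)

conv3Forward <- function(x, dims, W, b) {
  Cin <- dims[1]
  N <- prod(dims[2:4])
  Cout <- nrow(W)
  out <- numeric(Cout * N)
  chunk <- max(1L, floor(COL_CHUNK_ELEMS / (Cin * 27)))
  s <- 0L
  while (s < N) {
    nc <- min(chunk, N - s)
    col <- cpp_im2col3(x, as.integer(dims), s, nc)
    out[(s * Cout + 1):((s + nc) * Cout)] <- W %*% col + b
    s <- s + nc
  }
  out
}

conv3Backward <- function(x, dims, W, gradOut) {
  Cin <- dims[1]
  N <- prod(dims[2:4])
  Cout <- nrow(W)
  gW <- matrix(0, Cout, ncol(W))
  gx <- numeric(length(x))
  gm <- matrix(gradOut, nrow = Cout)
  chunk <- max(1L, floor(COL_CHUNK_ELEMS / (Cin * 27)))
  s <- 0L
  while (s < N) {
    nc <- min(chunk, N - s)
    col <- cpp_im2col3(x, as.integer(dims), s, nc)
    gchunk <- gm[, (s + 1):(s + nc), drop = FALSE]
    gW <- gW + gchunk %*% t(col)
    gcol <- crossprod(W, gchunk)
    cpp_col2im3_add(gcol, as.integer(dims), s, gx)
    s <- s + nc
  }
  list(gx = gx, gW = gW, gb = rowSums(gm))
}

conv1Forward <- function(x, Cin, W, b) {
  xm <- matrix(x, nrow = Cin)
  as.numeric(W %*% xm + b)
}

conv1Backward <- function(x, Cin, W, gradOut) {
  Cout <- nrow(W)
  gm <- matrix(gradOut, nrow = Cout)
  xm <- matrix(x, nrow = Cin)
  list(gx = as.numeric(crossprod(W, gm)), gW = gm %*% t(xm),
       gb = rowSums(gm))
}

reluForward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

reluBackward <- function(gradOut, mask) gradOut * mask

# Effective group count: at most `groups`, at most C, and dividing C.
effectiveGroups <- function(C, groups) {
  g <- min(groups, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

groupNormForward <- function(x, C, gamma, beta, groups, eps = 1e-5) {
  xm <- matrix(x, nrow = C)
  G <- effectiveGroups(C, groups)
  Cg <- C %/% G
  gi <- rep(seq_len(G), each = Cg)
  M <- Cg * ncol(xm)
  mu <- rowSums(rowsum(xm, gi, reorder = FALSE)) / M
  xc <- xm - mu[gi]
  v <- rowSums(rowsum(xc^2, gi, reorder = FALSE)) / M
  invsd <- 1 / sqrt(v + eps)
  xhat <- xc * invsd[gi]
  out <- xhat * gamma + beta          # gamma, beta recycle per channel
  list(out = as.numeric(out), xhat = xhat, invsd = invsd, gi = gi, M = M)
}

groupNormBackward <- function(gradOut, C, gamma, cache) {
  gm <- matrix(gradOut, nrow = C)
  xhat <- cache$xhat
  gi <- cache$gi
  M <- cache$M
  dgamma <- rowSums(gm * xhat)
  dbeta <- rowSums(gm)
  dxhat <- gm * gamma
  m1 <- rowSums(rowsum(dxhat, gi, reorder = FALSE)) / M
  m2 <- rowSums(rowsum(dxhat * xhat, gi, reorder = FALSE)) / M
  dx <- (dxhat - m1[gi] - xhat * m2[gi]) * cache$invsd[gi]
  list(gx = as.numeric(dx), gGamma = dgamma, gBeta = dbeta)
}

softmaxChannels <- function(x, K) {
  xm <- matrix(x, nrow = K)
  xm <- exp(sweep(xm, 2, apply(xm, 2, max)))
  sweep(xm, 2, colSums(xm), `/`)
}

# d loss / d logits given d loss / d probs, for a channel-wise softmax.
softmaxBackward <- function(gradProbs, probsM) {
  probsM * sweep(gradProbs, 2, colSums(gradProbs * probsM))
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
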