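#' @title WNet3D architecture configuration
#'
#' @description The dual 3D U-Net used for self-supervised segmentation.
#' Each of the two U-Nets (encoder and decoder) has seven blocks over
#' three resolution levels: blocks 1-3 descend (each followed by 2x2x2
#' max pooling), block 4 is the bottleneck, and blocks 5-7 ascend behind
#' 2x2x2 stride-2 transpose convolutions with skip concatenations from
#' blocks 3, 2 and 1. Every block holds two 3x3x3 convolutions; the five
#' middle blocks (2-6) follow each convolution with a ReLU and group
#' normalization, while the first and last blocks are plain convolution
#' pairs. The encoder ends in a 1x1x1 convolution and a channel softmax
#' (K classes); the decoder takes the K probability channels and ends in
#' a 1x1x1 convolution producing the reconstruction.
#'
#' @slot inChannels integer, input channels (1).
#' @slot nClasses integer, segmentation classes K (>= 2).
#' @slot features integer(3), widths of the three levels; the bottleneck
#'   uses twice the last width. Default 64/128/256; 8/16/32 is a
#'   CPU-friendly small setting.
#' @slot groups integer, group-normalization group count; clipped per
#'   layer to the channel count.
#' @slot recChannels integer, reconstruction output channels (1).
#' @export
setClass("WNetArchitecture",
         representation(inChannels = "integer", nClasses = "integer",
                        features = "integer", groups = "integer",
                        recChannels = "integer"),
         prototype(inChannels = 1L, nClasses = 2L,
                   features = c(64L, 128L, 256L), groups = 8L,
                   recChannels = 1L),
         validity = function(object) {
           msg <- character()
           if (length(object@features) != 3L)
             msg <- c(msg, "exactly 3 resolution levels are required")
           w <- c(object@features, 2L * object@features[3])
           if (any(w %% pmin(object@groups, w) != 0))
             msg <- c(msg,
               "feature widths must be divisible by the effective group count")
           if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
           if (object@groups < 1L) msg <- c(msg, "groups must be >= 1")
           if (length(msg)) msg else TRUE
         })

#' Construct a [WNetArchitecture-class]
#'
#' @param inChannels Input channels (default 1).
#' @param nClasses Number of classes K (default 2).
#' @param features Widths of the three levels (default `c(64,128,256)`;
#'   use `c(8,16,32)` for fast CPU-scale models).
#' @param groups Group-normalization groups (default 8, clipped to the
#'   channel count per layer).
#' @param recChannels Reconstruction channels (default 1).
#' @return A `WNetArchitecture` object.
#' @export
wnetArchitecture <- function(inChannels = 1L, nClasses = 2L,
                             features = c(64L, 128L, 256L), groups = 8L,
                             recChannels = 1L) {
  new("WNetArchitecture", inChannels = as.integer(inChannels),
      nClasses = as.integer(nClasses), features = as.integer(features),
      groups = as.integer(groups), recChannels = as.integer(recChannels))
}

#' @title Self-supervised training configuration
#'
#' @description Training hyperparameters. The learning rate is typically
#' chosen between 2e-5 and 2e-3 and the reconstruction weight between
#' 5e-3 and 5e-1, depending on the data; the loss is the weighted sum
#' `wNCuts * SoftNCuts + wRec * reconstruction`, updated in a single
#' backward pass with Adam.
#'
#' @slot epochs integer >= 1 (default 50).
#' @slot batchSize integer >= 1 (default 2).
#' @slot learningRate numeric > 0 (default 2e-5).
#' @slot wNCuts,wRec positive loss weights (defaults 0.5 and 0.5).
#' @slot recLoss "MSE" or "BCE". MSE reconstructs the \[0, 100\]
#'   remapped volume (the scale the weight range is calibrated for);
#'   BCE applies a sigmoid to the decoder output and targets the
#'   unit-scaled volume, as a cross-entropy target must lie in \[0, 1\].
#' @slot affinity an [AffinityConfig-class].
#' @slot seed integer RNG seed.
#' @slot deterministic logical; seeded, single-threaded training.
#' @slot patchSize training cube edge (default 64).
#' @export
setClass("TrainConfig",
         representation(epochs = "integer", batchSize = "integer",
                        learningRate = "numeric", wNCuts = "numeric",
                        wRec = "numeric", recLoss = "character",
                        affinity = "AffinityConfig", seed = "integer",
                        deterministic = "logical", patchSize = "integer"),
         prototype(epochs = 50L, batchSize = 2L, learningRate = 2e-5,
                   wNCuts = 0.5, wRec = 0.5, recLoss = "MSE",
                   affinity = new("AffinityConfig"), seed = 0L,
                   deterministic = TRUE, patchSize = 64L),
         validity = function(object) {
           msg <- character()
           if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
           if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
           if (object@learningRate <= 0)
             msg <- c(msg, "learningRate must be > 0")
           if (object@wNCuts <= 0 || object@wRec < 0)
             msg <- c(msg, "loss weights must be positive")
           if (!object@recLoss %in% c("MSE", "BCE"))
             msg <- c(msg, "recLoss must be 'MSE' or 'BCE'")
           if (length(msg)) msg else TRUE
         })

#' Construct a [TrainConfig-class]
#'
#' @param epochs,batchSize,learningRate,wNCuts,wRec,recLoss,affinity,seed,deterministic,patchSize
#'   See the class documentation.
#' @return A `TrainConfig` object.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 2L, learningRate = 2e-5,
                        wNCuts = 0.5, wRec = 0.5, recLoss = "MSE",
                        affinity = affinityConfig(), seed = 0L,
                        deterministic = TRUE, patchSize = 64L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), wNCuts = as.numeric(wNCuts),
      wRec = as.numeric(wRec), recLoss = recLoss, affinity = affinity,
      seed = as.integer(seed), deterministic = isTRUE(deterministic),
      patchSize = as.integer(patchSize))
}

#' @title A (possibly trained) WNet3D model
#'
#' @description Holds the parameters of both U-Nets, the architecture,
#' the training configuration and per-epoch loss history. Create with
#' [buildWNet3D()], train with [trainSelfSupervised()].
#'
#' @slot params named list of parameter arrays.
#' @slot arch a [WNetArchitecture-class].
#' @slot trainConfig the [TrainConfig-class] used (or NULL).
#' @slot history data.frame with per-epoch `ncuts`, `reconstruction`
#'   and `total` losses.
#' @slot foreground integer; encoder class treated as foreground
#'   (NA until selected).
#' @export
setClass("WNet3D",
         representation(params = "list", arch = "WNetArchitecture",
                        trainConfig = "ANY", history = "data.frame",
                        foreground = "integer"),
         prototype(foreground = NA_integer_))

setMethod("show", "WNet3D", function(object) {
  f <- object@arch@features
  cat("WNet3D model\n")
  cat("  features:", paste(f, collapse = "/"),
      " bottleneck:", 2 * f[3], "\n")
  cat("  classes:", object@arch@nClasses,
      " parameters:", format(countParameters(object), big.mark = ","), "\n")
  cat("  trained epochs:", nrow(object@history), "\n")
})

#' Number of trainable parameters of a model
#' @param model A [WNet3D-class].
#' @return Integer parameter count.
#' @export
countParameters <- function(model) {
  sum(vapply(model@params, length, numeric(1)))
}

#' Per-epoch training losses
#' @param model A [WNet3D-class].
#' @return data.frame with columns `epoch`, `ncuts`, `reconstruction`,
#'   `total`.
#' @export
trainingHistory <- function(model) model@history

# ---- parameter construction ------------------------------------------------

# Channel plan for one U-Net: per block the (in, out) of its two convs,
# plus the three transpose convolutions.
unetChannelPlan <- function(inC, f) {
  fb <- 2L * f[3]
  list(blocks = list(
         c(inC, f[1]), c(f[1], f[2]), c(f[2], f[3]), c(f[3], fb),
         c(2L * f[3], f[3]), c(2L * f[2], f[2]), c(2L * f[1], f[1])),
       up = list(c(fb, f[3]), c(f[3], f[2]), c(f[2], f[1])))
}

GN_BLOCKS <- 2:6  # the five middle blocks carry ReLU + group norm

initUNetParams <- function(prefix, inC, outC, arch) {
  f <- arch@features
  plan <- unetChannelPlan(inC, f)
  p <- list()
  heW <- function(cout, fanin) matrix(rnorm(cout * fanin) *
                                        sqrt(2 / fanin), cout, fanin)
  for (b in 1:7) {
    cin <- plan$blocks[[b]][1]; cout <- plan$blocks[[b]][2]
    for (j in 1:2) {
      ci <- if (j == 1) cin else cout
      nm <- sprintf("%s_b%d_c%d", prefix, b, j)
      p[[paste0(nm, "_W")]] <- heW(cout, ci * 27L)
      p[[paste0(nm, "_b")]] <- numeric(cout)
      if (b %in% GN_BLOCKS) {
        p[[paste0(nm, "_g")]] <- rep(1, cout)
        p[[paste0(nm, "_be")]] <- numeric(cout)
      }
    }
  }
  for (l in 1:3) {
    ci <- plan$up[[l]][1]; co <- plan$up[[l]][2]
    p[[sprintf("%s_u%d_W", prefix, l)]] <- rnorm(co * ci * 8L) *
      sqrt(2 / (ci * 8))
    p[[sprintf("%s_u%d_b", prefix, l)]] <- numeric(co)
  }
  p[[paste0(prefix, "_head_W")]] <- heW(outC, plan$blocks[[7]][2])
  p[[paste0(prefix, "_head_b")]] <- numeric(outC)
  p
}

#' Build an untrained WNet3D
#'
#' Initialises both U-Nets (He initialisation, unit group-norm gains).
#'
#' @param arch A [WNetArchitecture-class].
#' @param seed RNG seed for the initialisation.
#' @return A [WNet3D-class] model.
#' @export
buildWNet3D <- function(arch = wnetArchitecture(), seed = 0L) {
  validObject(arch)
  set.seed(seed)
  params <- c(initUNetParams("enc", arch@inChannels, arch@nClasses, arch),
              initUNetParams("dec", arch@nClasses, arch@recChannels, arch))
  new("WNet3D", params = params, arch = arch, trainConfig = NULL,
      history = data.frame(epoch = integer(), ncuts = numeric(),
                           reconstruction = numeric(), total = numeric()),
      foreground = NA_integer_)
}

# Closed-form parameter count of a U-Net with an arbitrary number of
# levels (used to compare the trimmed 3-level model against a naive
# 4-level variant).
unetParamCount <- function(inC, features, outC, gnAll = FALSE) {
  L <- length(features)
  fb <- 2 * features[L]
  widths <- c(features, fb, rev(features))
  ins <- c(inC, features[-L], features[L],
           2 * rev(features))
  n <- 0
  nb <- length(widths)
  for (b in seq_len(nb)) {
    ci <- ins[b]; co <- widths[b]
    n <- n + co * ci * 27 + co + co * co * 27 + co  # two convs
    if (gnAll || (b > 1 && b < nb)) n <- n + 4 * co # gamma+beta per conv
  }
  prev <- fb
  for (l in L:1) {
    n <- n + features[l] * prev * 8 + features[l]
    prev <- features[l]
  }
  n + outC * features[1] + outC
}

# ---- forward / backward ----------------------------------------------------

blockForward <- function(p, nm, x, sp, cin, cout, useGN, groups) {
  cache <- list()
  cur <- x; ci <- cin
  for (j in 1:2) {
    base <- sprintf("%s_c%d", nm, j)
    cache[[paste0("x", j)]] <- cur
    cache[[paste0("ci", j)]] <- ci
    cur <- conv3Forward(cur, c(ci, sp), p[[paste0(base, "_W")]],
                        p[[paste0(base, "_b")]])
    if (useGN) {
      r <- reluForward(cur)
      cache[[paste0("relu", j)]] <- r$mask
      gn <- groupNormForward(r$out, cout, p[[paste0(base, "_g")]],
                             p[[paste0(base, "_be")]], groups)
      cache[[paste0("gn", j)]] <- gn[c("xhat", "invsd", "gi", "M")]
      cur <- gn$out
    }
    ci <- cout
  }
  list(out = cur, cache = cache)
}

blockBackward <- function(p, nm, gradOut, sp, cout, useGN, cache, grads) {
  g <- gradOut
  for (j in 2:1) {
    base <- sprintf("%s_c%d", nm, j)
    if (useGN) {
      gb <- groupNormBackward(g, cout, p[[paste0(base, "_g")]],
                              cache[[paste0("gn", j)]])
      grads[[paste0(base, "_g")]] <- gb$gGamma
      grads[[paste0(base, "_be")]] <- gb$gBeta
      g <- reluBackward(gb$gx, cache[[paste0("relu", j)]])
    }
    ci <- cache[[paste0("ci", j)]]
    cb <- conv3Backward(cache[[paste0("x", j)]], c(ci, sp),
                        p[[paste0(base, "_W")]], g)
    grads[[paste0(base, "_W")]] <- cb$gW
    grads[[paste0(base, "_b")]] <- cb$gb
    g <- cb$gx
  }
  list(gx = g, grads = grads)
}

concatChannels <- function(a, ca, b, cb) {
  as.numeric(rbind(matrix(a, nrow = ca), matrix(b, nrow = cb)))
}

splitChannels <- function(x, ca, cb) {
  m <- matrix(x, nrow = ca + cb)
  list(a = as.numeric(m[seq_len(ca), , drop = FALSE]),
       b = as.numeric(m[ca + seq_len(cb), , drop = FALSE]))
}

unetForward <- function(p, prefix, x, sp, inC, outC, arch) {
  f <- arch@features; fb <- 2L * f[3]; G <- arch@groups
  plan <- unetChannelPlan(inC, f)
  s <- list(sp, sp %/% 2L, sp %/% 4L, sp %/% 8L)
  cache <- list()
  nm <- function(b) sprintf("%s_b%d", prefix, b)
  b1 <- blockForward(p, nm(1), x, s[[1]], inC, f[1], FALSE, G)
  pool1 <- cpp_maxpool2(b1$out, as.integer(c(f[1], s[[1]])))
  b2 <- blockForward(p, nm(2), pool1$out, s[[2]], f[1], f[2], TRUE, G)
  pool2 <- cpp_maxpool2(b2$out, as.integer(c(f[2], s[[2]])))
  b3 <- blockForward(p, nm(3), pool2$out, s[[3]], f[2], f[3], TRUE, G)
  pool3 <- cpp_maxpool2(b3$out, as.integer(c(f[3], s[[3]])))
  b4 <- blockForward(p, nm(4), pool3$out, s[[4]], f[3], fb, TRUE, G)
  u1 <- cpp_upconv2_forward(b4$out, as.integer(c(fb, s[[4]])),
                            p[[sprintf("%s_u1_W", prefix)]], f[3])
  u1 <- u1 + rep(p[[sprintf("%s_u1_b", prefix)]], prod(s[[3]]))
  cat1 <- concatChannels(u1, f[3], b3$out, f[3])
  b5 <- blockForward(p, nm(5), cat1, s[[3]], 2L * f[3], f[3], TRUE, G)
  u2 <- cpp_upconv2_forward(b5$out, as.integer(c(f[3], s[[3]])),
                            p[[sprintf("%s_u2_W", prefix)]], f[2])
  u2 <- u2 + rep(p[[sprintf("%s_u2_b", prefix)]], prod(s[[2]]))
  cat2 <- concatChannels(u2, f[2], b2$out, f[2])
  b6 <- blockForward(p, nm(6), cat2, s[[2]], 2L * f[2], f[2], TRUE, G)
  u3 <- cpp_upconv2_forward(b6$out, as.integer(c(f[2], s[[2]])),
                            p[[sprintf("%s_u3_W", prefix)]], f[1])
  u3 <- u3 + rep(p[[sprintf("%s_u3_b", prefix)]], prod(s[[1]]))
  cat3 <- concatChannels(u3, f[1], b1$out, f[1])
  b7 <- blockForward(p, nm(7), cat3, s[[1]], 2L * f[1], f[1], FALSE, G)
  head <- conv1Forward(b7$out, f[1], p[[paste0(prefix, "_head_W")]],
                       p[[paste0(prefix, "_head_b")]])
  cache <- list(b1 = b1$cache, b2 = b2$cache, b3 = b3$cache,
                b4 = b4$cache, b5 = b5$cache, b6 = b6$cache,
                b7 = b7$cache,
                pool1 = pool1, pool2 = pool2, pool3 = pool3,
                b1out = b1$out, b2out = b2$out, b3out = b3$out,
                b4out = b4$out, b5out = b5$out, b6out = b6$out,
                b7out = b7$out, x = x, s = s, inC = inC)
  list(out = head, cache = cache)
}

unetBackward <- function(p, prefix, gradHead, cache, inC, outC, arch) {
  f <- arch@features; fb <- 2L * f[3]; G <- arch@groups
  s <- cache$s
  grads <- list()
  nm <- function(b) sprintf("%s_b%d", prefix, b)
  hb <- conv1Backward(cache$b7out, f[1], p[[paste0(prefix, "_head_W")]],
                      gradHead)
  grads[[paste0(prefix, "_head_W")]] <- hb$gW
  grads[[paste0(prefix, "_head_b")]] <- hb$gb
  r7 <- blockBackward(p, nm(7), hb$gx, s[[1]], f[1], FALSE, cache$b7,
                      grads)
  grads <- r7$grads
  sp3 <- splitChannels(r7$gx, f[1], f[1])
  ub3 <- cpp_upconv2_backward(cache$b6out, as.integer(c(f[2], s[[2]])),
                              p[[sprintf("%s_u3_W", prefix)]], f[1], sp3$a)
  grads[[sprintf("%s_u3_W", prefix)]] <- ub3$grad_w
  grads[[sprintf("%s_u3_b", prefix)]] <-
    rowSums(matrix(sp3$a, nrow = f[1]))
  r6 <- blockBackward(p, nm(6), ub3$grad_input, s[[2]], f[2], TRUE,
                      cache$b6, grads)
  grads <- r6$grads
  sp2 <- splitChannels(r6$gx, f[2], f[2])
  ub2 <- cpp_upconv2_backward(cache$b5out, as.integer(c(f[3], s[[3]])),
                              p[[sprintf("%s_u2_W", prefix)]], f[2], sp2$a)
  grads[[sprintf("%s_u2_W", prefix)]] <- ub2$grad_w
  grads[[sprintf("%s_u2_b", prefix)]] <-
    rowSums(matrix(sp2$a, nrow = f[2]))
  r5 <- blockBackward(p, nm(5), ub2$grad_input, s[[3]], f[3], TRUE,
                      cache$b5, grads)
  grads <- r5$grads
  sp1 <- splitChannels(r5$gx, f[3], f[3])
  ub1 <- cpp_upconv2_backward(cache$b4out, as.integer(c(fb, s[[4]])),
                              p[[sprintf("%s_u1_W", prefix)]], f[3], sp1$a)
  grads[[sprintf("%s_u1_W", prefix)]] <- ub1$grad_w
  grads[[sprintf("%s_u1_b", prefix)]] <-
    rowSums(matrix(sp1$a, nrow = f[3]))
  r4 <- blockBackward(p, nm(4), ub1$grad_input, s[[4]], fb, TRUE,
                      cache$b4, grads)
  grads <- r4$grads
  g3 <- cpp_maxpool2_backward(r4$gx, cache$pool3$argmax,
                              as.integer(c(f[3], s[[3]]))) + sp1$b
  r3 <- blockBackward(p, nm(3), g3, s[[3]], f[3], TRUE, cache$b3, grads)
  grads <- r3$grads
  g2 <- cpp_maxpool2_backward(r3$gx, cache$pool2$argmax,
                              as.integer(c(f[2], s[[2]]))) + sp2$b
  r2 <- blockBackward(p, nm(2), g2, s[[2]], f[2], TRUE, cache$b2, grads)
  grads <- r2$grads
  g1 <- cpp_maxpool2_backward(r2$gx, cache$pool1$argmax,
                              as.integer(c(f[1], s[[1]]))) + sp3$b
  r1 <- blockBackward(p, nm(1), g1, s[[1]], f[1], FALSE, cache$b1, grads)
  list(grads = r1$grads, gx = r1$gx)
}

checkSpatial <- function(sp) {
  if (any(sp %% 8L != 0L))
    wnStop("wnet3d_bad_shape",
           "spatial dimensions must be divisible by 8 (three 2x2x2 ",
           "pooling levels); got ", paste(sp, collapse = "x"))
}

#' Forward pass of a WNet3D on one patch
#'
#' Runs the encoder (producing per-voxel class probabilities) and the
#' decoder (reconstructing the input from the probabilities). The input
#' is expected on the unit scale; intensities are min-max remapped to
#' \[0, 1\] if they are not already within it.
#'
#' @param model A [WNet3D-class].
#' @param vol 3D array with all dimensions divisible by 8.
#' @return A list with `probs` (K, Z, Y, X array; channel softmax) and
#'   `reconstruction` (3D array).
#' @export
forwardWNet3D <- function(model, vol) {
  assertVolume(vol)
  sp <- dim(vol)
  checkSpatial(sp)
  if (min(vol) < 0 || max(vol) > 1) vol <- remapIntensity(vol, 0, 1)
  arch <- model@arch
  K <- arch@nClasses
  enc <- unetForward(model@params, "enc", as.numeric(vol), sp,
                     arch@inChannels, K, arch)
  probsM <- softmaxChannels(enc$out, K)
  dec <- unetForward(model@params, "dec", as.numeric(probsM), sp, K,
                     arch@recChannels, arch)
  list(probs = array(probsM, dim = c(K, sp)),
       reconstruction = array(dec$out, dim = sp))
}

#' Weighted sum of the two training losses
#'
#' @param ncuts,rec Scalar loss values.
#' @param wNCuts,wRec Positive weights.
#' @return `wNCuts * ncuts + wRec * rec`.
#' @export
combinedLoss <- function(ncuts, rec, wNCuts, wRec) {
  if (wNCuts <= 0 || wRec < 0)
    wnStop("wnet3d_bad_config", "loss weights must be positive")
  wNCuts * ncuts + wRec * rec
}

# One forward + single backward pass on one unit-scaled patch.
wnetTrainStep <- function(params, x01, sp, arch, cfg) {
  K <- arch@nClasses
  enc <- unetForward(params, "enc", x01, sp, arch@inChannels, K, arch)
  probsM <- softmaxChannels(enc$out, K)
  probs4 <- array(probsM, dim = c(K, sp))
  ng <- softNCutsLossGrad(probs4, array(x01 * 100, dim = sp),
                          cfg@affinity)
  dec <- unetForward(params, "dec", as.numeric(probsM), sp, K,
                     arch@recChannels, arch)
  N <- length(x01)
  if (cfg@recLoss == "MSE") {
    # reconstruction on the [0,100] remapped scale, the convention the
    # reconstruction-weight range (5e-3 .. 5e-1) is calibrated for
    diff <- dec$out - x01 * 100
    rec <- sum(diff^2) / N
    gRecon <- cfg@wRec * 2 * diff / N
  } else {
    sg <- 1 / (1 + exp(-dec$out))
    eps <- 1e-12
    rec <- -sum(x01 * log(sg + eps) + (1 - x01) * log(1 - sg + eps)) / N
    gRecon <- cfg@wRec * (sg - x01) / N
  }
  decB <- unetBackward(params, "dec", gRecon, dec$cache, K,
                       arch@recChannels, arch)
  gProbs <- cfg@wNCuts * matrix(ng$gradient, nrow = K) +
    matrix(decB$gx, nrow = K)
  gLogits <- softmaxBackward(gProbs, probsM)
  encB <- unetBackward(params, "enc", as.numeric(gLogits), enc$cache,
                       arch@inChannels, K, arch)
  list(ncuts = ng$loss, rec = rec,
       grads = c(encB$grads, decB$grads))
}

#' Train a WNet3D without ground truth
#'
#' Volumes are min-max remapped (the \[0, 100\] range assumed by the
#' default intensity sigma is applied internally for the cuts loss),
#' tiled into cubic patches, augmented by random flips and 90-degree
#' rotations, and used to minimise
#' `wNCuts * SoftNCuts + wRec * reconstruction` with Adam in a single
#' backward pass per batch. No labels are used anywhere.
#'
#' The soft cut objective is non-convex; small runs occasionally settle
#' in a high-cut minimum. `restarts` enables a restart rule driven by
#' the training loss alone (no labels): if the epoch-mean NCuts term is
#' still above `restartThreshold` at epoch `restartAfter`, the attempt
#' is abandoned and training restarts with the next seed, up to
#' `restarts` extra attempts; the final attempt always runs to
#' completion. The rule is deterministic, so training remains exactly
#' reproducible for a fixed configuration.
#'
#' @param volumes A 3D array or list of 3D arrays.
#' @param cfg A [TrainConfig-class].
#' @param arch A [WNetArchitecture-class].
#' @param verbose Print per-epoch losses.
#' @param restarts Maximum number of restart attempts (default 0, off).
#' @param restartAfter Epoch at which the restart rule is evaluated.
#' @param restartThreshold NCuts level above which the attempt is
#'   considered stuck.
#' @return A trained [WNet3D-class] with per-epoch history; the seed of
#'   the kept attempt is in the history's `"attemptSeed"` attribute.
#' @export
trainSelfSupervised <- function(volumes, cfg = trainConfig(),
                                arch = wnetArchitecture(),
                                verbose = FALSE, restarts = 0L,
                                restartAfter = 12L,
                                restartThreshold = 0.15) {
  if (is.array(volumes)) volumes <- list(volumes)
  if (!is.list(volumes) || length(volumes) == 0L)
    wnStop("wnet3d_bad_input", "need at least one volume")
  lapply(volumes, assertVolume)
  validObject(cfg); validObject(arch)
  patches <- unlist(lapply(volumes, function(v) {
    v01 <- remapIntensity(v, 0, 1)
    lapply(extractPatches(v01, cfg@patchSize), `[[`, "volume")
  }), recursive = FALSE)
  sp <- rep(cfg@patchSize, 3L)
  checkSpatial(sp)
  for (attempt in seq_len(restarts + 1L)) {
    attemptSeed <- cfg@seed + attempt - 1L
    lastAttempt <- attempt == restarts + 1L
    fit <- trainAttempt(patches, sp, cfg, arch, attemptSeed, verbose,
                        checkAt = if (lastAttempt) 0L else
                          as.integer(restartAfter),
                        checkThreshold = restartThreshold)
    if (!fit$aborted) break
    if (verbose)
      message(sprintf(
        "restart: NCuts %.3f above %.2f at epoch %d (seed %d)",
        fit$hist$ncuts[restartAfter], restartThreshold, restartAfter,
        attemptSeed))
  }
  hist <- fit$hist
  attr(hist, "attemptSeed") <- attemptSeed
  new("WNet3D", params = fit$params, arch = arch, trainConfig = cfg,
      history = hist, foreground = NA_integer_)
}

# One seeded optimization run; abandons early when the cut term is
# still above checkThreshold at epoch checkAt (0 disables the check).
trainAttempt <- function(patches, sp, cfg, arch, seed, verbose,
                         checkAt = 0L, checkThreshold = Inf) {
  set.seed(seed)
  params <- buildWNet3D(arch, seed = seed)@params
  adam <- adamInit(params)
  hist <- data.frame(epoch = seq_len(cfg@epochs), ncuts = NA_real_,
                     reconstruction = NA_real_, total = NA_real_)
  np <- length(patches)
  for (ep in seq_len(cfg@epochs)) {
    ord <- sample.int(np)
    epN <- epR <- 0
    i <- 1L
    while (i <= np) {
      idx <- ord[i:min(np, i + cfg@batchSize - 1L)]
      acc <- NULL
      bN <- bR <- 0
      for (j in idx) {
        x <- augmentVolume(patches[[j]], mode = "selfsup")$volume
        st <- wnetTrainStep(params, as.numeric(x), sp, arch, cfg)
        bN <- bN + st$ncuts; bR <- bR + st$rec
        acc <- if (is.null(acc)) st$grads else
          mapply(`+`, acc, st$grads, SIMPLIFY = FALSE)
      }
      nb <- length(idx)
      acc <- lapply(acc, `/`, nb)
      up <- adamStep(params, acc, adam, cfg@learningRate)
      params <- up$params; adam <- up$state
      epN <- epN + bN; epR <- epR + bR
      i <- i + nb
    }
    hist$ncuts[ep] <- epN / np
    hist$reconstruction[ep] <- epR / np
    hist$total[ep] <- combinedLoss(epN / np, epR / np, cfg@wNCuts,
                                   cfg@wRec)
    if (!is.finite(hist$total[ep]))
      wnStop("wnet3d_nonfinite_loss",
             "non-finite loss at epoch ", ep,
             " (ncuts = ", hist$ncuts[ep], ", rec = ",
             hist$reconstruction[ep], ")")
    if (verbose)
      message(sprintf("epoch %d: ncuts %.4f rec %.5f total %.4f", ep,
                      hist$ncuts[ep], hist$reconstruction[ep],
                      hist$total[ep]))
    if (checkAt > 0L && ep == checkAt &&
        hist$ncuts[ep] > checkThreshold)
      return(list(params = params, hist = hist, aborted = TRUE))
  }
  list(params = params, hist = hist, aborted = FALSE)
}

#' One-epoch loss-balance diagnostic
#'
#' Trains for a single epoch and reports the raw magnitudes of the two
#' loss terms, to guide the choice of `wNCuts`/`wRec` (the weights are
#' never adapted silently).
#'
#' @inheritParams trainSelfSupervised
#' @return Named numeric: `ncuts`, `reconstruction`.
#' @export
lossBalanceDiagnostic <- function(volumes, cfg = trainConfig(),
                                  arch = wnetArchitecture()) {
  cfg@epochs <- 1L
  h <- trainingHistory(trainSelfSupervised(volumes, cfg, arch))
  c(ncuts = h$ncuts[1], reconstruction = h$reconstruction[1])
}

#' Pick the encoder class that tracks image brightness
#'
#' Self-supervised training does not define which class is "foreground";
#' the class whose probability correlates most positively with intensity
#' is the natural choice for bright nuclei (overridable wherever a class
#' index is accepted).
#'
#' @param probs (K, Z, Y, X) probability array.
#' @param vol Matching 3D intensity volume.
#' @return The class index.
#' @export
selectForegroundClass <- function(probs, vol) {
  assertVolume(vol)
  K <- dim(probs)[1]
  cors <- vapply(seq_len(K), function(k) {
    p <- as.numeric(probs[k, , , ])
    if (sd(p) == 0 || sd(vol) == 0) return(-Inf)
    cor(p, as.numeric(vol))
  }, numeric(1))
  which.max(cors)
}

#' Sliding-window semantic inference
#'
#' Tiles the volume with overlapping windows, averages the per-window
#' probabilities and renormalizes per voxel. Volumes smaller than the
#' window or with sizes not divisible by 8 are reflect-padded and the
#' result cropped back.
#'
#' @param model A trained [WNet3D-class].
#' @param vol 3D intensity volume (any scale; min-max remapped
#'   internally).
#' @param window Window edge, divisible by 8 (default 64).
#' @param overlap Fractional window overlap (default 0.25).
#' @return A (K, Z, Y, X) probability array matching `vol`.
#' @export
slidingWindowPredict <- function(model, vol, window = 64L,
                                 overlap = 0.25) {
  assertVolume(vol)
  window <- as.integer(window)
  if (window %% 8L != 0L)
    wnStop("wnet3d_bad_shape", "window must be divisible by 8")
  v <- remapIntensity(vol, 0, 1)
  d0 <- dim(v)
  padHi <- pmax(window - d0, 0)
  padHi <- padHi + (8L - (d0 + padHi) %% 8L) %% 8L
  pad <- cbind(c(0L, 0L, 0L), padHi)
  v <- padReflect(v, pad)
  d <- dim(v)
  K <- model@arch@nClasses
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  sz <- tileStarts(d[1], window, stride)
  sy <- tileStarts(d[2], window, stride)
  sx <- tileStarts(d[3], window, stride)
  acc <- array(0, dim = c(K, d))
  cnt <- array(0, dim = d)
  for (x in sx) for (y in sy) for (z in sz) {
    rz <- z:(z + window - 1L); ry <- y:(y + window - 1L)
    rx <- x:(x + window - 1L)
    fw <- forwardWNet3D(model, v[rz, ry, rx, drop = FALSE])
    acc[, rz, ry, rx] <- acc[, rz, ry, rx, drop = FALSE] + fw$probs
    cnt[rz, ry, rx] <- cnt[rz, ry, rx, drop = FALSE] + 1
  }
  for (k in seq_len(K)) acc[k, , , ] <- acc[k, , , ] / cnt
  tot <- apply(acc, 2:4, sum)
  for (k in seq_len(K)) acc[k, , , ] <- acc[k, , , ] / tot
  acc[, seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
}

# ---- checkpointing ---------------------------------------------------------

archAsList <- function(arch) {
  list(inChannels = arch@inChannels, nClasses = arch@nClasses,
       features = arch@features, groups = arch@groups,
       recChannels = arch@recChannels)
}

cfgAsList <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  list(epochs = cfg@epochs, batchSize = cfg@batchSize,
       learningRate = cfg@learningRate, wNCuts = cfg@wNCuts,
       wRec = cfg@wRec, recLoss = cfg@recLoss,
       affinity = list(sigmaI = cfg@affinity@sigmaI,
                       sigmaX = cfg@affinity@sigmaX,
                       radius = cfg@affinity@radius,
                       nClasses = cfg@affinity@nClasses),
       seed = cfg@seed, deterministic = cfg@deterministic,
       patchSize = cfg@patchSize)
}

#' Save a model checkpoint
#'
#' The checkpoint is a single self-describing file holding the weights,
#' the architecture, the training configuration and its seed, so
#' [loadModel()] needs no external configuration.
#'
#' @param model A [WNet3D-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
saveModel <- function(model, path) {
  if (!dir.exists(dirname(path)))
    wnStop("wnet3d_unwritable", "parent directory does not exist: ",
           dirname(path))
  saveRDS(list(format = "wnet3d-checkpoint", version = 1L,
               arch = archAsList(model@arch),
               trainConfig = cfgAsList(model@trainConfig),
               params = model@params, history = model@history,
               foreground = model@foreground),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [saveModel()].
#' @param arch Optional [WNetArchitecture-class]; if given, loading
#'   fails unless the stored architecture matches exactly.
#' @return A [WNet3D-class].
#' @export
loadModel <- function(path, arch = NULL) {
  if (!file.exists(path))
    wnStop("wnet3d_missing_file", "file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    wnStop("wnet3d_corrupt_checkpoint", "cannot read checkpoint: ",
           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "wnet3d-checkpoint"))
    wnStop("wnet3d_corrupt_checkpoint", "not a wnet3d checkpoint: ", path)
  stored <- do.call(wnetArchitecture, obj$arch)
  if (!is.null(arch)) {
    validObject(arch)
    if (!identical(archAsList(arch), archAsList(stored)))
      wnStop("wnet3d_config_mismatch",
             "checkpoint architecture (K = ", stored@nClasses,
             ", features ", paste(stored@features, collapse = "/"),
             ") does not match the requested architecture")
  }
  expected <- names(c(initUNetParams("enc", stored@inChannels,
                                     stored@nClasses, stored),
                      initUNetParams("dec", stored@nClasses,
                                     stored@recChannels, stored)))
  if (!identical(sort(expected), sort(names(obj$params))))
    wnStop("wnet3d_corrupt_checkpoint",
           "checkpoint parameters do not match the stored architecture")
  cfg <- NULL
  if (!is.null(obj$trainConfig)) {
    tc <- obj$trainConfig
    tc$affinity <- do.call(affinityConfig, tc$affinity)
    cfg <- do.call(trainConfig, tc)
  }
  new("WNet3D", params = obj$params, arch = stored, trainConfig = cfg,
      history = as.data.frame(obj$history),
      foreground = as.integer(obj$foreground))
}
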