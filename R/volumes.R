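#' Read a single-channel volume from a multi-page TIFF
#'
#' Pages are stacked along the first (Z) axis, so a file with `nz` pages of
#' `Y x X` frames becomes a `(nz, Y, X)` array; a single-page image becomes
#' `(1, Y, X)`. Integer samples are returned at their stored values,
#' floating-point samples as stored.
#'
#' @param path Path to a 2D or 3D single-channel TIFF file.
#' @return A 3D numeric array in (Z, Y, X) order.
#' @export
readVolume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    wnStop("wnet3d_bad_path", "path must be a single file path")
  if (!file.exists(path))
    wnStop("wnet3d_missing_file", "file not found: ", path)
  pages <- tryCatch({
    info <- as.data.frame(tiff::readTIFF(path, payload = FALSE))
    isInt <- isTRUE(info$bits.per.sample[1] <= 16L) ||
      identical(info$sample.format[1], "uint")
    # as.is returns stored integer values, but corrupts float samples
    tiff::readTIFF(path, all = TRUE, as.is = isInt)
  }, error = function(e)
    wnStop("wnet3d_not_an_image",
           "could not read '", path, "' as TIFF: ",
           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    wnStop("wnet3d_multichannel",
           "multi-channel/RGB TIFF not supported: ", path)
  d <- dim(pages[[1]])
  vol <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) {
    if (!identical(dim(pages[[z]]), d))
      wnStop("wnet3d_not_an_image", "TIFF pages differ in shape: ", path)
    vol[z, , ] <- pages[[z]]
  }
  storage.mode(vol) <- "double"
  if (!all(is.finite(vol)))
    wnStop("wnet3d_nonfinite", "volume contains non-finite values: ", path)
  vol
}

#' Write a volume or instance map to a multi-page TIFF
#'
#' Non-negative integer-valued data (instance maps, integer intensities)
#' are stored as unsigned integers wide enough for the maximum value
#' (8 or 16 bit) and round-trip exactly through [readVolume()].
#' Floating-point data are stored as 32-bit float samples and must lie in
#' \[0, 1\] (the package's on-disk convention for intensity and
#' probability volumes).
#'
#' @param vol 3D array in (Z, Y, X) order.
#' @param path Output path; the parent directory must exist.
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  if (is.null(dim(vol)) || length(dim(vol)) != 3L || any(dim(vol) < 1L))
    wnStop("wnet3d_bad_volume", "vol must be a non-empty 3D array")
  if (!dir.exists(dirname(path)))
    wnStop("wnet3d_unwritable", "parent directory does not exist: ",
           dirname(path))
  if (!all(is.finite(vol)))
    wnStop("wnet3d_nonfinite", "cannot write non-finite values")
  isInt <- all(vol == round(vol)) && min(vol) >= 0
  if (isInt) {
    mx <- max(vol)
    if (mx > 65535)
      wnStop("wnet3d_label_overflow",
             "integer values above 65535 are not representable ",
             "in the supported TIFF sample formats")
    bits <- if (mx > 255) 16L else 8L
    denom <- 2^bits - 1
    pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ] / denom)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                              compression = "none", reduce = FALSE),
              silent = TRUE)
  } else {
    if (min(vol) < 0 || max(vol) > 1)
      wnStop("wnet3d_float_range",
             "floating-point volumes must be in [0,1] on disk; ",
             "rescale before writing (e.g. remapIntensity(vol, 0, 1))")
    pages <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ])
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                              compression = "none", reduce = FALSE),
              silent = TRUE)
  }
  if (inherits(ok, "try-error"))
    wnStop("wnet3d_unwritable", "could not write TIFF: ", path)
  invisible(path)
}

#' Affine intensity remap
#'
#' Maps the volume's minimum to `lo` and maximum to `hi`. The \[0, 100\]
#' default is the intensity scale assumed by the Soft Normalized Cuts
#' loss with its default intensity sigma of 1. A constant volume maps to
#' all-`lo`.
#'
#' @param vol 3D numeric array.
#' @param lo,hi Target range, `hi > lo`.
#' @return The remapped volume.
#' @export
remapIntensity <- function(vol, lo = 0, hi = 100) {
  assertVolume(vol)
  if (!(hi > lo)) wnStop("wnet3d_bad_range", "hi must exceed lo")
  mn <- min(vol); mx <- max(vol)
  if (mx == mn) return(array(lo, dim = dim(vol)))
  (vol - mn) * (hi - lo) / (mx - mn) + lo
}

#' Percentile clipping
#'
#' Sets values below the `pLo` percentile to that percentile value and
#' values above the `pHi` percentile to that value; interior values are
#' unchanged. Percentiles use linear interpolation between order
#' statistics (`stats::quantile` type 7). This is the supervised-training
#' normalization; self-supervised training uses [remapIntensity()] only.
#'
#' @param vol 3D numeric array.
#' @param pLo,pHi Percentiles in \[0, 100\] with `pLo < pHi`.
#' @return The clipped volume.
#' @export
percentileClipNormalize <- function(vol, pLo = 1, pHi = 99) {
  assertVolume(vol)
  if (!(pLo >= 0 && pLo < pHi && pHi <= 100))
    wnStop("wnet3d_bad_range", "need 0 <= pLo < pHi <= 100")
  q <- quantile(vol, c(pLo, pHi) / 100, names = FALSE, type = 7)
  pmin(pmax(vol, q[1]), q[2])
}

tileStarts <- function(size, edge, stride = edge) {
  if (size < edge)
    wnStop("wnet3d_bad_patch", "dimension ", size,
           " is smaller than the patch edge ", edge)
  s <- seq.int(1L, size - edge + 1L, by = stride)
  if (s[length(s)] + edge - 1L < size) s <- c(s, size - edge + 1L)
  s
}

#' Tile a volume into cubic patches
#'
#' Deterministic edge-aligned tiling; when a dimension is not a multiple
#' of `edge`, the final window per axis is shifted to end at the boundary
#' (overlapping its neighbour), so the union of patches covers every
#' voxel. Label patches, if given, are cut at identical coordinates.
#'
#' @param vol 3D numeric array.
#' @param edge Cube edge length in voxels (default 64, the training
#'   patch size).
#' @param labels Optional instance map with the same shape.
#' @return A list of patches; each element has `volume`, `labels`
#'   (or NULL) and `origin` (1-based (z,y,x) corner).
#' @export
extractPatches <- function(vol, edge = 64L, labels = NULL) {
  assertVolume(vol)
  if (edge <= 0) wnStop("wnet3d_bad_patch", "edge must be positive")
  if (!is.null(labels)) assertInstanceMap(labels, vol)
  d <- dim(vol)
  sz <- tileStarts(d[1], edge); sy <- tileStarts(d[2], edge)
  sx <- tileStarts(d[3], edge)
  out <- vector("list", length(sz) * length(sy) * length(sx))
  i <- 0L
  for (x in sx) for (y in sy) for (z in sz) {
    i <- i + 1L
    rz <- z:(z + edge - 1L); ry <- y:(y + edge - 1L); rx <- x:(x + edge - 1L)
    out[[i]] <- list(
      volume = vol[rz, ry, rx, drop = FALSE],
      labels = if (is.null(labels)) NULL else
        labels[rz, ry, rx, drop = FALSE],
      origin = c(z = z, y = y, x = x))
  }
  out
}

flipAxis <- function(a, axis) {
  ix <- rep(list(quote(expr = )), 3)
  ix[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), ix, list(drop = FALSE)))
}

# 90-degree rotation (k quarter-turns) in the plane of two axes.
rot90Axis <- function(a, axes, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    perm <- 1:3
    perm[axes] <- axes[2:1]
    a <- flipAxis(aperm(a, perm), axes[1])
  }
  a
}

#' Random geometric (and optional photometric) augmentation
#'
#' In `selfsup` mode only axis flips and 90-degree rotations are drawn,
#' so the multiset of voxel values is preserved exactly. `supervised`
#' mode adds a random additive intensity shift, a small random affine
#' warp and an elastic deformation; geometric transforms are applied
#' identically to the labels with nearest-neighbour resampling.
#'
#' @param vol 3D numeric array.
#' @param labels Optional instance map, transformed alongside.
#' @param mode `"selfsup"` or `"supervised"`.
#' @param seed Optional integer; a fixed seed gives identical output.
#' @param params Supervised-mode magnitudes: `intensityShift` (additive,
#'   fraction of the intensity range, default 0.05), `maxRotation`
#'   (degrees, default 10), `scaleRange` (default c(0.9, 1.1)),
#'   `elasticSigma` (smoothing of the displacement field, voxels,
#'   default 4) and `elasticAmplitude` (voxels, default 2).
#' @return A list with `volume` and `labels`.
#' @export
augmentVolume <- function(vol, labels = NULL,
                          mode = c("selfsup", "supervised"),
                          seed = NULL, params = list()) {
  mode <- match.arg(mode)
  assertVolume(vol)
  if (!is.null(labels)) assertInstanceMap(labels, vol)
  if (!is.null(seed)) set.seed(seed)
  p <- modifyList(list(intensityShift = 0.05, maxRotation = 10,
                       scaleRange = c(0.9, 1.1), elasticSigma = 4,
                       elasticAmplitude = 2), params)
  if (mode == "supervised") {
    res <- warpRandom(vol, labels, p)
    vol <- res$volume; labels <- res$labels
    shift <- runif(1, -1, 1) * p$intensityShift * diff(range(vol))
    vol <- vol + shift
  }
  for (axis in 1:3)
    if (runif(1) < 0.5) {
      vol <- flipAxis(vol, axis)
      if (!is.null(labels)) labels <- flipAxis(labels, axis)
    }
  planes <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pl <- planes[[sample.int(3L, 1L)]]
  k <- sample.int(4L, 1L) - 1L
  sq <- dim(vol)[pl[1]] == dim(vol)[pl[2]]
  if (sq) {  # rotation only defined when the plane is square
    vol <- rot90Axis(vol, pl, k)
    if (!is.null(labels)) labels <- rot90Axis(labels, pl, k)
  }
  list(volume = vol, labels = labels)
}

# Random affine + elastic warp; trilinear for intensities, nearest for
# labels. Used only by supervised-mode augmentation.
warpRandom <- function(vol, labels, p) {
  d <- dim(vol)
  ang <- runif(3, -p$maxRotation, p$maxRotation) * pi / 180
  sc <- runif(3, p$scaleRange[1], p$scaleRange[2])
  rz <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  rx <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  A <- rz %*% ry %*% rx %*% diag(1 / sc)
  ctr <- (d + 1) / 2
  grid <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                                x = seq_len(d[3])))
  src <- sweep(sweep(grid, 2, ctr) %*% t(A), 2, ctr, `+`)
  if (p$elasticAmplitude > 0) {
    for (a in 1:3) {
      field <- array(rnorm(prod(d)), dim = d)
      field <- gaussianSmooth3D(field, p$elasticSigma)
      field <- field / max(abs(field), 1e-12) * p$elasticAmplitude
      src[, a] <- src[, a] + as.vector(field)
    }
  }
  newVol <- array(trilinear(vol, src), dim = d)
  newLab <- NULL
  if (!is.null(labels)) {
    si <- pmin(pmax(round(src), 1), matrix(d, nrow(src), 3, byrow = TRUE))
    newLab <- array(labels[cbind(si[, 1], si[, 2], si[, 3])], dim = d)
  }
  list(volume = newVol, labels = newLab)
}

trilinear <- function(vol, pts) {
  d <- dim(vol)
  p0 <- pmin(pmax(floor(pts), 1), matrix(d - 1, nrow(pts), 3, byrow = TRUE))
  fr <- pmin(pmax(pts - p0, 0), 1)
  acc <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dx) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * vol[cbind(p0[, 1] + dz, p0[, 2] + dy, p0[, 3] + dx)]
  }
  acc
}
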