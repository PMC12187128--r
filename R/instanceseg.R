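# Semantic-to-instance conversion and label post-processing. All
# connectivity (components, adjacency, borders) is 26-connected.

dims3 <- function(vol) as.integer(dim(vol))

gaussianKernel1D <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter (kernel truncated at 4 sigma, mirror
#' boundary). `sigma = 0` returns the input.
#'
#' @param vol 3D numeric array.
#' @param sigma Standard deviation in voxels.
#' @return The smoothed volume.
#' @export
gaussianSmooth3D <- function(vol, sigma) {
  assertVolume(vol)
  if (sigma < 0) wnStop("wnet3d_bad_config", "sigma must be >= 0")
  if (sigma == 0) return(vol)
  k <- gaussianKernel1D(sigma)
  out <- as.numeric(vol)
  for (axis in 0:2)
    out <- cpp_sepconv(out, dims3(vol), k, axis)
  array(out, dim = dim(vol))
}

#' Threshold a probability channel
#'
#' @param probs (K, Z, Y, X) probability array.
#' @param classIndex Channel to threshold.
#' @param t Threshold in \[0, 1\]; the mask is `p > t` (strict).
#' @return A logical 3D array.
#' @export
thresholdProbabilities <- function(probs, classIndex, t) {
  if (length(dim(probs)) != 4L)
    wnStop("wnet3d_bad_probs", "probs must be a 4D (class,Z,Y,X) array")
  if (classIndex < 1 || classIndex > dim(probs)[1])
    wnStop("wnet3d_bad_class", "class index ", classIndex,
           " out of range 1..", dim(probs)[1])
  if (t < 0 || t > 1)
    wnStop("wnet3d_bad_config", "threshold must be in [0,1]")
  array(probs[classIndex, , , ] > t, dim = dim(probs)[2:4])
}

#' Otsu's threshold over a 256-bin histogram
#'
#' Exhaustive search over the 255 interior bin boundaries of a 256-bin
#' histogram spanning the volume's range, maximizing the between-class
#' variance; ties resolve to the lowest boundary.
#'
#' @param vol Non-constant 3D numeric array.
#' @return The scalar threshold (foreground is `vol > threshold`).
#' @export
otsuThreshold <- function(vol) {
  assertVolume(vol)
  mn <- min(vol); mx <- max(vol)
  if (mx == mn)
    wnStop("wnet3d_constant_volume",
           "Otsu threshold is undefined for a constant volume")
  nb <- 256L
  bin <- pmin(floor((vol - mn) / (mx - mn) * nb), nb - 1L)
  h <- tabulate(bin + 1L, nbins = nb)
  p <- h / sum(h)
  centers <- mn + (seq_len(nb) - 0.5) * (mx - mn) / nb
  w0 <- cumsum(p)[-nb]
  mu0 <- cumsum(p * centers)[-nb]
  muT <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigmaB <- rep(-Inf, nb - 1L)
  sigmaB[valid] <- (muT * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(sigmaB)
  mn + k * (mx - mn) / nb          # upper edge of bin k
}

compactRelabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Voronoi-Otsu instance labelling
#'
#' Seeds are the 26-connected regional maxima of the volume smoothed
#' with `spotSigma`; the object mask is the Otsu threshold of the volume
#' smoothed with `outlineSigma`; seeds outside the mask are dropped and
#' the mask is partitioned among the surviving seeds by shortest-path
#' flooding (a Voronoi tessellation within the mask). Avoids fusing
#' clumped convex objects better than plain connected components.
#'
#' @param vol Non-constant 3D numeric array (raw intensity or a
#'   thresholded probability map; both entry points are valid).
#' @param spotSigma Gaussian scale for seed detection (voxels).
#' @param outlineSigma Gaussian scale for the mask outline (voxels).
#'   The 0.65/0.65 defaults are the values used for mesoSPIM-style
#'   nuclei.
#' @return An integer 3D instance map (0 = background); all zeros when
#'   no seeds survive.
#' @export
voronoiOtsuLabel <- function(vol, spotSigma = 0.65, outlineSigma = 0.65) {
  assertVolume(vol)
  if (spotSigma < 0 || outlineSigma < 0)
    wnStop("wnet3d_bad_config", "sigmas must be >= 0")
  d <- dims3(vol)
  seeds <- cpp_regional_maxima(as.numeric(gaussianSmooth3D(vol, spotSigma)),
                               d)
  smoothed <- gaussianSmooth3D(vol, outlineSigma)
  mask <- as.numeric(smoothed) > otsuThreshold(smoothed)
  seeds[!mask] <- 0L
  if (!any(seeds > 0))
    return(array(0L, dim = dim(vol)))
  lab <- cpp_voronoi_flood(seeds, mask, d)
  array(compactRelabel(lab), dim = dim(vol))
}

#' Connected-component instance labelling (26-connectivity)
#'
#' @param mask Logical 3D array.
#' @return Integer 3D instance map labelled 1..n.
#' @export
connectedComponentsLabel <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    wnStop("wnet3d_bad_volume", "mask must be a 3D array")
  array(cpp_label26(as.logical(mask), dims3(mask)), dim = dim(mask))
}

#' Distance-transform watershed instance labelling
#'
#' Seeds at the regional maxima of the interior Euclidean distance map,
#' flooded within the mask by ascending negative distance; splits
#' touching convex objects near their neck.
#'
#' @param mask Logical 3D array.
#' @return Integer 3D instance map; labels partition the mask exactly.
#' @export
watershedLabel <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    wnStop("wnet3d_bad_volume", "mask must be a 3D array")
  d <- dims3(mask)
  m <- as.logical(mask)
  if (!any(m)) return(array(0L, dim = dim(mask)))
  edt <- cpp_edt_sq(m, d)
  seeds <- cpp_regional_maxima(edt, d)
  seeds[!m] <- 0L
  lab <- cpp_watershed_flood(-edt, seeds, m, d)
  array(compactRelabel(lab), dim = dim(mask))
}

ballDilate <- function(mask, radius) {
  d <- dims3(mask)
  distToFg <- cpp_edt_sq(!mask, d)       # squared distance to the mask
  array(as.logical(mask) | (distToFg <= radius^2), dim = dim(mask))
}

ballErode <- function(mask, radius) {
  d <- dims3(mask)
  distToBg <- cpp_edt_sq(as.logical(mask), d)
  array(distToBg > radius^2, dim = dim(mask))
}

#' Morphological closing with a ball structuring element
#'
#' Dilation then erosion with an exact Euclidean ball of the given
#' radius (computed via distance transforms); removes holes and gaps up
#' to roughly the radius. Radius 0 is the identity. Used e.g. with
#' radius 8 to fill holes in semantic labels of large nuclei before
#' instance merging.
#'
#' @param mask Logical 3D array.
#' @param radius Ball radius in voxels, >= 0.
#' @return The closed logical mask.
#' @export
morphologicalClosing <- function(mask, radius) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    wnStop("wnet3d_bad_volume", "mask must be a 3D array")
  if (radius < 0) wnStop("wnet3d_bad_config", "radius must be >= 0")
  if (radius == 0) return(array(as.logical(mask), dim = dim(mask)))
  ballErode(ballDilate(mask, radius), radius)
}

#' Merge touching labels by border intensity
#'
#' For every pair of labels sharing a 26-adjacent border, the mean
#' intensity over the border voxels (both sides, each voxel counted
#' once) is computed; pairs whose border mean lies within `[lo, hi]`
#' are merged, transitively (union-find), and the result is relabelled
#' compactly. The \[35, 100\] defaults assume the volume is remapped to
#' \[0, 100\] and target over-split bright nuclei.
#'
#' @param instances Integer 3D instance map.
#' @param vol Intensity volume of the same shape (remapped to \[0,100\]
#'   for the default bounds).
#' @param lo,hi Inclusive intensity bounds for merging.
#' @return The merged instance map; label count never increases and
#'   foreground support is unchanged.
#' @export
mergeLabelsByBorderIntensity <- function(instances, vol, lo = 35,
                                         hi = 100) {
  assertInstanceMap(instances)
  assertVolume(vol)
  if (!identical(dim(instances), dim(vol)))
    wnStop("wnet3d_shape_mismatch",
           "instance map and volume shapes differ")
  bp <- cpp_border_pairs(as.integer(instances), as.numeric(vol),
                         dims3(vol))
  sel <- bp$border_mean >= lo & bp$border_mean <= hi
  if (!any(sel)) return(instances)
  mx <- max(instances)
  parent <- seq_len(mx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(sel)) {
    ra <- find(bp$a[i]); rb <- find(bp$b[i])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(mx), find, integer(1))
  out <- instances
  pos <- instances > 0
  out[pos] <- roots[instances[pos]]
  array(compactRelabel(out), dim = dim(instances))
}

#' Remove labels by voxel volume
#'
#' Labels whose voxel count falls outside `[minVoxels, maxVoxels]` are
#' set to background — the size rule used to discard aberrantly small or
#' large particles (noise specks, imaging artifacts).
#'
#' @param instances Integer 3D instance map.
#' @param minVoxels,maxVoxels Inclusive size bounds
#'   (`0 <= minVoxels < maxVoxels`; `maxVoxels` may be `Inf`).
#' @param relabel Compactly relabel survivors (default TRUE); otherwise
#'   surviving labels keep their identity.
#' @return The filtered instance map.
#' @export
filterByVolume <- function(instances, minVoxels = 0, maxVoxels = Inf,
                           relabel = TRUE) {
  assertInstanceMap(instances)
  if (minVoxels < 0 || minVoxels >= maxVoxels)
    wnStop("wnet3d_bad_config", "need 0 <= minVoxels < maxVoxels")
  mx <- max(instances)
  if (mx == 0) return(instances)
  counts <- tabulate(instances[instances > 0], nbins = mx)
  drop <- which(counts > 0 & (counts < minVoxels | counts > maxVoxels))
  out <- instances
  if (length(drop)) out[out %in% drop] <- 0L
  if (relabel) out <- array(compactRelabel(out), dim = dim(instances))
  out
}
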