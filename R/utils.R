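# Internal helpers: classed errors and argument checking.

wnStop <- function(class, ...) {
  stop(structure(class = c(class, "wnet3d_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assertVolume <- function(vol, name = "vol", finite = TRUE) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    wnStop("wnet3d_bad_volume", name, " must be a 3D array (Z,Y,X)")
  if (any(dim(vol) < 1L))
    wnStop("wnet3d_bad_volume", name, " has an empty dimension")
  if (finite && !all(is.finite(vol)))
    wnStop("wnet3d_nonfinite", name, " contains non-finite values")
  invisible(vol)
}

assertInstanceMap <- function(labels, vol = NULL, name = "labels") {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    wnStop("wnet3d_bad_volume", name, " must be a 3D array (Z,Y,X)")
  if (any(labels < 0) || any(labels != round(labels)))
    wnStop("wnet3d_bad_labels", name, " must contain non-negative integers")
  if (!is.null(vol) && !identical(dim(labels), dim(vol)))
    wnStop("wnet3d_shape_mismatch", name,
           " shape differs from the paired volume")
  invisible(labels)
}

assertProbs <- function(probs, name = "probs", tol = 1e-5) {
  if (!is.array(probs) || length(dim(probs)) != 4L)
    wnStop("wnet3d_bad_probs", name, " must be a 4D array (class,Z,Y,X)")
  if (any(probs < -tol) || any(probs > 1 + tol))
    wnStop("wnet3d_bad_probs", name, " has values outside [0,1]")
  sums <- apply(probs, 2:4, sum)
  if (max(abs(sums - 1)) > tol)
    wnStop("wnet3d_bad_probs", name,
           " class memberships do not sum to 1 per voxel")
  invisible(probs)
}

# Mirror ("reflect") padding of a 3D array; pad is a 3x2 matrix of
# (low, high) pad widths per axis.
padReflect <- function(vol, pad) {
  d <- dim(vol)
  ix <- lapply(1:3, function(a) {
    i <- c(rev(seq_len(pad[a, 1])), seq_len(d[a]),
           d[a] + 1 - seq_len(pad[a, 2]))
    pmin(pmax(i, 1L), d[a])
  })
  vol[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}
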