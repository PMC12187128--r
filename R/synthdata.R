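#' @title Synthetic 3D nuclei volume configuration
#'
#' @description Seeded generator of volumes emulating the statistics the
#' self-supervised method assumes: bright, roughly convex nuclei with
#' local contrast against a darker background, optional brightness
#' halos, smooth background gradients and bright streak artifacts.
#' Intensities are on the \[0, 1\] scale used for volumes on disk.
#'
#' @slot shape integer(3), volume shape (Z, Y, X).
#' @slot nCells integer >= 0.
#' @slot radiusRange numeric(2), ellipsoid semi-axis range in voxels.
#' @slot cellIntensityRange numeric(2), peak intensity per nucleus.
#' @slot backgroundLevel numeric, base background intensity.
#' @slot psfSigma numeric, Gaussian blur applied to the clean signal
#'   before noise, emulating the microscope point-spread function
#'   (0 disables).
#' @slot noiseSd numeric, additive Gaussian noise sd.
#' @slot noiseModel "gaussian" or "poisson".
#' @slot minSeparation numeric, minimum centre-to-centre distance.
#' @slot halo numeric, amplitude of a dim brightness halo around each
#'   nucleus (0 disables).
#' @slot gradientAmplitude numeric, amplitude of a smooth linear
#'   background gradient (0 disables).
#' @slot seed integer RNG seed.
#' @export
setClass("SynthConfig",
         representation(shape = "integer", nCells = "integer",
                        radiusRange = "numeric",
                        cellIntensityRange = "numeric",
                        backgroundLevel = "numeric",
                        psfSigma = "numeric", noiseSd = "numeric",
                        noiseModel = "character",
                        minSeparation = "numeric", halo = "numeric",
                        gradientAmplitude = "numeric", seed = "integer"),
         validity = function(object) {
           msg <- character()
           if (length(object@shape) != 3L || any(object@shape < 1L))
             msg <- c(msg, "shape must be three positive integers")
           if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
           if (any(object@radiusRange < 1))
             msg <- c(msg, "radii must be >= 1 voxel")
           if (object@psfSigma < 0)
             msg <- c(msg, "psfSigma must be >= 0")
           if (object@minSeparation < 0)
             msg <- c(msg, "minSeparation must be >= 0")
           if (!object@noiseModel %in% c("gaussian", "poisson"))
             msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson'")
           if (length(msg)) msg else TRUE
         })

#' Construct a [SynthConfig-class]
#'
#' Defaults place 30 nuclei of 3-6 voxel semi-axes (peak intensity
#' 0.45-0.7 over a 0.1 background, a 0.7-voxel point-spread blur and
#' Gaussian noise sd 0.003 — a high-contrast, spatially coherent regime
#' typical of nuclear stains in cleared tissue) in a 64-cube, pairwise
#' separated by at least 14 voxels so ground truth is unambiguous.
#'
#' @param shape,nCells,radiusRange,cellIntensityRange,backgroundLevel,psfSigma,noiseSd,noiseModel,minSeparation,halo,gradientAmplitude,seed
#'   See the class documentation.
#' @return A `SynthConfig` object.
#' @export
synthConfig <- function(shape = c(64L, 64L, 64L), nCells = 30L,
                        radiusRange = c(3, 6),
                        cellIntensityRange = c(0.45, 0.7),
                        backgroundLevel = 0.1, psfSigma = 0.7,
                        noiseSd = 0.003, noiseModel = "gaussian",
                        minSeparation = 2 * max(radiusRange) + 2,
                        halo = 0, gradientAmplitude = 0, seed = 1L) {
  new("SynthConfig", shape = as.integer(shape),
      nCells = as.integer(nCells), radiusRange = as.numeric(radiusRange),
      cellIntensityRange = as.numeric(cellIntensityRange),
      backgroundLevel = as.numeric(backgroundLevel),
      psfSigma = as.numeric(psfSigma),
      noiseSd = as.numeric(noiseSd), noiseModel = noiseModel,
      minSeparation = as.numeric(minSeparation),
      halo = as.numeric(halo),
      gradientAmplitude = as.numeric(gradientAmplitude),
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nCells, "nuclei in",
      paste(object@shape, collapse = "x"), "volume, radii",
      paste(object@radiusRange, collapse = "-"), "voxels, seed",
      object@seed, "\n")
})

MAX_PLACEMENT_ATTEMPTS <- 10000L

#' Generate a synthetic nuclei volume with exact instance labels
#'
#' Nuclei are axis-aligned ellipsoids with a near-uniform ("plateau")
#' brightness profile and a soft shoulder at the rim, placed at
#' rejection-sampled centres respecting the minimum separation. The instance map marks each
#' ellipsoid's support with labels 1..n and is created before noise is
#' added, so ground truth is exact by construction. With a fixed seed
#' the output is bit-identical across runs.
#'
#' @param cfg A [SynthConfig-class].
#' @return A list with `volume` (3D array, values clipped to \[0, 1\])
#'   and `labels` (integer 3D array).
#' @export
generateNucleiVolume <- function(cfg = synthConfig()) {
  validObject(cfg)
  set.seed(cfg@seed)
  d <- cfg@shape
  vol <- array(cfg@backgroundLevel, dim = d)
  if (cfg@gradientAmplitude > 0) {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    ramp <- outer(outer(seq_len(d[1]) * dir[1], seq_len(d[2]) * dir[2],
                        `+`), seq_len(d[3]) * dir[3], `+`)
    ramp <- (ramp - min(ramp)) / max(1e-12, diff(range(ramp)))
    vol <- vol + cfg@gradientAmplitude * ramp
  }
  labels <- array(0L, dim = d)
  centers <- matrix(numeric(0), 0, 3)
  for (i in seq_len(cfg@nCells)) {
    ax <- runif(3, cfg@radiusRange[1], cfg@radiusRange[2])
    placed <- FALSE
    for (att in seq_len(MAX_PLACEMENT_ATTEMPTS)) {
      ctr <- vapply(1:3, function(a)
        runif(1, 1 + ax[a], d[a] - ax[a]), numeric(1))
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - ctr)^2))) >= cfg@minSeparation) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      wnStop("wnet3d_placement_failure",
             "could not place nucleus ", i, " after ",
             MAX_PLACEMENT_ATTEMPTS, " attempts; enlarge the volume or ",
             "reduce nCells/minSeparation")
    centers <- rbind(centers, ctr)
    peak <- runif(1, cfg@cellIntensityRange[1], cfg@cellIntensityRange[2])
    lo <- pmax(floor(ctr - ax - 1), 1)
    hi <- pmin(ceiling(ctr + ax + 1), d)
    rz <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rx <- lo[3]:hi[3]
    g <- expand.grid(z = rz, y = ry, x = rx)
    rho2 <- ((g$z - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
      ((g$x - ctr[3]) / ax[3])^2
    inside <- rho2 <= 1
    ix <- cbind(g$z, g$y, g$x)
    labels[ix[inside, , drop = FALSE]] <- i
    # plateau profile: near-uniform brightness with a soft shoulder at
    # the rim (real stained nuclei are filled, not Gaussian spots)
    prof <- peak * exp(-rho2^3)
    keep <- rho2 <= 1.6^2            # profile support a bit past the rim
    vol[ix[keep, , drop = FALSE]] <- vol[ix[keep, , drop = FALSE]] +
      prof[keep]
    if (cfg@halo > 0) {
      ring <- rho2 > 1 & rho2 <= 1.5^2
      vol[ix[ring, , drop = FALSE]] <- vol[ix[ring, , drop = FALSE]] +
        cfg@halo * peak
    }
  }
  if (cfg@psfSigma > 0)
    vol <- gaussianSmooth3D(vol, cfg@psfSigma)
  if (cfg@noiseSd > 0) {
    if (cfg@noiseModel == "gaussian") {
      vol <- vol + rnorm(length(vol), sd = cfg@noiseSd)
    } else {
      # Poisson shot noise at a photon budget matching the requested sd
      # at the background level
      lambda <- cfg@backgroundLevel / cfg@noiseSd^2
      vol <- array(rpois(length(vol), pmax(vol, 0) * lambda) / lambda,
                   dim = d)
    }
  }
  vol <- pmin(pmax(vol, 0), 1)
  list(volume = array(vol, dim = d), labels = labels)
}

#' Add a bright streak artifact
#'
#' Emulates non-cellular bright structures (e.g. tissue-clearing
#' artifacts) that a self-supervised foreground detector may pick up.
#' The intensity is altered inside the artifact region only; labels are
#' unchanged (artifacts are not cells). The artifact's voxel mask is
#' returned so evaluations can exclude the region.
#'
#' @param vol 3D volume.
#' @param labels Matching instance map.
#' @param spec List: `amplitude` (added intensity, default 0.3), `axis`
#'   (streak direction 1-3, default 3), `width` (half-width in voxels,
#'   default 2), `position` ((z,y) or axis-appropriate centre; default
#'   placed to avoid nuclei), `avoidLabels` (default TRUE).
#' @return A list with `volume`, `labels` (unchanged) and
#'   `artifactMask` (logical 3D array).
#' @export
addArtifact <- function(vol, labels, spec = list()) {
  assertVolume(vol)
  assertInstanceMap(labels, vol)
  s <- modifyList(list(amplitude = 0.3, axis = 3L, width = 2L,
                       position = NULL, avoidLabels = TRUE), spec)
  d <- dim(vol)
  perp <- setdiff(1:3, s$axis)
  pickMask <- function(pos) {
    ix <- lapply(1:3, function(a) seq_len(d[a]))
    for (j in 1:2) {
      r <- max(1, pos[j] - s$width):min(d[perp[j]], pos[j] + s$width)
      ix[[perp[j]]] <- r
    }
    m <- array(FALSE, dim = d)
    m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
    m
  }
  if (is.null(s$position)) {
    cand <- expand.grid(a = seq(1 + s$width, d[perp[1]] - s$width,
                                by = 1),
                        b = seq(1 + s$width, d[perp[2]] - s$width,
                                by = 1))
    found <- NULL
    for (i in sample.int(nrow(cand))) {
      m <- pickMask(c(cand$a[i], cand$b[i]))
      if (!s$avoidLabels || !any(labels[m] > 0)) { found <- m; break }
    }
    if (is.null(found))
      wnStop("wnet3d_placement_failure",
             "no artifact position avoiding all nuclei")
    mask <- found
  } else {
    if (any(s$position < 1) || any(s$position > d[perp]))
      wnStop("wnet3d_bad_config", "artifact position outside volume")
    mask <- pickMask(s$position)
  }
  out <- vol
  out[mask] <- pmin(out[mask] + s$amplitude, 1)
  list(volume = out, labels = labels, artifactMask = mask)
}

#' Write a benchmark suite of paired volumes and labels
#'
#' Generates `nVolumes` seeded volumes (seeds `seed`, `seed + 1`, ...),
#' writes float32 volume and uint16 label TIFFs, and a JSON manifest
#' recording files, per-volume seeds and cell counts. Regenerating from
#' the manifest seeds reproduces the files byte-identically.
#'
#' @param outDir Output directory (must exist or be creatable).
#' @param nVolumes Number of volumes.
#' @param cfg A [SynthConfig-class] (its seed slot is overridden
#'   per volume).
#' @param seed Base seed.
#' @return The manifest path, invisibly; the manifest is
#'   `manifest.json` in `outDir`.
#' @export
makeBenchmarkSuite <- function(outDir, nVolumes = 4L,
                               cfg = synthConfig(), seed = 1L) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    wnStop("wnet3d_unwritable", "cannot create directory: ", outDir)
  entries <- vector("list", nVolumes)
  for (i in seq_len(nVolumes)) {
    cfg@seed <- as.integer(seed + i - 1L)
    gv <- generateNucleiVolume(cfg)
    vf <- sprintf("vol_%03d.tif", i)
    lf <- sprintf("lab_%03d.tif", i)
    writeVolume(gv$volume, file.path(outDir, vf))
    writeVolume(gv$labels, file.path(outDir, lf))
    entries[[i]] <- list(volume = vf, labels = lf, seed = cfg@seed,
                         n_cells = max(gv$labels))
  }
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(generator = "wnet3d::makeBenchmarkSuite",
         shape = cfg@shape, volumes = entries),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
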