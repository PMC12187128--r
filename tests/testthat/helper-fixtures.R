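# Shared fixture builders (all generated in code; no binary files).

# Solid sphere mask in a given volume shape.
sphereMask <- function(d, centre, radius) {
  g <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  m <- array(FALSE, dim = d)
  m[g[rowSums(sweep(g, 2, centre)^2) <= radius^2, , drop = FALSE]] <- TRUE
  m
}

# Small, fast synthetic-volume configuration for desk-scale tests:
# high-contrast plateau nuclei on a clean background — the regime the
# self-supervised method assumes.
tinySynth <- function(seed, shape = c(32L, 32L, 32L), nCells = 15L,
                      radiusRange = c(3, 4.5), minSeparation = 9) {
  synthConfig(shape = shape, nCells = nCells, radiusRange = radiusRange,
              cellIntensityRange = c(0.55, 0.85), backgroundLevel = 0.08,
              psfSigma = 0.5, noiseSd = 0.003,
              minSeparation = minSeparation, seed = seed)
}

# Even smaller volumes for the fast training unit tests.
microSynth <- function(seed) {
  tinySynth(seed, shape = c(16L, 16L, 16L), nCells = 2L,
            radiusRange = c(2, 3), minSeparation = 6)
}

# CPU-scale training setup shared by the training tests.
tinyArch <- function() wnetArchitecture(features = c(8L, 16L, 32L))

tinyTrainConfig <- function(epochs, seed = 123L, patchSize = 16L) {
  trainConfig(epochs = epochs, batchSize = 2L, learningRate = 2e-3,
              wNCuts = 0.5, wRec = 5e-3, seed = seed,
              patchSize = patchSize)
}
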