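# Shared fixtures, built in code. Kept deliberately small so the whole
# suite stays CPU-friendly.

# A noise-free phantom config on a small grid: exact intensities, fast.
quietPhantomConfig <- function(...) {
  phantomConfig(volumeShape = c(48L, 48L, 48L), noiseSigma = 0,
                diameterRange = c(8, 12), ...)
}

# Bright-vs-dark toy patches: linearly separable on mean intensity.
toyPatches <- function(n = 32L, size = 64L, muBenign = -700, muMalignant = -300,
                       sigma = 100, seed = 2L) {
  set.seed(seed)
  mk <- function(mu, lab, i)
    PatchImage(matrix(stats::rnorm(size * size, mu, sigma), size, size),
               sourceCase = paste0(lab, i), label = lab,
               orientation = "axial", symmetryOp = "r0")
  c(lapply(seq_len(n), function(i) mk(muBenign, "benign", i)),
    lapply(seq_len(n), function(i) mk(muMalignant, "malignant", i)))
}

# An asymmetric test matrix (all dihedral images distinct).
asymMatrix <- function(s = 5L) matrix(seq_len(s * s) + sqrt(seq_len(s * s)), s, s)

asymPatch <- function(s = 5L)
  PatchImage(asymMatrix(s), sourceCase = "t", label = "benign",
             orientation = "axial", symmetryOp = "r0")

# A tiny WGAN config for contract tests.
tinyWGANConfig <- function(...) {
  wganConfig(widths = "tiny", batchSize = 16L, nCritic = 2L, seed = 1L, ...)
}
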