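# Shared fixtures, built in code at test time.

# Substrate used throughout: soft silicone, incompressible, 40x optics.
testSubstrate <- function() SubstrateModel(12000, 0.5, 0.16)

# Noiseless scene config for ground-truth recovery tests.
noiselessConfig <- function(seed, magnitude = 300, radius = 30,
                            imageDim = c(256, 256)) {
  sceneConfig(imageDim = imageDim, noiseGaussian = 0, noisePoisson = 0,
              pattern = list(kind = "inward_dipole", magnitude = magnitude,
                             radius = radius),
              seed = seed)
}

# Render a field of beads at given positions with controlled SNR
# (peak intensity / gaussian read-noise sd); SNR = Inf is noiseless.
renderAtSNR <- function(positions, imageDim, snr, seed) {
  renderBeads(positions, imageDim, psfSigma = 1.3, intensity = 1,
              background = 0.02,
              noiseGaussian = if (is.finite(snr)) 1 / snr else 0,
              seed = seed)
}

# Independent brute-force two-tailed Mann-Whitney p by enumeration of
# all group assignments of the pooled sample (tie-free data).
enumMannWhitneyP <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  r <- rank(pool)
  cmb <- utils::combn(length(pool), na)
  us <- apply(cmb, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  u0 <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u0), mean(us >= u0)))
}

# Smooth long-wavelength warp field (max ~2 px) used for tracking
# accuracy tests; gentle relative to the 61 px tracking window.
smoothWarp <- function(x, y) {
  cbind(2 * sin(2 * pi * x / 768) * cos(2 * pi * y / 1024),
        -1.5 * cos(2 * pi * x / 1024) * sin(2 * pi * y / 768))
}

# Uniformly seeded bead positions.
uniformBeads <- function(n, imageDim, seed) {
  set.seed(seed)
  cbind(x = runif(n, 5, imageDim[2] - 4), y = runif(n, 5, imageDim[1] - 4))
}
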