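# Independent oracles kept deliberately naive: they re-derive the quantities
# the package computes via a different route.

# O(N^2) discrete-Fourier summation, one-sided magnitude spectrum of a
# demeaned series.
dft_oracle <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  k <- 0:(n %/% 2)
  sapply(k, function(kk) {
    re <- sum(x * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * kk * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  })
}

# brute-force normal equations (X'X)^{-1} X'Y
ne_oracle <- function(X, Y) solve(t(X) %*% X, t(X) %*% Y)

# band spectra object from a raw nonnegative matrix (rows renormalized)
band_from_matrix <- function(mat, frequencies, fmin = min(frequencies)) {
  structure(list(power = mat / rowSums(mat), frequencies_hz = frequencies,
                 fmin_hz = fmin, normalized = TRUE,
                 tr = NULL, n_timepoints = NULL, voxel_index = NULL),
            class = "band_spectra")
}

# minimal PE-map object for metric tests (voxel-aligned vectors)
fake_pe_maps <- function(beta_c, p_beta_c,
                         beta_r = rep(0, length(beta_c)),
                         p_beta_r = rep(1, length(beta_c)),
                         alpha = rep(0, length(beta_c)),
                         p_alpha = rep(1, length(beta_c))) {
  n <- length(beta_c)
  structure(list(alpha = alpha, beta_r = beta_r, beta_c = beta_c,
                 p_alpha = p_alpha, p_beta_r = p_beta_r, p_beta_c = p_beta_c,
                 residual_rms = rep(0, n), dof = 10L, n_voxels = n, nb = 13L,
                 alternative = "two.sided"),
            class = "pe_maps")
}

# small synthetic dataset + normalized band spectra, reused across files
small_sim <- function(n_voxels = 80, n_volumes = 256, noise_scale = 0.3,
                      seed = 11, ...) {
  truth <- simulate_ground_truth(n_voxels = n_voxels, n_volumes = n_volumes,
                                 noise_scale = noise_scale, seed = seed, ...)
  dat <- simulate_epi_dataset(truth)
  sp <- band_normalize(amplitude_spectrum(dat$ts), fmin = truth$fmin)
  list(truth = truth, dat = dat, spectra = sp)
}
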