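#' Voxel time-series set
#'
#' Container for a set of masked EPI voxel time series sampled at a common
#' repetition time (TR).  Rows are voxels, columns are timepoints.
#'
#' @param data numeric matrix, voxels x timepoints (a vector is treated as a
#'   single voxel).
#' @param tr sampling interval (TR) in seconds.
#' @param voxel_index optional integer matrix (voxels x 3) of 3D coordinates
#'   into the source volume grid.
#' @return an object of class `"voxel_ts"`.
#' @export
voxel_ts <- function(data, tr, voxel_index = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (ncol(data) < 8L)
    stop("at least 8 timepoints are required, got ", ncol(data))
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite values in voxel row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (!is.null(voxel_index)) {
    voxel_index <- as.matrix(voxel_index)
    if (nrow(voxel_index) != nrow(data))
      stop("'voxel_index' must have one row per voxel")
  }
  structure(list(data = data, tr = tr, voxel_index = voxel_index),
            class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat("Voxel time-series set:", nrow(x$data), "voxels x", ncol(x$data),
      "timepoints, TR =", x$tr, "s (fs =",
      format(1 / x$tr, digits = 4), "Hz)\n")
  invisible(x)
}

#' One-sided frequency grid of a sampled time series
#'
#' Frequencies f_k = k / (N * TR) for k = 0 .. floor(N/2).  The grid runs
#' from 0 Hz up to the Nyquist frequency 1/(2 TR).
#'
#' @param n number of timepoints.
#' @param tr sampling interval in seconds.
#' @return an object of class `"frequency_grid"`: a list with
#'   `frequencies_hz`, `resolution_hz` (1/(N TR)) and `nyquist_hz` (1/(2 TR)).
#' @export
frequency_grid <- function(n, tr) {
  if (n < 8L) stop("at least 8 timepoints are required")
  if (tr <= 0) stop("'tr' must be positive")
  k <- 0:(n %/% 2L)
  structure(list(frequencies_hz = k / (n * tr),
                 resolution_hz = 1 / (n * tr),
                 nyquist_hz = 1 / (2 * tr)),
            class = "frequency_grid")
}

#' One-sided amplitude spectrum of voxel time series
#'
#' Removes each voxel's temporal mean and returns the magnitude of the
#' discrete Fourier transform, |FT(S)|, at the one-sided frequencies
#' f_0 = 0 .. f_{N/2} (Nyquist).  With `power = TRUE` the squared magnitude
#' is returned instead; the default follows the amplitude-spectrum reading
#' of the voxelwise spectral model.
#'
#' @param ts a [voxel_ts()] object.
#' @param power return |FT|^2 instead of |FT|.
#' @return class `"full_spectra"`: list with `amplitude` (voxels x
#'   frequencies, nonnegative), `grid` (a [frequency_grid()]), plus the TR,
#'   timepoint count and voxel index carried through from the input.
#' @export
amplitude_spectrum <- function(ts, power = FALSE) {
  stopifnot(inherits(ts, "voxel_ts"))
  x <- ts$data
  n <- ncol(x)
  x <- x - rowMeans(x)
  grid <- frequency_grid(n, ts$tr)
  nf <- length(grid$frequencies_hz)
  ft <- stats::mvfft(t(x))[seq_len(nf), , drop = FALSE]
  amp <- t(Mod(ft))
  if (power) amp <- amp^2
  structure(list(amplitude = amp, grid = grid, tr = ts$tr,
                 n_timepoints = n, voxel_index = ts$voxel_index),
            class = "full_spectra")
}

#' Restrict spectra to a frequency band and normalize each voxel to unit sum
#'
#' Keeps frequencies in \code{[fmin, nyquist]} and divides each voxel's row
#' by its band sum so that every row sums to 1.  The normalization makes
#' spectra comparable across voxels and subjects irrespective of absolute
#' signal level.
#'
#' @param spectra a `"full_spectra"` object from [amplitude_spectrum()], or a
#'   plain nonnegative matrix together with `grid`.
#' @param fmin lower band edge in Hz (default 0.2, excluding the
#'   low-frequency neurovascular regime).
#' @param grid a [frequency_grid()] (only needed when `spectra` is a matrix).
#' @return class `"band_spectra"`: list with `power` (voxels x band bins,
#'   rows summing to 1), `frequencies_hz`, `fmin_hz`, `normalized = TRUE`.
#' @export
band_normalize <- function(spectra, fmin = 0.2, grid = NULL) {
  if (inherits(spectra, "full_spectra")) {
    grid <- spectra$grid
    meta <- spectra[c("tr", "n_timepoints", "voxel_index")]
    mat <- spectra$amplitude
  } else {
    if (is.null(grid)) stop("'grid' is required for matrix input")
    meta <- list(tr = NULL, n_timepoints = NULL, voxel_index = NULL)
    mat <- as.matrix(spectra)
  }
  if (fmin >= grid$nyquist_hz)
    stop("'fmin' (", fmin, " Hz) must lie below the Nyquist frequency (",
         format(grid$nyquist_hz, digits = 4), " Hz)")
  sel <- which(grid$frequencies_hz >= fmin)  # one-sided grid tops out at Nyquist
  if (length(sel) < 4L)
    stop("fewer than 4 frequency bins in the band [", fmin, ", ",
         format(grid$nyquist_hz, digits = 4), "] Hz")
  band <- mat[, sel, drop = FALSE]
  if (any(band < 0)) stop("spectra must be nonnegative")
  s <- rowSums(band)
  zero <- which(s <= 0)
  if (length(zero))
    stop("zero band power in voxel row(s) ",
         paste(utils::head(zero, 5L), collapse = ", "),
         "; exclude them from the mask before normalizing")
  structure(c(list(power = band / s,
                   frequencies_hz = grid$frequencies_hz[sel],
                   fmin_hz = fmin, normalized = TRUE),
              meta),
            class = "band_spectra")
}

#' @export
print.band_spectra <- function(x, ...) {
  cat("Band spectra:", nrow(x$power), "voxels x", ncol(x$power),
      "frequency bins in [", format(x$fmin_hz, digits = 3), ",",
      format(max(x$frequencies_hz), digits = 4), "] Hz",
      if (isTRUE(x$normalized)) "(unit-sum normalized)", "\n")
  invisible(x)
}

#' Externally recorded physiological trace
#'
#' @param samples numeric waveform samples.
#' @param sampling_rate_hz sampling rate in Hz (e.g. 1000 for typical
#'   pulse-oximetry / respiratory-belt recordings).
#' @param modality `"cardiac"` or `"respiratory"`.
#' @return class `"physio_trace"`.
#' @export
physio_trace <- function(samples, sampling_rate_hz,
                         modality = c("cardiac", "respiratory")) {
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be positive")
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 modality = modality),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d samples at %g Hz (%.1f s)\n",
              x$modality, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Sub-sample a physiological trace to the EPI repetition time
#'
#' Takes one trace value per EPI volume at the volume onset times
#' t_i = (i-1) * TR, by nearest-sample decimation (no anti-alias filtering:
#' aliasing of above-Nyquist physiological harmonics into the sampled band
#' is part of the modelled physics).
#'
#' @param trace a [physio_trace()].
#' @param tr EPI repetition time in seconds.
#' @param n_volumes number of EPI volumes.
#' @return a single-row [voxel_ts()].
#' @export
subsample_trace <- function(trace, tr, n_volumes) {
  stopifnot(inherits(trace, "physio_trace"))
  avail <- length(trace$samples) / trace$sampling_rate_hz
  need <- n_volumes * tr
  if (avail < need - 1e-9)
    stop(sprintf(
      "trace too short: %.3f s required for %d volumes at TR %.3f s, %.3f s available",
      need, n_volumes, tr, avail))
  idx <- round((0:(n_volumes - 1L)) * tr * trace$sampling_rate_hz) + 1L
  idx <- pmin(idx, length(trace$samples))
  voxel_ts(trace$samples[idx], tr = tr)
}

#' Frequency bin carrying maximal spectral power
#'
#' Ties are broken toward the lowest frequency.
#'
#' @param power numeric vector (one spectrum) or matrix (voxels x bins).
#' @param frequencies_hz frequencies corresponding to the bins.
#' @return the dominant frequency (one value per spectrum row).
#' @export
dominant_frequency <- function(power, frequencies_hz) {
  if (is.matrix(power)) {
    if (ncol(power) == 0L) stop("empty frequency band")
    stopifnot(ncol(power) == length(frequencies_hz))
    return(frequencies_hz[apply(power, 1L, which.max)])
  }
  if (length(power) == 0L) stop("empty frequency band")
  stopifnot(length(power) == length(frequencies_hz))
  frequencies_hz[which.max(power)]
}

#' Alias of a true frequency under sampling
#'
#' Folds a true frequency into the sampled band \code{[0, f_sample/2]}
#' according to \code{f_alias = |f_true - n * f_sample|} with the integer n
#' that places the result at or below the Nyquist frequency.
#'
#' @param f_true_hz true frequency (vectorized), >= 0.
#' @param f_sample_hz sampling frequency, > 0.
#' @return aliased frequency in `[0, f_sample_hz / 2]`.
#' @export
alias_frequency <- function(f_true_hz, f_sample_hz) {
  if (any(f_true_hz < 0)) stop("'f_true_hz' must be >= 0")
  if (f_sample_hz <= 0) stop("'f_sample_hz' must be > 0")
  a <- f_true_hz %% f_sample_hz
  pmin(a, f_sample_hz - a)
}

#' Spectral regressors for the voxelwise spectral model
#'
#' The three explanatory spectra of the model: a constant-1 thermal-noise
#' baseline, a respiratory spectrum `xr` and a cardiac spectrum `xc`, each
#' defined over the analysis band and (xr, xc) normalized to unit band sum.
#'
#' @param xc cardiac amplitude spectrum over the band (nonnegative).
#' @param xr respiratory amplitude spectrum over the band (nonnegative).
#' @param frequencies_hz band frequencies.
#' @param normalize divide `xc` and `xr` by their sums (default TRUE).
#' @return class `"spectral_regressors"`.
#' @export
spectral_regressors <- function(xc, xr, frequencies_hz, normalize = TRUE) {
  if (length(xc) != length(frequencies_hz) ||
      length(xr) != length(frequencies_hz))
    stop("'xc' and 'xr' must match the length of 'frequencies_hz'")
  if (any(xc < 0) || any(xr < 0))
    stop("regressor spectra must be nonnegative")
  if (normalize) {
    if (sum(xc) <= 0 || sum(xr) <= 0)
      stop("cannot normalize an all-zero regressor spectrum")
    xc <- xc / sum(xc)
    xr <- xr / sum(xr)
  } else {
    if (abs(sum(xc) - 1) > 1e-9 || abs(sum(xr) - 1) > 1e-9)
      stop("'xc' and 'xr' must each sum to 1 (or use normalize = TRUE)")
  }
  structure(list(baseline = rep(1, length(frequencies_hz)),
                 xr = as.numeric(xr), xc = as.numeric(xc),
                 frequencies_hz = as.numeric(frequencies_hz)),
            class = "spectral_regressors")
}

#' @export
print.spectral_regressors <- function(x, ...) {
  cat("Spectral regressors over", length(x$frequencies_hz), "band bins [",
      format(min(x$frequencies_hz), digits = 3), ",",
      format(max(x$frequencies_hz), digits = 4), "] Hz\n")
  cat("  dominant cardiac frequency:    ",
      format(dominant_frequency(x$xc, x$frequencies_hz), digits = 4), "Hz\n")
  cat("  dominant respiratory frequency:",
      format(dominant_frequency(x$xr, x$frequencies_hz), digits = 4), "Hz\n")
  invisible(x)
}
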