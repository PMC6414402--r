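#' Simulate external cardiac and respiratory recordings
#'
#' Quasi-periodic waveforms emulating pulse-oximetry and respiratory-pad
#' recordings: a fundamental plus decaying harmonics whose instantaneous
#' frequency drifts slowly around the mean rate.  Deterministic under
#' `seed`.
#'
#' @param duration_s recording duration in seconds.
#' @param sampling_rate_hz trace sampling rate (default 1000 Hz).
#' @param cardiac_rate_hz mean cardiac rate (default 1.1 Hz, i.e. 66 bpm).
#' @param cardiac_drift_hz amplitude of the slow cardiac-rate drift.
#' @param resp_rate_hz mean respiratory rate (default 0.3 Hz).
#' @param resp_drift_hz amplitude of the slow respiratory-rate drift.
#' @param n_harmonics number of harmonics (1 = pure tone).
#' @param drift_freq_hz frequency of the slow rate modulation.
#' @param seed optional RNG seed.
#' @return list with [physio_trace()] elements `cardiac` and `respiratory`.
#' @export
simulate_physio_traces <- function(duration_s, sampling_rate_hz = 1000,
                                   cardiac_rate_hz = 1.1,
                                   cardiac_drift_hz = 0.05,
                                   resp_rate_hz = 0.3,
                                   resp_drift_hz = 0.02,
                                   n_harmonics = 3L,
                                   drift_freq_hz = 0.01,
                                   seed = NULL) {
  stopifnot(duration_s > 0, sampling_rate_hz > 0, n_harmonics >= 1L)
  if (cardiac_rate_hz < 0.7 || cardiac_rate_hz > 2)
    warning("cardiac rate ", cardiac_rate_hz,
            " Hz is outside the usual physiological range (0.7-2 Hz)")
  if (resp_rate_hz < 0.15 || resp_rate_hz > 0.5)
    warning("respiratory rate ", resp_rate_hz,
            " Hz is outside the usual physiological range (0.15-0.5 Hz)")
  if (!is.null(seed)) set.seed(seed)
  ns <- ceiling(duration_s * sampling_rate_hz)
  t <- (0:(ns - 1L)) / sampling_rate_hz
  wave <- function(f0, drift) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    finst <- f0 + drift * sin(2 * pi * drift_freq_hz * t + phi0)
    phase <- 2 * pi * cumsum(finst) / sampling_rate_hz
    sig <- 0
    for (h in seq_len(n_harmonics))
      sig <- sig + cos(h * phase + stats::runif(1, 0, 2 * pi)) / h
    sig
  }
  list(cardiac = physio_trace(wave(cardiac_rate_hz, cardiac_drift_hz),
                              sampling_rate_hz, "cardiac"),
       respiratory = physio_trace(wave(resp_rate_hz, resp_drift_hz),
                                  sampling_rate_hz, "respiratory"))
}

#' Ground truth for a synthetic fast-TR EPI dataset
#'
#' Draws the generating state of a synthetic scan: external physiological
#' traces, the regressor spectra they imply at the EPI sampling rate
#' (including any aliasing of above-Nyquist harmonics), per-voxel
#' coefficient maps satisfying the unit-sum coupling
#' \eqn{\alpha N_b + \beta_r + \beta_c = 1}, and a partial-volume map.
#' Defaults mirror a fast-TR 7T protocol: TR 0.328 s and 2200 volumes
#' (about 12 min of data).
#'
#' @param shape 3D grid dimensions; the voxel count is `prod(shape)`.
#' @param n_voxels shortcut for `shape = c(n_voxels, 1, 1)`.
#' @param tr repetition time in seconds (default 0.328).
#' @param n_volumes number of EPI volumes (default 2200).
#' @param fmin analysis-band lower edge in Hz (default 0.2).
#' @param frac_cardiac,frac_resp fraction of voxels carrying cardiac /
#'   respiratory modulation.
#' @param assignment `"independent"` draws the cardiac and respiratory
#'   voxel sets independently; `"co_occurring"` makes a single "perfused"
#'   voxel set (fraction `frac_cardiac`) carry both modulations, as in
#'   tissue where physiological power travels with blood, CSF and chest
#'   motion together.
#' @param beta_c_range,beta_r_range uniform ranges for the nonzero
#'   coefficients.
#' @param noise_scale per-bin spectral noise, relative to the flat thermal
#'   floor (default 0.3; 0 gives an exact noiseless instance).
#' @param amp overall spectral amplitude scale (arbitrary signal units).
#' @param seed RNG seed (required: the truth is the seed's deterministic
#'   function).
#' @inheritParams simulate_physio_traces
#' @return class `"physio_truth"`.
#' @export
simulate_ground_truth <- function(shape = c(8L, 8L, 4L), n_voxels = NULL,
                                  tr = 0.328, n_volumes = 2200L, fmin = 0.2,
                                  cardiac_rate_hz = 1.1,
                                  cardiac_drift_hz = 0.05,
                                  resp_rate_hz = 0.3, resp_drift_hz = 0.02,
                                  n_harmonics = 3L,
                                  frac_cardiac = 0.4, frac_resp = 0.4,
                                  assignment = c("independent",
                                                 "co_occurring"),
                                  beta_c_range = c(0.1, 0.4),
                                  beta_r_range = c(0.1, 0.4),
                                  noise_scale = 0.3, amp = 100,
                                  seed = 1L) {
  if (!is.null(n_voxels)) shape <- c(as.integer(n_voxels), 1L, 1L)
  n <- prod(shape)
  if (n < 4L) stop("need at least 4 voxels")
  fs <- 1 / tr
  if (cardiac_rate_hz * n_harmonics > fs / 2)
    message("cardiac harmonics above the EPI Nyquist frequency (",
            format(fs / 2, digits = 4), " Hz) will alias into the band")
  set.seed(seed)
  traces <- simulate_physio_traces(
    duration_s = n_volumes * tr + 1,
    cardiac_rate_hz = cardiac_rate_hz, cardiac_drift_hz = cardiac_drift_hz,
    resp_rate_hz = resp_rate_hz, resp_drift_hz = resp_drift_hz,
    n_harmonics = n_harmonics)
  regressors <- informed_init(traces$cardiac, traces$respiratory,
                              tr = tr, n_volumes = n_volumes, fmin = fmin)
  assignment <- match.arg(assignment)
  nb <- length(regressors$frequencies_hz)
  if (assignment == "co_occurring") {
    has_c <- has_r <- stats::runif(n) < frac_cardiac
  } else {
    has_c <- stats::runif(n) < frac_cardiac
    has_r <- stats::runif(n) < frac_resp
  }
  beta_c <- ifelse(has_c, stats::runif(n, beta_c_range[1], beta_c_range[2]), 0)
  beta_r <- ifelse(has_r, stats::runif(n, beta_r_range[1], beta_r_range[2]), 0)
  alpha <- (1 - beta_c - beta_r) / nb
  pve <- stats::runif(n, 0.2, 1)
  structure(list(regressors = regressors, alpha = alpha, beta_r = beta_r,
                 beta_c = beta_c, pve = pve, shape = shape,
                 tr = tr, n_volumes = as.integer(n_volumes), fmin = fmin,
                 cardiac_rate_hz = cardiac_rate_hz,
                 cardiac_drift_hz = cardiac_drift_hz,
                 resp_rate_hz = resp_rate_hz,
                 noise_scale = noise_scale, amp = amp,
                 traces = traces, seed = seed),
            class = "physio_truth")
}

#' @export
print.physio_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d voxels (%s), TR %g s, %d volumes, seed %d\n",
              prod(x$shape), paste(x$shape, collapse = "x"), x$tr,
              x$n_volumes, x$seed))
  cat(sprintf("  cardiac %g Hz, respiratory %g Hz, noise scale %g\n",
              x$cardiac_rate_hz, x$resp_rate_hz, x$noise_scale))
  cat(sprintf("  %d cardiac-modulated, %d respiratory-modulated voxels\n",
              sum(x$beta_c > 0), sum(x$beta_r > 0)))
  invisible(x)
}

#' Simulate a fast-TR EPI dataset from a ground truth
#'
#' Synthesizes voxel time series whose band amplitude spectra follow the
#' three-regressor spectral model exactly by construction: per voxel the
#' band amplitude is assembled as
#' \eqn{amp \cdot (\alpha + \beta_r X_r(f) + \beta_c X_c(f))},
#' random phases are drawn, and the one-sided spectrum is
#' inverse-transformed to a real time series.  A low-frequency
#' "neurovascular" component below 0.1 Hz exercises the band cut, and
#' per-bin Gaussian amplitude noise (relative scale `noise_scale`)
#' represents the realization variability of the thermal floor.
#' Deterministic under the truth's seed.
#'
#' @param truth a [simulate_ground_truth()] object.
#' @return class `"physio_sim"`: list with `ts` (a [voxel_ts()]), `mask`
#'   (a [tissue_mask()]), `cardiac` and `respiratory` traces, and `truth`.
#' @export
simulate_epi_dataset <- function(truth) {
  stopifnot(inherits(truth, "physio_truth"))
  set.seed(truth$seed + 1L)
  n <- prod(truth$shape)
  N <- truth$n_volumes
  grid <- frequency_grid(N, truth$tr)
  f <- grid$frequencies_hz
  nf <- length(f)
  nb <- length(truth$regressors$frequencies_hz)
  band <- which(f >= truth$fmin)
  stopifnot(length(band) == nb)

  # per-voxel one-sided amplitudes (voxels x frequencies)
  A <- matrix(0, n, nf)
  A[, -1L] <- truth$amp * truth$alpha               # thermal floor everywhere
  lowf <- which(f > 0 & f < 0.1)
  A[, lowf] <- A[, lowf] + truth$amp * 8 / nb       # neurovascular regime
  A[, band] <- truth$amp *
    (truth$alpha +
     truth$beta_r %o% truth$regressors$xr +
     truth$beta_c %o% truth$regressors$xc)
  if (truth$noise_scale > 0) {
    A[, -1L] <- pmax(A[, -1L] +
      matrix(stats::rnorm(n * (nf - 1L), 0,
                          truth$noise_scale * truth$amp / nb), n, nf - 1L), 0)
  }

  # hermitian spectrum -> real time series whose |FFT| reproduces A exactly
  phase <- matrix(stats::runif(n * nf, 0, 2 * pi), n, nf)
  phase[, 1L] <- 0
  even <- N %% 2L == 0L
  if (even) phase[, nf] <- sample(c(0, pi), n, replace = TRUE)
  Z <- matrix(0i, N, n)
  Z[seq_len(nf), ] <- t(A * exp(1i * phase))
  conj_rows <- if (even) seq(2L, nf - 1L) else seq(2L, nf)
  Z[N + 2L - conj_rows, ] <- Conj(Z[conj_rows, ])
  X <- Re(stats::mvfft(Z, inverse = TRUE)) / N

  ts <- voxel_ts(t(X), tr = truth$tr,
                 voxel_index = arrayInd(seq_len(n), truth$shape))
  structure(list(ts = ts,
                 mask = tissue_mask(truth$pve, label = "grey"),
                 cardiac = truth$traces$cardiac,
                 respiratory = truth$traces$respiratory,
                 truth = truth),
            class = "physio_sim")
}

#' @export
print.physio_sim <- function(x, ...) {
  cat("Synthetic fast-TR EPI dataset\n")
  print(x$ts)
  print(x$mask)
  invisible(x)
}
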