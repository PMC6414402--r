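#' Initial regressor spectra from external physiological recordings
#'
#' Builds the "informed" initial guess: each externally recorded trace is
#' sub-sampled to the EPI repetition time (so that above-Nyquist harmonics
#' alias exactly as they do in the EPI data), magnitude-spectrum
#' transformed, restricted to the analysis band and normalized to unit sum.
#'
#' @param cardiac,respiratory [physio_trace()] recordings covering the scan.
#' @param tr EPI repetition time in seconds.
#' @param n_volumes number of EPI volumes.
#' @param fmin lower band edge in Hz.
#' @return a [spectral_regressors()] object.
#' @export
informed_init <- function(cardiac, respiratory, tr, n_volumes, fmin = 0.2) {
  stopifnot(inherits(cardiac, "physio_trace"),
            inherits(respiratory, "physio_trace"))
  band_of <- function(trace) {
    ts <- subsample_trace(trace, tr, n_volumes)
    band_normalize(amplitude_spectrum(ts), fmin = fmin)
  }
  bc <- band_of(cardiac)
  br <- band_of(respiratory)
  spectral_regressors(xc = bc$power[1L, ], xr = br$power[1L, ],
                      frequencies_hz = bc$frequencies_hz)
}

#' Initial regressor spectra from the EPI data themselves
#'
#' Builds the "data-driven" initial guess from the mask-average EPI band
#' spectrum: bins at or below `split_hz` seed the respiratory spectrum and
#' bins above it seed the cardiac spectrum (each zeroed outside its side and
#' renormalized).  The subsequent dual-regression iterations are free to
#' move mass across the split, so respiratory harmonics above it and aliased
#' cardiac components below it can reappear in the refined spectra.
#'
#' @param spectra a normalized [band_normalize()] result.
#' @param split_hz frequency separating the respiratory (<=) and cardiac (>)
#'   seed regimes; default 0.6 Hz.
#' @return a [spectral_regressors()] object.
#' @export
data_driven_init <- function(spectra, split_hz = 0.6) {
  stopifnot(inherits(spectra, "band_spectra"))
  f <- spectra$frequencies_hz
  avg <- colMeans(spectra$power)
  lo <- f <= split_hz
  xr <- ifelse(lo, avg, 0)
  xc <- ifelse(lo, 0, avg)
  if (sum(xr) <= 0 || sum(xc) <= 0)
    stop("all spectral mass lies on one side of the ", split_hz,
         " Hz split; cannot seed both regressors")
  spectral_regressors(xc = xc, xr = xr, frequencies_hz = f)
}

#' Refine regressor spectra by a GLM along the frequency dimension
#'
#' The complement of [fit_spatial_glm()]: holding the per-voxel parameter
#' estimates fixed, solves per frequency bin the least-squares system
#' \deqn{P[s, f] \approx \alpha[s] b[f] + \beta_r[s] X_r[f] + \beta_c[s] X_c[f]}
#' jointly for the three spectral rows.  The baseline row is then reset to
#' the constant-1 vector (a non-flat thermal baseline would contradict the
#' model's premise), negative entries of the refined physiological spectra
#' are clipped to zero (amplitude spectra are nonnegative), and each is
#' renormalized to unit band sum so the coefficient scale is stable across
#' iterations.
#'
#' @param spectra a normalized [band_normalize()] result (>= 4 voxels).
#' @param pe_maps a [fit_spatial_glm()] result for the same voxels.
#' @param reset_baseline reset the refined baseline row to constant 1
#'   (default TRUE; FALSE retained for sensitivity checks).
#' @param raw return the raw 3 x Nb least-squares solution (rows baseline,
#'   respiratory, cardiac) before the reset/clip/renormalize steps.
#' @return a [spectral_regressors()] object, or a matrix when `raw = TRUE`.
#' @export
refine_spectra <- function(spectra, pe_maps, reset_baseline = TRUE,
                           raw = FALSE) {
  stopifnot(inherits(spectra, "band_spectra"), inherits(pe_maps, "pe_maps"))
  P <- spectra$power                            # voxels x Nb
  if (nrow(P) < 4L) stop("need at least 4 voxels, got ", nrow(P))
  A <- cbind(pe_maps$alpha, pe_maps$beta_r, pe_maps$beta_c)
  if (nrow(A) != nrow(P))
    stop("PE maps and spectra have different voxel counts")
  qrA <- qr(A)
  if (qrA$rank < 3L)
    stop("rank-deficient PE matrix (condition number ",
         format(kappa(A), digits = 4),
         "): the coefficient maps do not span three directions")
  rows <- qr.coef(qrA, P)                       # 3 x Nb
  rownames(rows) <- c("baseline", "respiratory", "cardiac")
  if (raw) return(rows)
  xr <- pmax(rows[2L, ], 0)
  xc <- pmax(rows[3L, ], 0)
  if (sum(xr) <= 0 || sum(xc) <= 0)
    stop("refined ", if (sum(xr) <= 0) "respiratory" else "cardiac",
         " spectrum is all-zero after clipping negatives")
  out <- spectral_regressors(xc = xc, xr = xr,
                             frequencies_hz = spectra$frequencies_hz)
  if (!reset_baseline) out$baseline <- rows[1L, ]
  out
}

#' Iterative dual regression of EPI band spectra
#'
#' The main fitting function.  Alternates between the spatial GLM
#' ([fit_spatial_glm()]: regressor spectra -> per-voxel coefficient maps)
#' and the frequency GLM ([refine_spectra()]: coefficient maps -> refined
#' spectra), starting from either externally informed or data-driven initial
#' regressors, until the sum of absolute changes between successive refined
#' spectra falls below `tolerance` for the cardiac and respiratory spectra
#' separately.  The final coefficient maps are refit against the converged
#' regressors.
#'
#' @param spectra a normalized [band_normalize()] result.
#' @param init optional [spectral_regressors()] initial guess; when given,
#'   `mode` is ignored.
#' @param mode `"data_driven"` (band-split seed from the EPI spectra, the
#'   default) or `"informed"` (requires `cardiac` and `respiratory` traces).
#' @param cardiac,respiratory [physio_trace()] recordings (informed mode).
#' @param split_hz respiratory/cardiac split for the data-driven seed.
#' @param tolerance convergence threshold on the L1 change of each refined
#'   spectrum between iterations (default 0.01).
#' @param max_iter iteration cap (default 50); hitting it yields
#'   `converged = FALSE`, not an error.
#' @param alternative significance sidedness passed to [fit_spatial_glm()].
#' @return an object of class `"dualreg"` with components `regressors`
#'   (final [spectral_regressors()]), `pe_maps` (final [fit_spatial_glm()]
#'   maps), `n_iterations`, `change_trace` (per-iteration L1 change, columns
#'   `respiratory` and `cardiac`), `converged`, `init_mode`, and the inputs
#'   needed by the methods.
#' @seealso [summary.dualreg()], [coef.dualreg()], [fitted.dualreg()],
#'   [metrics_report()]
#' @examples
#' truth <- simulate_ground_truth(n_voxels = 60, n_volumes = 128, seed = 1)
#' dat <- simulate_epi_dataset(truth)
#' sp <- band_normalize(amplitude_spectrum(dat$ts), fmin = truth$fmin)
#' fit <- dualreg(sp, mode = "data_driven")
#' fit
#' @export
dualreg <- function(spectra, init = NULL,
                    mode = c("data_driven", "informed"),
                    cardiac = NULL, respiratory = NULL, split_hz = 0.6,
                    tolerance = 0.01, max_iter = 50L,
                    alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(spectra, "band_spectra"))
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  if (!is.null(init)) {
    stopifnot(inherits(init, "spectral_regressors"))
    init_mode <- "custom"
  } else {
    mode <- match.arg(mode)
    init_mode <- mode
    init <- switch(mode,
      data_driven = data_driven_init(spectra, split_hz = split_hz),
      informed = {
        if (is.null(cardiac) || is.null(respiratory))
          stop("informed mode requires 'cardiac' and 'respiratory' traces")
        if (is.null(spectra$tr) || is.null(spectra$n_timepoints))
          stop("spectra carry no TR/timepoint metadata; ",
               "build the init with informed_init() instead")
        informed_init(cardiac, respiratory, tr = spectra$tr,
                      n_volumes = spectra$n_timepoints,
                      fmin = spectra$fmin_hz)
      })
  }
  if (length(init$frequencies_hz) != ncol(spectra$power))
    stop("initial regressors and spectra are on different bands")

  reg <- init
  trace <- matrix(NA_real_, nrow = max_iter, ncol = 2L,
                  dimnames = list(NULL, c("respiratory", "cardiac")))
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    pe <- fit_spatial_glm(spectra, reg, alternative = alternative)
    new_reg <- refine_spectra(spectra, pe)
    trace[i, "respiratory"] <- sum(abs(new_reg$xr - reg$xr))
    trace[i, "cardiac"]     <- sum(abs(new_reg$xc - reg$xc))
    reg <- new_reg
    if (trace[i, "cardiac"] < tolerance &&
        trace[i, "respiratory"] < tolerance) {
      converged <- TRUE
      break
    }
  }
  n_iter <- if (converged) i else max_iter
  pe <- fit_spatial_glm(spectra, reg, alternative = alternative)
  structure(list(regressors = reg, pe_maps = pe,
                 n_iterations = n_iter,
                 change_trace = trace[seq_len(n_iter), , drop = FALSE],
                 converged = converged, init_mode = init_mode,
                 init = init, tolerance = tolerance, max_iter = max_iter,
                 spectra = spectra, call = match.call()),
            class = "dualreg")
}

#' @export
print.dualreg <- function(x, ...) {
  cat("Iterative dual regression of EPI band spectra\n")
  cat(sprintf("  %d voxels, %d band bins in [%.3g, %.4g] Hz, init: %s\n",
              x$pe_maps$n_voxels, x$pe_maps$nb, x$spectra$fmin_hz,
              max(x$spectra$frequencies_hz), x$init_mode))
  cat(sprintf("  %s after %d iteration(s) (tolerance %g; final L1 change: cardiac %.3g, respiratory %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$tolerance,
              x$change_trace[x$n_iterations, "cardiac"],
              x$change_trace[x$n_iterations, "respiratory"]))
  invisible(x)
}

#' Summary of a dual-regression fit
#'
#' @param object a [dualreg()] fit.
#' @param p_threshold per-voxel significance threshold for the counts.
#' @param ... unused.
#' @return class `"summary.dualreg"`.
#' @export
summary.dualreg <- function(object, p_threshold = 0.01, ...) {
  pe <- object$pe_maps
  f <- object$regressors$frequencies_hz
  structure(list(fit = object, p_threshold = p_threshold,
                 n_sig_cardiac = sum(pe$p_beta_c < p_threshold),
                 n_sig_resp = sum(pe$p_beta_r < p_threshold),
                 mean_pe = c(alpha = mean(pe$alpha),
                             beta_r = mean(pe$beta_r),
                             beta_c = mean(pe$beta_c)),
                 dominant_cardiac_hz = dominant_frequency(object$regressors$xc, f),
                 dominant_resp_hz = dominant_frequency(object$regressors$xr, f)),
            class = "summary.dualreg")
}

#' @export
print.summary.dualreg <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  dominant frequencies: cardiac %.4g Hz, respiratory %.4g Hz\n",
              x$dominant_cardiac_hz, x$dominant_resp_hz))
  cat(sprintf("  significant at p < %g: cardiac %d/%d, respiratory %d/%d voxels\n",
              x$p_threshold, x$n_sig_cardiac, x$fit$pe_maps$n_voxels,
              x$n_sig_resp, x$fit$pe_maps$n_voxels))
  cat(sprintf("  mean PEs: alpha %.3g, beta_r %.3g, beta_c %.3g\n",
              x$mean_pe["alpha"], x$mean_pe["beta_r"], x$mean_pe["beta_c"]))
  invisible(x)
}

#' @export
coef.dualreg <- function(object, ...) coef(object$pe_maps)

#' @export
fitted.dualreg <- function(object, ...) {
  X <- cbind(object$regressors$baseline, object$regressors$xr,
             object$regressors$xc)
  B <- t(coef(object))
  t(X %*% B)
}

#' @export
residuals.dualreg <- function(object, ...) {
  object$spectra$power - fitted(object)
}

#' Coefficient maps for new spectra under the converged regressors
#'
#' @param object a [dualreg()] fit.
#' @param newspectra a normalized [band_normalize()] result on the same
#'   band; defaults to the fitted spectra.
#' @param ... unused.
#' @return a `"pe_maps"` object.
#' @export
predict.dualreg <- function(object, newspectra = NULL, ...) {
  if (is.null(newspectra)) return(object$pe_maps)
  fit_spatial_glm(newspectra, object$regressors,
                  alternative = object$pe_maps$alternative)
}

#' Plot a dual-regression fit
#'
#' Left panel: the converged cardiac and respiratory regressor spectra over
#' the analysis band (dashed: the initial guesses).  Right panel: the
#' per-iteration L1 change of each refined spectrum with the convergence
#' tolerance.
#'
#' @param x a [dualreg()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dualreg <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  f <- x$regressors$frequencies_hz
  graphics::matplot(f, cbind(x$regressors$xc, x$regressors$xr,
                             x$init$xc, x$init$xr),
                    type = "l", lty = c(1, 1, 2, 2),
                    col = c("firebrick", "steelblue", "firebrick", "steelblue"),
                    xlab = "frequency (Hz)", ylab = "normalized amplitude",
                    main = "Refined spectra", ...)
  graphics::legend("topright", bty = "n", lty = c(1, 1, 2),
                   col = c("firebrick", "steelblue", "grey40"),
                   legend = c("cardiac", "respiratory", "initial"))
  it <- seq_len(x$n_iterations)
  graphics::matplot(it, x$change_trace, type = "b", pch = 1, log = "y",
                    col = c("steelblue", "firebrick"), lty = 1,
                    xlab = "iteration", ylab = "L1 change",
                    main = "Convergence")
  graphics::abline(h = x$tolerance, lty = 3)
  invisible(x)
}
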