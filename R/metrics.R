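#' Tissue mask from partial-volume estimates
#'
#' Mask membership is `pve > threshold` (strict inequality).
#'
#' @param pve per-voxel partial-volume estimates in `[0, 1]`.
#' @param threshold minimum PVE (default 0.7).
#' @param label tissue label.
#' @return class `"tissue_mask"` with `pve`, `threshold`, `label` and the
#'   logical `members` vector.
#' @export
tissue_mask <- function(pve, threshold = 0.7,
                        label = c("grey", "white", "other")) {
  label <- match.arg(label)
  pve <- as.numeric(pve)
  if (any(!is.finite(pve)) || any(pve < 0) || any(pve > 1))
    stop("PVE values must be finite and in [0, 1]")
  structure(list(pve = pve, threshold = threshold, label = label,
                 members = pve > threshold),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("%s-matter mask: %d / %d voxels with PVE > %g\n",
              x$label, sum(x$members), length(x$pve), x$threshold))
  invisible(x)
}

pick_pe <- function(pe_maps, which) {
  switch(which,
         alpha  = list(beta = pe_maps$alpha,  p = pe_maps$p_alpha),
         beta_r = list(beta = pe_maps$beta_r, p = pe_maps$p_beta_r),
         beta_c = list(beta = pe_maps$beta_c, p = pe_maps$p_beta_c))
}

#' PVE-weighted mean parameter estimate over significant mask voxels
#'
#' \deqn{\langle\beta\rangle = \sum_{PVE>0.7,\ p<0.01} \beta \cdot PVE \Big/
#'       \sum_{PVE>0.7,\ p<0.01} PVE}
#' Only voxels passing both the tissue-mask PVE threshold and the per-voxel
#' significance threshold contribute; the PVE weighting compensates
#' age-related partial-volume differences.
#'
#' @param pe_maps a [fit_spatial_glm()] result (voxel-aligned with `mask`).
#' @param mask a [tissue_mask()].
#' @param which coefficient: `"beta_c"`, `"beta_r"` or `"alpha"`.
#' @param p_threshold per-voxel significance threshold (default 0.01).
#' @return the weighted mean, with attribute `n_selected`.  An empty
#'   selection returns `NA` (with `n_selected = 0`), never 0.
#' @export
mean_pe <- function(pe_maps, mask, which = c("beta_c", "beta_r", "alpha"),
                    p_threshold = 0.01) {
  which <- match.arg(which)
  stopifnot(inherits(pe_maps, "pe_maps"), inherits(mask, "tissue_mask"))
  if (length(mask$pve) != pe_maps$n_voxels)
    stop("mask and PE maps are not voxel-aligned")
  v <- pick_pe(pe_maps, which)
  sel <- mask$members & v$p < p_threshold
  if (!any(sel))
    return(structure(NA_real_, n_selected = 0L))
  w <- mask$pve[sel]
  structure(sum(v$beta[sel] * w) / sum(w), n_selected = sum(sel))
}

#' Spatial extent of significant physiological modulation
#'
#' The PVE-weighted fraction of the tissue mask showing significant
#' modulation:
#' \deqn{R = \sum_{PVE>0.7,\ p<0.01} PVE \Big/ \sum_{PVE>0.7} PVE.}
#'
#' @inheritParams mean_pe
#' @param which coefficient: `"beta_c"` or `"beta_r"`.
#' @return a ratio in `[0, 1]`.
#' @export
spatial_extent <- function(pe_maps, mask, which = c("beta_c", "beta_r"),
                           p_threshold = 0.01) {
  which <- match.arg(which)
  stopifnot(inherits(pe_maps, "pe_maps"), inherits(mask, "tissue_mask"))
  if (length(mask$pve) != pe_maps$n_voxels)
    stop("mask and PE maps are not voxel-aligned")
  if (!any(mask$members)) stop("empty tissue mask")
  v <- pick_pe(pe_maps, which)
  sel <- mask$members & v$p < p_threshold
  sum(mask$pve[sel]) / sum(mask$pve[mask$members])
}

#' Windowed cardiac pulsatility metric
#'
#' The mean normalized band power in a fixed-width frequency window centred
#' at the dominant frequency of the externally measured cardiac spectrum,
#' averaged over the selected voxels.  The window is clipped at the band
#' edges.  Operating on unit-sum normalized spectra makes the metric
#' comparable across voxels and subjects; set `normalized = FALSE` on the
#' input spectra upstream to use raw magnitudes.
#'
#' @param spectra a [band_normalize()] result.
#' @param external a [spectral_regressors()] holding the external cardiac
#'   spectrum (its `xc` defines the window centre); alternatively a single
#'   numeric frequency in Hz.
#' @param voxels optional logical or integer subset of voxels (e.g. the
#'   tissue mask, or the significant-cardiac voxels); default all.
#' @param window_hz full window width in Hz (default 0.04).
#' @return the voxel-average windowed mean power, with attributes `n_bins`
#'   and `n_voxels`.
#' @export
pulsatility_metric <- function(spectra, external, voxels = NULL,
                               window_hz = 0.04) {
  stopifnot(inherits(spectra, "band_spectra"))
  f <- spectra$frequencies_hz
  centre <- if (is.numeric(external) && length(external) == 1L) external
            else {
              stopifnot(inherits(external, "spectral_regressors"))
              dominant_frequency(external$xc, external$frequencies_hz)
            }
  bins <- which(abs(f - centre) <= window_hz / 2 + 1e-12)
  if (!length(bins))
    stop("no frequency bins within the ", window_hz,
         " Hz window around ", format(centre, digits = 4),
         " Hz (bin spacing ", format(diff(f[1:2]), digits = 4), " Hz)")
  P <- spectra$power
  if (!is.null(voxels)) P <- P[voxels, , drop = FALSE]
  if (nrow(P) == 0L)
    return(structure(NA_real_, n_bins = length(bins), n_voxels = 0L))
  structure(mean(rowMeans(P[, bins, drop = FALSE])),
            n_bins = length(bins), n_voxels = nrow(P))
}

#' Percentage overlap of two significant-voxel masks
#'
#' Jaccard overlap by default, `100 * |A intersect B| / |A union B|`; the
#' `"min"` method uses the smaller mask as denominator instead.
#'
#' @param mask_a,mask_b logical vectors over the same voxel universe.
#' @param method `"jaccard"` (default) or `"min"`.
#' @return percentage in `[0, 100]`; `NA` when both masks are empty.
#' @export
mask_overlap <- function(mask_a, mask_b, method = c("jaccard", "min")) {
  method <- match.arg(method)
  if (length(mask_a) != length(mask_b))
    stop("masks must share the same voxel universe")
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  inter <- sum(mask_a & mask_b)
  denom <- switch(method,
                  jaccard = sum(mask_a | mask_b),
                  min = min(sum(mask_a), sum(mask_b)))
  if (denom == 0L) return(NA_real_)
  100 * inter / denom
}

#' Partial correlation with covariate control
#'
#' Correlates the residuals of `x` and `y` after least-squares removal of
#' the covariates (plus intercept); the p-value is the two-sided t-transform
#' with `n - ncov - 2` degrees of freedom.  With no covariates this reduces
#' to the Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates of no
#'   interest (e.g. the complementary coefficient, dominant physiological
#'   rate, mean absolute displacement).
#' @return list with `r`, `p`, `df`, `n`.  Degenerate residuals (e.g. `y` an
#'   exact linear function of the covariates) yield `r = NA`, `p = NA`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have the same length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  ncov <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per case")
    if (!all(is.finite(covariates))) stop("covariates must be finite")
    ncov <- ncol(covariates)
  }
  if (n <= ncov + 2L)
    stop("need n > ncov + 2 cases (n = ", n, ", ncov = ", ncov, ")")
  Z <- cbind(rep(1, n), covariates)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  df <- n - ncov - 2L
  if (sum(rx^2) < 1e-12 * max(1, sum(x^2)) ||
      sum(ry^2) < 1e-12 * max(1, sum(y^2)))
    return(list(r = NA_real_, p = NA_real_, df = df, n = n))
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       df = df, n = n)
}

#' Scalar summary of a dual-regression fit in a tissue mask
#'
#' Collects the PVE-weighted mean coefficients, spatial extents, significant
#' voxel counts and (when an external cardiac spectrum is supplied) the
#' windowed cardiac pulsatility metric — computed once over all mask voxels
#' and once over the significantly cardiac-modulated voxels only.
#'
#' @param fit a [dualreg()] fit.
#' @param mask a [tissue_mask()] aligned with the fitted voxels.
#' @param external optional [spectral_regressors()] with the externally
#'   measured cardiac spectrum for the pulsatility metric.
#' @param p_threshold per-voxel significance threshold (default 0.01).
#' @param window_hz pulsatility window width (default 0.04 Hz).
#' @return class `"metrics_report"`.
#' @export
metrics_report <- function(fit, mask, external = NULL, p_threshold = 0.01,
                           window_hz = 0.04) {
  stopifnot(inherits(fit, "dualreg"), inherits(mask, "tissue_mask"))
  pe <- fit$pe_maps
  sig_c <- pe$p_beta_c < p_threshold
  sig_r <- pe$p_beta_r < p_threshold
  puls_all <- puls_sig <- NA_real_
  if (!is.null(external)) {
    puls_all <- as.numeric(pulsatility_metric(fit$spectra, external,
                                              voxels = mask$members,
                                              window_hz = window_hz))
    puls_sig <- as.numeric(pulsatility_metric(fit$spectra, external,
                                              voxels = mask$members & sig_c,
                                              window_hz = window_hz))
  }
  structure(list(
    label = mask$label,
    mean_alpha  = as.numeric(mean_pe(pe, mask, "alpha",  p_threshold)),
    mean_beta_r = as.numeric(mean_pe(pe, mask, "beta_r", p_threshold)),
    mean_beta_c = as.numeric(mean_pe(pe, mask, "beta_c", p_threshold)),
    extent_c = spatial_extent(pe, mask, "beta_c", p_threshold),
    extent_r = spatial_extent(pe, mask, "beta_r", p_threshold),
    pulsatility_all_voxels = puls_all,
    pulsatility_significant = puls_sig,
    n_significant_cardiac = sum(sig_c & mask$members),
    n_significant_respiratory = sum(sig_r & mask$members),
    n_mask_voxels = sum(mask$members),
    p_threshold = p_threshold, pve_threshold = mask$threshold,
    window_hz = window_hz,
    converged = fit$converged, n_iterations = fit$n_iterations,
    init_mode = fit$init_mode),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Physiological-modulation metrics (%s matter, PVE > %g, p < %g)\n",
              x$label, x$pve_threshold, x$p_threshold))
  cat(sprintf("  mean PEs  <alpha> %.4g  <beta_r> %.4g  <beta_c> %.4g\n",
              x$mean_alpha, x$mean_beta_r, x$mean_beta_c))
  cat(sprintf("  spatial extent  Rc %.3f  Rr %.3f  (%d / %d / %d cardiac / respiratory / mask voxels)\n",
              x$extent_c, x$extent_r, x$n_significant_cardiac,
              x$n_significant_respiratory, x$n_mask_voxels))
  if (is.finite(x$pulsatility_all_voxels))
    cat(sprintf("  cardiac pulsatility metric (%g Hz window): all voxels %.4g, significant only %.4g\n",
                x$window_hz, x$pulsatility_all_voxels,
                x$pulsatility_significant))
  invisible(x)
}
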