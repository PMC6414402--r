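#' Fit the voxelwise spectral GLM
#'
#' For every voxel, regresses the unit-sum normalized band amplitude
#' spectrum P(f) on the three explanatory spectra — constant baseline,
#' respiratory Xr(f) and cardiac Xc(f) — by ordinary least squares along
#' the frequency dimension:
#' \deqn{P(f) = \alpha \cdot 1 + \beta_r X_r(f) + \beta_c X_c(f) + \varepsilon(f).}
#' Coefficient significance is a single-coefficient t-test with
#' \eqn{N_b - 3} degrees of freedom (two-sided by default; a one-sided
#' \eqn{\beta > 0} option exists since physiological power contributions
#' are nonnegative by physics).
#'
#' Because the voxel spectrum and both physiological regressors are each
#' normalized to unit band sum, noiseless coefficients are coupled:
#' \eqn{\alpha N_b + \beta_r + \beta_c = 1}.  A voxel gaining cardiac power
#' therefore loses baseline amplitude; statistical tests downstream account
#' for this by including the complementary coefficient as a covariate.
#'
#' @param spectra a normalized [band_normalize()] result.
#' @param regressors a [spectral_regressors()] object on the same band.
#' @param alternative `"two.sided"` (default) or `"greater"` (tests
#'   beta > 0).
#' @return class `"pe_maps"`: per-voxel parameter estimates `alpha`,
#'   `beta_r`, `beta_c` with standard errors `se_*`, t-statistics `t_*`,
#'   p-values `p_*`, `residual_rms`, and the residual degrees of freedom
#'   `dof`.
#' @export
fit_spatial_glm <- function(spectra, regressors,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(spectra, "band_spectra"),
            inherits(regressors, "spectral_regressors"))
  if (!isTRUE(spectra$normalized))
    stop("spectra must be unit-sum normalized (see band_normalize)")
  nb <- ncol(spectra$power)
  if (nb != length(regressors$frequencies_hz))
    stop("spectra and regressors are on different frequency bands")
  if (nb <= 3L)
    stop("need more than 3 band frequencies, got ", nb)
  X <- cbind(baseline = regressors$baseline,
             respiratory = regressors$xr,
             cardiac = regressors$xc)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("rank-deficient design matrix (condition number ",
         format(kappa(X), digits = 4),
         "): the regressor spectra are collinear")
  P <- t(spectra$power)                       # Nb x voxels
  B <- qr.coef(qrX, P)                        # 3 x voxels
  res <- P - X %*% B
  dof <- nb - 3L
  rss <- colSums(res^2)
  sigma2 <- rss / dof
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(xtx_inv), sigma2))    # 3 x voxels
  tstat <- ifelse(se > 0, B / se,
                  ifelse(B != 0, sign(B) * Inf, 0))
  pval <- switch(alternative,
                 two.sided = 2 * stats::pt(abs(tstat), dof, lower.tail = FALSE),
                 greater   = stats::pt(tstat, dof, lower.tail = FALSE))
  structure(list(alpha = B[1L, ], beta_r = B[2L, ], beta_c = B[3L, ],
                 se_alpha = se[1L, ], se_beta_r = se[2L, ], se_beta_c = se[3L, ],
                 t_alpha = tstat[1L, ], t_beta_r = tstat[2L, ], t_beta_c = tstat[3L, ],
                 p_alpha = pval[1L, ], p_beta_r = pval[2L, ], p_beta_c = pval[3L, ],
                 residual_rms = sqrt(rss / nb),
                 dof = dof, n_voxels = ncol(P), nb = nb,
                 alternative = alternative),
            class = "pe_maps")
}

#' @export
print.pe_maps <- function(x, p_threshold = 0.01, ...) {
  cat("Spectral GLM parameter-estimate maps:", x$n_voxels, "voxels,",
      x$nb, "band bins, dof =", x$dof, "\n")
  cat(sprintf("  significant at p < %g (%s): cardiac %d, respiratory %d\n",
              p_threshold, x$alternative,
              sum(x$p_beta_c < p_threshold),
              sum(x$p_beta_r < p_threshold)))
  cat(sprintf("  mean PEs: alpha %.3g, beta_r %.3g, beta_c %.3g\n",
              mean(x$alpha), mean(x$beta_r), mean(x$beta_c)))
  invisible(x)
}

#' @export
coef.pe_maps <- function(object, ...) {
  cbind(alpha = object$alpha, beta_r = object$beta_r,
        beta_c = object$beta_c)
}
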