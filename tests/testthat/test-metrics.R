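test_that("the PVE-weighted mean PE follows its defining arithmetic", {
  pe <- fake_pe_maps(beta_c = c(2, 4), p_beta_c = c(0.001, 0.001))
  m <- tissue_mask(c(0.8, 0.8))
  expect_equal(as.numeric(mean_pe(pe, m, "beta_c")), 3.0)

  # one significant voxel: its beta regardless of PVE
  pe1 <- fake_pe_maps(beta_c = c(2, 4), p_beta_c = c(0.5, 0.001))
  m1 <- tissue_mask(c(0.9, 0.75))
  expect_equal(as.numeric(mean_pe(pe1, m1, "beta_c")), 4)
  expect_equal(attr(mean_pe(pe1, m1, "beta_c"), "n_selected"), 1L)

  # unequal weights
  pe2 <- fake_pe_maps(beta_c = c(1, 3), p_beta_c = c(0.001, 0.001))
  m2 <- tissue_mask(c(0.8, 1.0))
  expect_equal(as.numeric(mean_pe(pe2, m2, "beta_c")),
               (1 * 0.8 + 3 * 1.0) / 1.8)
})

test_that("an empty selection is signalled, never reported as zero", {
  pe <- fake_pe_maps(beta_c = c(2, 4), p_beta_c = c(0.5, 0.9))
  m <- tissue_mask(c(0.8, 0.8))
  out <- mean_pe(pe, m, "beta_c")
  expect_true(is.na(out))
  expect_equal(attr(out, "n_selected"), 0L)
})

test_that("mean_pe is invariant to duplicating every voxel", {
  set.seed(30)
  n <- 20
  pe <- fake_pe_maps(beta_c = runif(n), p_beta_c = runif(n, 0, 0.05))
  m <- tissue_mask(runif(n, 0.5, 1))
  pe2 <- fake_pe_maps(beta_c = rep(pe$beta_c, 2),
                      p_beta_c = rep(pe$p_beta_c, 2))
  m2 <- tissue_mask(rep(m$pve, 2))
  expect_equal(as.numeric(mean_pe(pe, m, "beta_c")),
               as.numeric(mean_pe(pe2, m2, "beta_c")), tolerance = 1e-12)
})

test_that("spatial extent is the PVE-weighted significant fraction", {
  pe <- fake_pe_maps(beta_c = c(1, 1, 1), p_beta_c = c(0.5, 0.5, 0.001))
  m <- tissue_mask(c(0.8, 0.9, 1.0))
  expect_equal(spatial_extent(pe, m, "beta_c"), 1.0 / 2.7)

  all_sig <- fake_pe_maps(beta_c = c(1, 1), p_beta_c = c(1e-4, 1e-4))
  expect_equal(spatial_extent(all_sig, tissue_mask(c(0.8, 0.9)), "beta_c"), 1)
  none <- fake_pe_maps(beta_c = c(1, 1), p_beta_c = c(0.5, 0.5))
  expect_equal(spatial_extent(none, tissue_mask(c(0.8, 0.9)), "beta_c"), 0)
  expect_error(spatial_extent(none, tissue_mask(c(0.1, 0.2)), "beta_c"),
               "empty tissue mask")
})

test_that("lowering the p threshold never increases the spatial extent", {
  set.seed(31)
  n <- 200
  pe <- fake_pe_maps(beta_c = runif(n), p_beta_c = runif(n))
  m <- tissue_mask(runif(n))
  ext <- sapply(c(0.2, 0.1, 0.05, 0.01, 0.001),
                function(p) spatial_extent(pe, m, "beta_c", p_threshold = p))
  expect_true(all(diff(ext) <= 0))
})

test_that("the windowed pulsatility metric averages around the cardiac peak", {
  f <- seq(0.2, 1.5, by = 0.01)
  nb <- length(f)
  flat <- band_from_matrix(matrix(1, 3, nb), f)
  expect_equal(as.numeric(pulsatility_metric(flat, external = 1.0)), 1 / nb)

  # single-tone voxel, window of one bin at the centre
  tone <- matrix(1e-9, 1, nb); tone[1, which(f == 1.0)] <- 1
  sp <- band_from_matrix(tone, f)
  m <- pulsatility_metric(sp, external = 1.0, window_hz = 0.005)
  expect_equal(attr(m, "n_bins"), 1L)
  expect_equal(as.numeric(m), max(sp$power))

  # centre at the band edge: window clips to the available bins
  edge <- pulsatility_metric(flat, external = 1.5, window_hz = 0.04)
  expect_equal(attr(edge, "n_bins"), 3L)
  expect_equal(as.numeric(edge), 1 / nb)

  # the centre may come from an external regressor's dominant frequency
  xc <- rep(1e-6, nb); xc[which(f == 1.0)] <- 1
  reg <- spectral_regressors(xc = xc, xr = rep(1, nb), frequencies_hz = f)
  expect_equal(as.numeric(pulsatility_metric(flat, reg)), 1 / nb)
})

test_that("mask overlap implements Jaccard with an intersection-over-smaller option", {
  a <- c(rep(TRUE, 9), TRUE, FALSE)
  b <- c(rep(TRUE, 9), FALSE, TRUE)
  expect_equal(mask_overlap(a, b), 100 * 9 / 11)
  expect_equal(mask_overlap(a, a), 100)
  expect_equal(mask_overlap(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  # |A int B| = 9, |A un B| = 10
  a2 <- c(rep(TRUE, 9), TRUE)
  b2 <- c(rep(TRUE, 9), FALSE)
  expect_equal(mask_overlap(a2, b2), 90)
  expect_equal(mask_overlap(a2, b2, method = "min"), 100)
  expect_true(is.na(mask_overlap(logical(3), logical(3))))
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.2, 6.9)
  y <- c(2.1, 1.9, 3.7, 3.9, 5.8, 6.1)
  z <- cbind(c(0.5, 1.1, 1.8, 2.2, 3.1, 3.6))
  out <- partial_correlation(x, y, z)
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  r_expect <- cor(rx, ry)
  t_expect <- r_expect * sqrt((6 - 1 - 2) / (1 - r_expect^2))
  expect_equal(out$r, r_expect, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(abs(t_expect), 3, lower.tail = FALSE),
               tolerance = 1e-10)

  # no covariates: Pearson
  out0 <- partial_correlation(x, y)
  expect_equal(out0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(out0$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  # y an exact linear function of the covariates: undefined, signalled
  deg <- partial_correlation(x, 2 * z[, 1] + 3, z)
  expect_true(is.na(deg$r) && is.na(deg$p))
  expect_error(partial_correlation(1:3, 1:3, cbind(1:3, 3:1)), "ncov")
})

test_that("growing spatial extent drives the all-voxel metric but not the per-voxel one", {
  # cohort where only the fraction of modulated voxels grows with age;
  # per-voxel cardiac amplitude is identical throughout
  ages <- seq(20, 75, length.out = 10)
  frac <- seq(0.15, 0.6, length.out = 10)
  all_vox <- sig_only <- numeric(10)
  for (j in 1:10) {
    truth <- simulate_ground_truth(n_voxels = 300, n_volumes = 256,
                                   frac_cardiac = frac[j], frac_resp = 0.3,
                                   beta_c_range = c(0.3, 0.3),
                                   cardiac_drift_hz = 0, seed = 600 + j)
    dat <- simulate_epi_dataset(truth)
    sp <- band_normalize(amplitude_spectrum(dat$ts), fmin = truth$fmin)
    pe <- fit_spatial_glm(sp, truth$regressors)
    sig <- pe$p_beta_c < 0.01
    all_vox[j] <- pulsatility_metric(sp, truth$regressors)
    sig_only[j] <- pulsatility_metric(sp, truth$regressors, voxels = sig)
  }
  trend_all <- partial_correlation(ages, all_vox)
  trend_sig <- partial_correlation(ages, sig_only)
  expect_gt(trend_all$r, 0)
  expect_lt(trend_all$p, 0.05)
  expect_gt(trend_sig$p, 0.05)
})

test_that("the metrics report collects every scalar consistently", {
  s <- small_sim(n_voxels = 120, n_volumes = 512, seed = 23)
  fit <- dualreg(s$spectra, init = s$truth$regressors)
  mask <- tissue_mask(s$truth$pve)
  rep <- metrics_report(fit, mask, external = s$truth$regressors)
  expect_true(rep$extent_c >= 0 && rep$extent_c <= 1)
  expect_true(rep$extent_r >= 0 && rep$extent_r <= 1)
  expect_equal(rep$extent_c,
               spatial_extent(fit$pe_maps, mask, "beta_c"))
  expect_equal(rep$mean_beta_c,
               as.numeric(mean_pe(fit$pe_maps, mask, "beta_c")))
  expect_gte(rep$pulsatility_significant, rep$pulsatility_all_voxels)
  expect_output(print(rep), "spatial extent")
})
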