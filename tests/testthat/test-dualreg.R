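test_that("informed initialization puts a pure tone's mass at its bin", {
  tr <- 0.5; n_vol <- 64
  t <- (0:(64 * 100 - 1)) / 100
  tone <- physio_trace(cos(2 * pi * 0.75 * t), 100, "cardiac")
  resp <- physio_trace(cos(2 * pi * 0.25 * t), 100, "respiratory")
  reg <- informed_init(tone, resp, tr = tr, n_volumes = n_vol, fmin = 0.2)
  # 0.75 Hz falls exactly on bin 24 of a 64-point grid at TR 0.5
  expect_equal(dominant_frequency(reg$xc, reg$frequencies_hz), 0.75)
  expect_gt(max(reg$xc), 0.99)
  expect_equal(sum(reg$xc), 1, tolerance = 1e-9)
  expect_equal(sum(reg$xr), 1, tolerance = 1e-9)
  expect_true(all(reg$baseline == 1))
})

test_that("above-Nyquist cardiac tones alias into the informed spectrum", {
  tr <- 0.328; n_vol <- 512; fs <- 1 / tr
  t <- (0:(200 * 1000 - 1)) / 1000
  tone <- physio_trace(cos(2 * pi * 2.2 * t), 1000, "cardiac")
  resp <- physio_trace(cos(2 * pi * 0.3 * t), 1000, "respiratory")
  reg <- informed_init(tone, resp, tr = tr, n_volumes = n_vol, fmin = 0.2)
  expect_lt(abs(dominant_frequency(reg$xc, reg$frequencies_hz) -
                alias_frequency(2.2, fs)),
            1 / (n_vol * tr) + 1e-12)
})

test_that("a white-noise trace yields an approximately flat spectrum", {
  set.seed(8)
  tr <- 0.328; n_vol <- 2048
  noise <- physio_trace(rnorm(700 * 1000), 1000, "cardiac")
  resp <- physio_trace(rnorm(700 * 1000), 1000, "respiratory")
  reg <- informed_init(noise, resp, tr = tr, n_volumes = n_vol, fmin = 0.2)
  nb <- length(reg$xc)
  # smoothed (20-bin block averages) flat within a modest ratio
  blocks <- colMeans(matrix(reg$xc[1:(20 * (nb %/% 20))], 20))
  expect_lt(max(blocks) / min(blocks), 2.5)
})

test_that("the data-driven seed splits the mask-average spectrum at 0.6 Hz", {
  f <- seq(0.2, 1.5, length.out = 14)
  set.seed(2)
  P <- matrix(runif(4 * 14, 0.1, 1), 4); P <- P / rowSums(P)
  sp <- band_from_matrix(P, f)
  reg <- data_driven_init(sp, split_hz = 0.6)
  lo <- f <= 0.6
  expect_true(all(reg$xc[lo] == 0))
  expect_true(all(reg$xr[!lo] == 0))
  avg <- colMeans(sp$power)
  expect_equal(reg$xr[lo], avg[lo] / sum(avg[lo]), tolerance = 1e-12)
  expect_equal(reg$xc[!lo], avg[!lo] / sum(avg[!lo]), tolerance = 1e-12)

  # a split exactly on a bin assigns that bin to the respiratory side
  f2 <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  sp2 <- band_from_matrix(matrix(1, 4, 5), f2)
  reg2 <- data_driven_init(sp2, split_hz = 0.6)
  expect_equal(reg2$xr, c(1, 1, 1, 0, 0) / 3)
  expect_equal(reg2$xc, c(0, 0, 0, 1, 1) / 2)

  # identical voxels: the seed equals either voxel's zeroed, renormalized row
  sp3 <- band_from_matrix(rbind(P[1, ], P[1, ], P[1, ], P[1, ]), f)
  reg3 <- data_driven_init(sp3)
  row <- sp3$power[1, ]
  expect_equal(reg3$xc[!lo], (row[!lo] / sum(row[!lo])), tolerance = 1e-12)

  expect_error(data_driven_init(band_from_matrix(
    cbind(matrix(1, 4, 4), matrix(0, 4, 10)), f)), "one side")
})

test_that("refining noiseless data returns the generating spectra", {
  s <- small_sim(n_voxels = 50, noise_scale = 0, seed = 12)
  pe <- fit_spatial_glm(s$spectra, s$truth$regressors)
  ref <- refine_spectra(s$spectra, pe)
  expect_equal(ref$xc, s$truth$regressors$xc, tolerance = 1e-8)
  expect_equal(ref$xr, s$truth$regressors$xr, tolerance = 1e-8)
})

test_that("refinement rejects rank-deficient coefficient maps", {
  s <- small_sim(n_voxels = 20, seed = 13, frac_cardiac = 0)
  pe <- fit_spatial_glm(s$spectra, s$truth$regressors)
  pe$beta_c[] <- 0
  expect_error(refine_spectra(s$spectra, pe), "condition number")
})

test_that("the raw frequency GLM matches the normal-equations oracle", {
  set.seed(14)
  for (rep in 1:10) {
    nv <- 10; nb <- 12
    f <- seq(0.2, 1.4, length.out = nb)
    P <- matrix(runif(nv * nb, 0.05, 1), nv); P <- P / rowSums(P)
    sp <- band_from_matrix(P, f)
    pe <- fake_pe_maps(beta_c = runif(nv), p_beta_c = runif(nv),
                       beta_r = runif(nv), alpha = runif(nv))
    rows <- refine_spectra(sp, pe, raw = TRUE)
    A <- cbind(pe$alpha, pe$beta_r, pe$beta_c)
    expect_equal(unname(rows), unname(ne_oracle(A, P)), tolerance = 1e-8)
  }
})

test_that("a noiseless dataset started at truth is an exact fixed point", {
  s <- small_sim(n_voxels = 50, noise_scale = 0, seed = 15)
  fit <- dualreg(s$spectra, init = s$truth$regressors)
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1L)
  expect_equal(as.numeric(fit$change_trace[1, ]), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(fit$pe_maps$beta_c), s$truth$beta_c, tolerance = 1e-6)
  expect_equal(unname(fit$pe_maps$alpha), s$truth$alpha, tolerance = 1e-6)
})

test_that("zero tolerance runs to the iteration cap without converging", {
  s <- small_sim(n_voxels = 30, seed = 16)
  fit <- dualreg(s$spectra, mode = "data_driven", tolerance = 0, max_iter = 3)
  expect_false(fit$converged)
  expect_equal(fit$n_iterations, 3L)
  expect_equal(nrow(fit$change_trace), 3L)
})

test_that("iterating from a data-driven seed moves the cardiac spectrum toward truth", {
  s <- small_sim(n_voxels = 150, n_volumes = 512, seed = 17)
  init <- data_driven_init(s$spectra)
  l1 <- function(reg) sum(abs(reg$xc - s$truth$regressors$xc))
  f1 <- dualreg(s$spectra, init = init, tolerance = 0, max_iter = 1)
  f2 <- dualreg(s$spectra, init = init, tolerance = 0, max_iter = 2)
  expect_lt(l1(f1$regressors), l1(init))
  expect_lte(l1(f2$regressors), l1(f1$regressors))
})

test_that("every iteration's regressors satisfy the model invariants", {
  s <- small_sim(n_voxels = 60, seed = 18)
  init <- data_driven_init(s$spectra)
  reg <- init
  for (i in 1:4) {
    pe <- fit_spatial_glm(s$spectra, reg)
    reg <- refine_spectra(s$spectra, pe)
    expect_true(all(reg$xc >= 0) && all(reg$xr >= 0))
    expect_equal(sum(reg$xc), 1, tolerance = 1e-9)
    expect_equal(sum(reg$xr), 1, tolerance = 1e-9)
    expect_true(all(reg$baseline == 1))
  }
})

test_that("the convergence decision reproduces from the change trace", {
  s <- small_sim(n_voxels = 60, seed = 19)
  fit <- dualreg(s$spectra, mode = "data_driven")
  expect_true(all(is.finite(fit$change_trace)))
  last <- fit$change_trace[fit$n_iterations, ]
  expect_equal(fit$converged,
               unname(last["cardiac"] < fit$tolerance &&
                      last["respiratory"] < fit$tolerance))
  if (fit$n_iterations > 1L) {
    earlier <- fit$change_trace[-fit$n_iterations, , drop = FALSE]
    expect_true(all(apply(earlier, 1,
                          function(ch) any(ch >= fit$tolerance))))
  }
})

test_that("dualreg methods expose coefficients, fits and residuals", {
  s <- small_sim(n_voxels = 40, seed = 20)
  fit <- dualreg(s$spectra, mode = "data_driven")
  B <- coef(fit)
  expect_equal(dim(B), c(40L, 3L))
  expect_equal(colnames(B), c("alpha", "beta_r", "beta_c"))
  expect_equal(fitted(fit) + residuals(fit), s$spectra$power,
               tolerance = 1e-12)
  # residuals orthogonal to the converged design
  X <- cbind(1, fit$regressors$xr, fit$regressors$xc)
  expect_lt(max(abs(t(X) %*% t(residuals(fit)))), 1e-8)
  # predict on the training spectra returns the stored maps
  pe2 <- predict(fit, s$spectra)
  expect_equal(pe2$beta_c, fit$pe_maps$beta_c, tolerance = 1e-12)
  expect_output(print(fit), "dual regression")
  expect_output(print(summary(fit)), "dominant frequencies")
})

test_that("informed and data-driven modes agree on separable synthetic data", {
  # spectrally separable: cardiac content above, respiratory below 0.6 Hz;
  # perfused voxels carry both modulations
  s <- small_sim(n_voxels = 250, n_volumes = 512, seed = 22,
                 n_harmonics = 1, assignment = "co_occurring")
  fi <- dualreg(s$spectra, init = s$truth$regressors)
  fd <- dualreg(s$spectra, mode = "data_driven")
  ov <- mask_overlap(fi$pe_maps$p_beta_c < 0.01, fd$pe_maps$p_beta_c < 0.01)
  expect_gte(ov, 95)
})
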