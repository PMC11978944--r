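test_that("HRF kernel is a unit-sum gamma variate peaking at alpha*tau", {
  for (par in list(c(3, 0.5), c(2, 1), c(6, 0.3))) {
    k <- hrf_kernel(hemodynamic_model(par[1], par[2], duration_s = 12), 0.05)
    expect_equal(sum(k), 1, tolerance = 1e-9)
    t_peak <- (which.max(k) - 1) * 0.05
    expect_lt(abs(t_peak - par[1] * par[2]), 0.05 + 1e-9)
  }
  # smaller alpha shifts the response earlier
  peaks <- vapply(c(1, 2, 4, 8), function(a) {
    k <- hrf_kernel(hemodynamic_model(a, 0.5, 16), 0.02)
    (which.max(k) - 1) * 0.02
  }, 1)
  expect_true(all(diff(peaks) > 0))
  expect_error(hrf_kernel(hemodynamic_model(3, 0.5, duration_s = 0.2), 0.1),
               "duration")
})

test_that("design matrix has the documented sampling and structure", {
  X <- build_design(stimulus_protocol())
  expect_equal(nrow(X), 138L)          # floor(330 / 2.4) + sample at t = 0
  expect_equal(colnames(X), c("stimulus", "drift", "intercept"))
  expect_equal(max(X[, "stimulus"]), 1)          # unit plateau
  # plateau holds across samples deep inside ON blocks
  t_on2 <- 30 + 60 + 15                           # middle of second ON block
  expect_equal(unname(X[which.min(abs(attr(X, "times") - t_on2)), "stimulus"]),
               1, tolerance = 1e-9)
  expect_equal(sum(X[, "drift"]), 0)              # centered ramp
  expect_true(all(X[attr(X, "times") < 30, "stimulus"] == 0))
  expect_error(build_design(stimulus_protocol(n_repeats = 0L)), "rank")
})

test_that("noise-free regressor data give a perfect capped fit", {
  X <- build_design(stimulus_protocol())
  y <- 5 + 2 * X[, "stimulus"]
  fit <- fit_voxelwise(cbind(y), X)
  expect_equal(unname(fit$beta[1, 1]), 2, tolerance = 1e-8)
  expect_equal(unname(abs(fit$z[1])), 8)          # z capped
  expect_equal(sign(fit$z[1]), sign(fit$beta[1, 1]))
})

test_that("dcbv scales with the series while rcbv is scale invariant", {
  ph <- small_phantom()
  v <- simulate_fus_series(ph, noise_sigma = 0.05, seed = 6)
  X <- build_design(stimulus_protocol(), n_samples = nrow(v$series))
  f1 <- fit_voxelwise(v$series, X)
  f2 <- fit_voxelwise(v$series * 7.5, X)
  expect_equal(f2$dcbv, 7.5 * f1$dcbv, tolerance = 1e-9)
  expect_equal(f2$rcbv, f1$rcbv, tolerance = 1e-9)
  expect_equal(f2$z, f1$z, tolerance = 1e-6)
  # z sign equals beta sign wherever defined
  ok <- is.finite(f1$z) & f1$z != 0
  expect_true(all(sign(f1$z[ok]) == sign(f1$beta[ok, 1])))
})

test_that("zero-variance voxels are flagged and excluded from maps", {
  X <- build_design(stimulus_protocol())
  Y <- cbind(rep(3, nrow(X)), 3 + rnorm(nrow(X)))
  fit <- fit_voxelwise(Y, X)
  expect_identical(fit$excluded, c(TRUE, FALSE))
  expect_true(is.na(fit$rcbv[1]) && is.finite(fit$rcbv[2]))
})

test_that("recovered rCBV matches the injected effect and its closed form", {
  ph <- small_phantom()
  A <- 0.15
  X <- build_design(stimulus_protocol())
  med_pre <- med_mean <- numeric(10)
  for (s in 1:10) {
    v <- simulate_fus_series(ph, noise_sigma = 0.05,
                             effect_map = matrix(A, 15, 15), seed = 100 + s)
    med_pre[s] <- stats::median(fit_voxelwise(v, X, baseline = "prestim")$rcbv)
    med_mean[s] <- stats::median(fit_voxelwise(v, X, baseline = "mean")$rcbv)
  }
  # resting-baseline estimator targets the injected steady-state fraction
  expect_lt(abs(stats::median(med_pre) - A), 0.01)
  # whole-series baseline dilutes it by exactly 1 + A * mean(regressor)
  xbar <- mean(X[, "stimulus"])
  expect_lt(abs(stats::median(med_mean) - A / (1 + A * xbar)), 0.005)
})

test_that("activation mask recovers a confined effect region", {
  ph <- small_phantom()
  eff <- matrix(0, 15, 15)
  eff[4:8, 5:10] <- 0.15                      # confined cortical-like patch
  v <- simulate_fus_series(ph, noise_sigma = 0.05, effect_map = eff,
                           seed = 17)
  X <- build_design(stimulus_protocol(), n_samples = nrow(v$series))
  fit <- fit_voxelwise(v, X)
  mask <- significance_mask(fit$p_map, n_tests = sum(!fit$excluded))
  truth <- eff > 0
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gt(dice, 0.8)
})

test_that("Bonferroni masking applies the corrected threshold", {
  expect_true(significance_mask(matrix(0.04), n_tests = 1))
  expect_false(significance_mask(matrix(0.04), n_tests = 2))
  p <- matrix(c(4e-5, 6e-5), 1)
  expect_equal(as.vector(significance_mask(p, n_tests = 1000)),
               c(TRUE, FALSE))
  expect_false(significance_mask(matrix(NA_real_), n_tests = 5)[1])
})
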