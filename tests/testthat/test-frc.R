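test_that("event splitting is balanced, disjoint and reproducible", {
  locs <- data.frame(x_um = runif(10), z_um = runif(10), frame = 1:10)
  h <- split_events(locs, seed = 1)
  expect_equal(sort(c(rownames(h[[1]]), rownames(h[[2]]))), sort(rownames(locs)))
  expect_equal(vapply(h, nrow, 1L), c(5L, 5L))
  locs11 <- rbind(locs, data.frame(x_um = 0.5, z_um = 0.5, frame = 11))
  h11 <- split_events(locs11, seed = 2)
  expect_lte(abs(nrow(h11[[1]]) - nrow(h11[[2]])), 1L)
  expect_identical(split_events(locs, seed = 9), split_events(locs, seed = 9))
  expect_error(split_events(locs[1, , drop = FALSE]), "at least 2")
  # block split separates odd and even frames
  hb <- split_events(locs, method = "blocks")
  expect_true(all(hb[[1]]$frame %% 2 == 1))
})

test_that("FRC is 1 for identical images and near 0 for independent noise", {
  set.seed(5)
  img <- matrix(rpois(64^2, 2), 64)
  cv <- frc_curve(img, img, pixel_um = 5)
  expect_true(all(abs(cv$frc[is.finite(cv$frc)] - 1) < 1e-9))
  a <- matrix(rnorm(256^2), 256)
  b <- matrix(rnorm(256^2), 256)
  cn <- frc_curve(a, b, pixel_um = 5)
  beyond <- cn$frc[cn$freq_per_um > 0][-1]
  expect_lt(mean(abs(beyond), na.rm = TRUE), 0.1)
})

test_that("FRC matches the direct-summation oracle on 32 x 32 images", {
  set.seed(6)
  x <- matrix(rnorm(32^2), 32)
  y <- 0.7 * x + 0.3 * matrix(rnorm(32^2), 32)
  fast <- frc_curve(x, y, pixel_um = 5)
  slow <- fusulm:::frc_curve_brute(x, y, pixel_um = 5)
  expect_equal(nrow(fast), nrow(slow))
  expect_equal(fast$freq_per_um, slow$freq_per_um, tolerance = 1e-12)
  expect_equal(fast$frc, slow$frc, tolerance = 1e-10)
  expect_equal(fast$n_bins, slow$n_bins)
})

test_that("FRC is symmetric and intensity-scale invariant", {
  set.seed(8)
  x <- matrix(rnorm(48^2), 48)
  y <- 0.5 * x + 0.5 * matrix(rnorm(48^2), 48)
  expect_equal(frc_curve(x, y, 5)$frc, frc_curve(y, x, 5)$frc,
               tolerance = 1e-12)
  expect_equal(frc_curve(3.7 * x, y, 5)$frc, frc_curve(x, y, 5)$frc,
               tolerance = 1e-12)
})

test_that("resolution criterion finds band limits and flags grid limits", {
  # flat curve at 1: grid-limited result of twice the pixel size
  flat <- frc_curve(matrix(rpois(64^2, 3), 64), matrix(rpois(64^2, 3), 64) * 0 +
                      matrix(rpois(64^2, 3), 64), pixel_um = 5)
  flat$frc[] <- 1
  r <- frc_resolution(flat)
  expect_true(r$grid_limited)
  expect_equal(r$resolution_um, 10)
  # band-limited pair: crossing at the cutoff within one ring width
  set.seed(9)
  N <- 128; px <- 5; fc_px <- 0.25    # cutoff in cycles/pixel
  qi <- c(0:(N / 2), -((N / 2) - 1):-1) / N
  lowpass <- function(m) Re(stats::fft(stats::fft(m) *
                                         (sqrt(outer(qi^2, qi^2, "+")) <= fc_px),
                                       inverse = TRUE)) / N^2
  common <- lowpass(matrix(rnorm(N^2), N))
  a <- common + 1e-8 * matrix(rnorm(N^2), N)
  b <- common + 1e-8 * matrix(rnorm(N^2), N)
  cv <- frc_curve(a, b, pixel_um = px)
  r2 <- frc_resolution(cv, smooth_rings = 1L)
  ring_w <- 1 / (N * px)
  expect_false(r2$grid_limited)
  expect_lt(abs(r2$freq_cross_per_um - fc_px / px), ring_w)
})

test_that("resolution degrades monotonically with localization blur", {
  set.seed(10)
  ph <- small_phantom()
  tru <- simulate_mb_truth(ph, duration_s = 1.2, mb_rate = 120,
                           rate_weighting = "length", seed = 14)
  res_at <- function(sigma) {
    locs <- tru
    locs$x_um <- locs$x_um + rnorm(nrow(locs), 0, sigma)
    locs$z_um <- locs$z_um + rnorm(nrow(locs), 0, sigma)
    frc_from_localizations(locs, ph$extent_um, grid_um = 5,
                           seed = 3)$resolution$resolution_um
  }
  r <- vapply(c(1, 6, 15), res_at, 1)
  expect_true(all(diff(r) > 0))
  # estimated resolution can never beat twice the rasterization grid
  expect_true(all(r >= 10))
})
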