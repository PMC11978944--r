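test_that("phantom generation is reproducible and honors the level spec", {
  p1 <- generate_phantom(n_per_level = c(5L, 5L, 5L), seed = 7)
  p2 <- generate_phantom(n_per_level = c(5L, 5L, 5L), seed = 7)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$segments), 15L)
  expect_equal(as.vector(table(p1$segments$level)), c(5L, 5L, 5L))
  expect_error(generate_phantom(n_per_level = integer()), "empty")
  # level-mean speeds monotone non-decreasing under the default ranges
  for (s in 1:5) {
    ph <- generate_phantom(seed = s)
    mu <- tapply(ph$segments$mean_speed_mm_s, ph$segments$level, mean)
    expect_true(all(diff(mu) >= 0))
    # and every draw sits inside its level's configured range
    rng <- cbind(1.5 * 2^(0:3), 3 * 2^(0:3))
    for (l in 1:4) {
      v <- ph$segments$mean_speed_mm_s[ph$segments$level == l]
      expect_true(all(v >= rng[l, 1] & v <= rng[l, 2]))
    }
  }
})

test_that("bubble arrivals follow per-segment Poisson statistics", {
  ph <- small_phantom()
  expect_equal(nrow(simulate_mb_truth(ph, mb_rate = 0, seed = 1)), 0L)
  # expected track count = sum of per-segment Poisson means = mb_rate x T
  rate <- 30; dur <- 2
  counts <- vapply(1:20, function(s) {
    tr <- simulate_mb_truth(ph, duration_s = dur, mb_rate = rate, seed = s)
    length(unique(tr$track_id))
  }, 1)
  mu <- rate * dur
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 20))
})

test_that("bubbles advect at the segment speed", {
  ph <- small_phantom()
  tr <- simulate_mb_truth(ph, frame_rate_Hz = 500, duration_s = 0.5,
                          mb_rate = 30, seed = 3)
  one <- tr[tr$track_id == tr$track_id[1], ]
  expect_gt(nrow(one), 2)
  step_um <- sqrt(diff(one$x_um)^2 + diff(one$z_um)^2) / diff(one$frame)
  # v [mm/s] / frame_rate = displacement per frame in mm
  expect_equal(step_um, rep(one$speed_mm_s[1] / 500 * 1000, nrow(one) - 1),
               tolerance = 1e-9)
})

test_that("rendered bubbles match their ground-truth positions", {
  ph <- generate_phantom(n_per_level = c(1L), extent_um = c(400, 400),
                         seed = 5)
  sim <- simulate_mb_frames(ph, duration_s = 0.05, mb_rate = 10,
                            psf_sigma_um = 20, pixel_um = 10, seed = 9)
  tru <- sim$truth
  skip_if(nrow(tru) == 0, "no bubble drawn at this seed")
  # pick a frame with a single bubble: its intensity-weighted centroid must
  # sit on the ground-truth position within 0.05 px
  per_frame <- table(tru$frame)
  f <- as.integer(names(per_frame)[per_frame == 1][1])
  skip_if(is.na(f), "no single-bubble frame")
  img <- Mod(sim$stack$frames[, , f])
  w <- img / sum(img)
  cx <- sum(t(w) * (seq_len(ncol(img)) - 0.5) * 10)
  cz <- sum(w * (seq_len(nrow(img)) - 0.5) * 10)
  row <- tru[tru$frame == f, ]
  expect_lt(abs(cx - row$x_um) / 10, 0.05)
  expect_lt(abs(cz - row$z_um) / 10, 0.05)
})

test_that("fUS series has the configured baseline and evoked plateau", {
  ph <- small_phantom()
  # no effect, no noise: series constant and equal to the baseline map
  v0 <- simulate_fus_series(ph, noise_sigma = 0,
                            effect_map = matrix(0, 15, 15), seed = 2)
  expect_equal(max(apply(v0$series, 2, stats::sd)), 0)
  expect_equal(v0$series[1, ], as.vector(v0$baseline_true))
  # uniform 15% effect, no noise: plateau-sample ratio is exactly 0.15
  v1 <- simulate_fus_series(ph, noise_sigma = 0,
                            effect_map = matrix(0.15, 15, 15), seed = 2)
  plateau <- which(v1$regressor == 1)
  expect_gt(length(plateau), 5)
  ratio <- colMeans(v1$series[plateau, , drop = FALSE]) /
    as.vector(v1$baseline_true) - 1
  expect_equal(ratio, rep(0.15, ncol(v1$series)), tolerance = 1e-6)
  # determinism
  v2 <- simulate_fus_series(ph, seed = 4)
  v3 <- simulate_fus_series(ph, seed = 4)
  expect_identical(v2$series, v3$series)
  expect_equal(nrow(v2$series),
               floor(protocol_duration(stimulus_protocol()) / 2.4) + 1)
})

test_that("fUS block averages recover the injected effect across seeds", {
  ph <- small_phantom()
  A <- 0.15
  est <- vapply(1:12, function(s) {
    v <- simulate_fus_series(ph, noise_sigma = 0.05,
                             effect_map = matrix(A, 15, 15), seed = s)
    plateau <- v$regressor == 1
    rest <- v$times < v$protocol$baseline_s
    mean(colMeans(v$series[plateau, ]) / colMeans(v$series[rest, ]) - 1)
  }, 1)
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - A), 3 * se + 1e-3)
})

test_that("clutter stacks have the constructed rank structure", {
  z0 <- simulate_clutter_frames(0, 1, 0, c(16, 16, 30), seed = 1)
  expect_equal(max(Mod(z0$frames)), 0)
  sv1 <- svd(matrix(simulate_clutter_frames(1, 1, 0, c(16, 16, 30),
                                            seed = 2)$frames, 256, 30))$d
  expect_gt(sv1[1], 0)
  expect_lt(sv1[2] / sv1[1], 1e-10)
  sv3 <- svd(matrix(simulate_clutter_frames(3, 10, 1e-3, c(16, 16, 30),
                                            seed = 3)$frames, 256, 30))$d
  expect_gt(sv3[3] / sv3[4], 10)
})
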