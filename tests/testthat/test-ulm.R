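test_that("Hungarian assignment matches brute-force enumeration", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- fusulm:::solve_assignment(cost)
    ref <- fusulm:::assignment_brute_force(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), ref$cost, tolerance = 1e-12)
  }
  # rectangular padding: more columns than rows
  set.seed(99)
  cost <- matrix(runif(12), 3, 4)
  a <- fusulm:::solve_assignment(cost)
  expect_equal(length(unique(a)), 3L)
})

test_that("localization refines spots to sub-pixel accuracy", {
  # spot on a pixel center: recovered at that center
  img <- spot_image(31, 31, x_um = 15.5, z_um = 15.5, sigma_um = 2)
  loc <- localize_mbs(img, 0.2, 7L, pixel_um = 1)
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$x_um, 15.5, tolerance = 1e-6)
  expect_equal(loc$z_um, 15.5, tolerance = 1e-6)
  # known +0.3 px offset recovered within 0.1 px (noise off)
  img2 <- spot_image(31, 31, x_um = 15.8, z_um = 15.6, sigma_um = 2)
  loc2 <- localize_mbs(img2, 0.2, 7L, pixel_um = 1)
  expect_lt(abs(loc2$x_um - 15.8), 0.1)
  expect_lt(abs(loc2$z_um - 15.6), 0.1)
  # two spots farther apart than twice the window: both found
  img3 <- spot_image(41, 41, 10.5, 10.5, 2) + spot_image(41, 41, 30.5, 30.5, 2)
  expect_equal(nrow(localize_mbs(img3, 0.2, 7L, 1)), 2L)
  # overlapping maxima closer than the window merge to the brighter one
  img4 <- spot_image(41, 41, 18.5, 20.5, 2, amplitude = 1) +
    spot_image(41, 41, 22.5, 20.5, 2, amplitude = 0.6)
  expect_equal(nrow(localize_mbs(img4, 0.2, 7L, 1)), 1L)
})

test_that("localization RMSE stays below half a pixel at 10 dB SNR", {
  set.seed(42)
  n_spots <- 40
  rmse_at <- function(noise_sd) {
    errs <- c()
    for (k in 1:n_spots) {
      x <- runif(1, 12, 20); z <- runif(1, 12, 20)
      img <- spot_image(31, 31, x, z, sigma_um = 2) +
        matrix(rnorm(31^2, 0, noise_sd), 31)
      loc <- localize_mbs(img, 0.45, 7L, 1)
      if (!nrow(loc)) next
      i <- which.min((loc$x_um - x)^2 + (loc$z_um - z)^2)
      errs <- c(errs, (loc$x_um[i] - x)^2 + (loc$z_um[i] - z)^2)
    }
    sqrt(mean(errs))
  }
  # peak amplitude 1, SNR 10 dB -> noise sd 10^(-10/20)
  r10 <- rmse_at(10^(-0.5))
  expect_lt(r10, 0.5)
  # degradation is monotone in noise
  r20 <- rmse_at(10^(-1))
  r30 <- rmse_at(10^(-1.5))
  expect_true(r30 <= r20 && r20 <= r10)
})

test_that("linking builds, separates and splits tracks correctly", {
  # one bubble, contiguous detections -> one track covering all frames
  one <- data.frame(frame = 1:10, x_um = 100 + 2 * (1:10), z_um = 50)
  tr <- link_tracks(one, max_link_um = 5, min_track_length = 5L)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(tr$frame, 1:10)
  # two parallel bubbles separated by 5x the gating radius: never merged
  two <- rbind(data.frame(frame = 1:10, x_um = 2 * (1:10), z_um = 0),
               data.frame(frame = 1:10, x_um = 2 * (1:10), z_um = 25))
  tr2 <- link_tracks(two, max_link_um = 5, min_track_length = 5L)
  expect_equal(length(unique(tr2$track_id)), 2L)
  by_id <- split(tr2$z_um, tr2$track_id)
  expect_true(all(vapply(by_id, function(z) length(unique(z)) == 1L, TRUE)))
  # a detection gap longer than max_gap splits the track
  gap <- data.frame(frame = c(1:6, 12:17), x_um = 10, z_um = 10)
  tr3 <- link_tracks(gap, max_link_um = 5, max_gap_frames = 2L,
                     min_track_length = 3L)
  expect_equal(length(unique(tr3$track_id)), 2L)
  # while a gap within max_gap is bridged
  gap2 <- data.frame(frame = c(1:6, 9:14), x_um = 10, z_um = 10)
  tr4 <- link_tracks(gap2, max_link_um = 5, max_gap_frames = 2L,
                     min_track_length = 3L)
  expect_equal(length(unique(tr4$track_id)), 1L)
})

test_that("track speeds follow displacement x frame rate", {
  still <- data.frame(frame = 1:8, x_um = 5, z_um = 5)
  expect_equal(track_speed(still, 500)$mean_speed_mm_s, 0)
  # 2 um per frame at 500 Hz = 1 mm/s
  mov <- data.frame(frame = 1:8, x_um = 2 * (1:8), z_um = 0)
  sp <- track_speed(mov, 500)
  expect_equal(sp$step_speeds_mm_s, rep(1, 7))
  expect_equal(sp$mean_speed_mm_s, 1)
  expect_error(track_speed(mov[1, ], 500), "fewer than 2")
  # position smoothing preserves the speed of a constant-velocity track
  expect_equal(track_speed(mov, 500, smooth_frames = 3L)$mean_speed_mm_s, 1)
})

test_that("simulated 10 mm/s bubbles are tracked within 5% (noise off)", {
  ph <- generate_phantom(n_per_level = c(2L), speed_ranges = cbind(10, 10),
                         diameter_ranges = cbind(30, 30),
                         extent_um = c(1000, 1000), seed = 8)
  sim <- simulate_mb_frames(ph, duration_s = 0.3, mb_rate = 15,
                            psf_sigma_um = 20, pixel_um = 10, seed = 12)
  locs <- localize_stack(sim$stack, 0.3)
  tracks <- link_tracks(locs, max_link_um = 40, min_track_length = 5L)
  skip_if(nrow(tracks) == 0, "no track at this seed")
  v <- vapply(unique(tracks$track_id), function(id)
    track_speed(tracks[tracks$track_id == id, ], 500)$mean_speed_mm_s, 1)
  expect_lt(abs(stats::median(v) - 10) / 10, 0.05)
})

test_that("rasterization conserves samples and matches the polyline oracle", {
  empty <- rasterize_tracks(data.frame(track_id = integer(),
                                       frame = integer(), x_um = numeric(),
                                       z_um = numeric()),
                            500, 5, c(200, 200))
  expect_equal(sum(empty$density), 0L)
  expect_true(all(is.na(empty$speed)))
  # one straight constant-speed track: speed map equals v on its support
  tr <- data.frame(track_id = 1L, frame = 1:6,
                   x_um = 20 + 10 * (0:5), z_um = 35 + 4 * (0:5))
  m <- rasterize_tracks(tr, 500, 5, c(200, 200))
  v_true <- sqrt(10^2 + 4^2) * 500 / 1000
  expect_equal(unique(m$speed[m$density > 0]), v_true, tolerance = 1e-9)
  # conservation: total counts equal total interpolated samples
  expect_equal(sum(m$density), m$n_samples)
  # support identical to the independent line-drawing oracle
  expect_equal(m$density > 0, rasterize_oracle_support(tr, 5, c(200, 200)))
  # a second, jagged polyline
  set.seed(13)
  tr2 <- data.frame(track_id = 1L, frame = 1:9,
                    x_um = cumsum(runif(9, 5, 25)),
                    z_um = 100 + cumsum(rnorm(9, 0, 12)))
  m2 <- rasterize_tracks(tr2, 500, 5, c(250, 250))
  expect_equal(m2$density > 0, rasterize_oracle_support(tr2, 5, c(250, 250)))
  expect_equal(sum(m2$density), m2$n_samples)
})

test_that("speed maps reproduce the phantom speed hierarchy", {
  ph <- small_phantom()
  sim <- simulate_mb_frames(ph, duration_s = 1, mb_rate = 40,
                            psf_sigma_um = 20, clutter_rank = 3L,
                            clutter_amplitude = 20, noise_sigma = 0.02,
                            rate_weighting = "length", seed = 33)
  filt <- svd_clutter_filter(sim$stack, 4L)
  locs <- localize_stack(filt, 0.3)
  tracks <- link_tracks(locs, max_link_um = 60, min_track_length = 5L)
  maps <- rasterize_tracks(tracks, 500, 5, ph$extent_um,
                           speed_smooth_frames = 5L)
  segs <- ph$segments
  occ <- which(maps$density > 0, arr.ind = TRUE)
  px <- (occ[, 2] - 0.5) * 5; pz <- (occ[, 1] - 0.5) * 5
  D <- vapply(seq_len(nrow(segs)),
              function(i) point_segment_dist(px, pz, segs[i, ]),
              numeric(length(px)))
  ord <- t(apply(D, 1, order))
  d1 <- D[cbind(seq_len(nrow(D)), ord[, 1])]
  d2 <- D[cbind(seq_len(nrow(D)), ord[, 2])]
  keep <- d1 < 10 & d2 > 40        # exclusive support, no crossing pixels
  v <- maps$speed[maps$density > 0][keep]
  seg_of <- ord[keep, 1]
  per_seg <- tapply(v, seg_of, stats::median)
  ids <- as.integer(names(per_seg))
  rec <- tapply(per_seg, segs$level[ids], mean)
  tru <- tapply(segs$mean_speed_mm_s[ids], segs$level[ids], mean)
  expect_equal(length(rec), 4L)
  expect_true(all(abs(rec / tru - 1) < 0.10))
  # and the recovered hierarchy is ordered
  expect_true(all(diff(rec) > 0))
})
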