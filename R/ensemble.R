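#' Simulate one combined fUS + ULM acquisition
#'
#' Generates a vascular phantom, runs the functional arm (stimulus-locked
#' Doppler voxel series, voxel-wise GLM) and the microvascular arm
#' (microbubble trajectories with localization jitter, optimal-assignment
#' tracking, super-resolved speed map), and pairs the resulting maps on the
#' common super-resolved grid.
#'
#' The default phantom couples the absolute evoked response to flow speed
#' through the flow-weighted baseline (larger/faster vessels carry more
#' Doppler power) while keeping the relative evoked fraction constant
#' across hierarchy levels — so the absolute CBV change tracks vessel rank
#' but the relative change does not.
#'
#' @param seed integer master seed for this acquisition.
#' @param phantom_args list of overrides for [generate_phantom()].
#' @param protocol a [stimulus_protocol()].
#' @param hrf a [hemodynamic_model()].
#' @param noise_sigma fUS multiplicative noise sd.
#' @param dt,voxel_um functional sampling interval (s) and voxel size (um).
#' @param frame_rate_Hz,ulm_duration_s,mb_rate microbubble acquisition rate,
#'   duration and arrival rate.
#' @param loc_noise_um localization jitter applied to ground-truth bubble
#'   positions (um).
#' @param max_link_um,min_track_length tracker settings (see
#'   [link_tracks()]).
#' @param grid_um super-resolved grid pitch (um).
#' @param speed_smooth_frames position smoothing for speed estimation.
#' @return an [acquisition_pair()] object; the phantom and GLM fit are
#'   attached as attributes `phantom` and `glm`.
#' @export
simulate_acquisition <- function(seed = 1L, phantom_args = list(),
                                 protocol = stimulus_protocol(),
                                 hrf = hemodynamic_model(),
                                 noise_sigma = 0.05, dt = 2.4,
                                 voxel_um = 100, frame_rate_Hz = 500,
                                 ulm_duration_s = 1.5, mb_rate = 30,
                                 loc_noise_um = 1, max_link_um = 60,
                                 min_track_length = 5L, grid_um = 5,
                                 speed_smooth_frames = 5L) {
  phantom <- do.call(generate_phantom,
                     c(list(seed = derive_seed(seed, "acq_phantom")),
                       phantom_args))
  vts <- simulate_fus_series(phantom, protocol, hrf,
                             noise_sigma = noise_sigma, dt = dt,
                             voxel_um = voxel_um,
                             seed = derive_seed(seed, "acq_fus"))
  X <- build_design(protocol, hrf, dt = dt, n_samples = nrow(vts$series))
  fit <- fit_voxelwise(vts, X)

  truth <- simulate_mb_truth(phantom, frame_rate_Hz, ulm_duration_s,
                             mb_rate, rate_weighting = "length",
                             seed = derive_seed(seed, "acq_mb"))
  locs <- truth[, c("frame", "x_um", "z_um")]
  if (loc_noise_um > 0 && nrow(locs)) {
    locs[, c("x_um", "z_um")] <- locs[, c("x_um", "z_um")] +
      with_seed(derive_seed(seed, "acq_locnoise"),
                matrix(stats::rnorm(2 * nrow(locs), 0, loc_noise_um),
                       ncol = 2))
  }
  tracks <- link_tracks(locs, max_link_um = max_link_um,
                        min_track_length = min_track_length)
  ulm <- rasterize_tracks(tracks, frame_rate_Hz, grid_um = grid_um,
                          extent_um = phantom$extent_um,
                          speed_smooth_frames = speed_smooth_frames)
  pair <- acquisition_pair(fit, ulm, voxel_um = voxel_um)
  attr(pair, "phantom") <- phantom
  attr(pair, "glm") <- fit
  pair
}

#' Simulate a cohort of acquisitions and run the group analysis
#'
#' Builds `n_acquisitions` independent synthetic acquisitions (each with its
#' own phantom and noise) and correlates the absolute (dcbv) and relative
#' (rcbv) evoked responses with microbubble speed at the group level.
#'
#' @param n_acquisitions number of acquisitions in the cohort.
#' @param seed master seed; acquisition `i` uses sub-stream `i`.
#' @param ... forwarded to [simulate_acquisition()].
#' @return list with `pairs`, and `group_result` objects `dcbv` and `rcbv`.
#' @export
simulate_group_ensemble <- function(n_acquisitions = 10L, seed = 1L, ...) {
  stopifnot(n_acquisitions >= 1)
  pairs <- lapply(seq_len(n_acquisitions), function(i)
    simulate_acquisition(seed = derive_seed(seed, paste0("acq", i)), ...))
  list(pairs = pairs,
       dcbv = group_speed_correlation(pairs, "dcbv"),
       rcbv = group_speed_correlation(pairs, "rcbv"))
}
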