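#' Complex beamformed frame stack
#'
#' Container for the slow-time sequence of complex beamformed frames of one
#' imaging plane, stored as a `(nz, nx, nt)` complex array.
#'
#' @param frames complex (or numeric) array `(nz, nx, nt)`.
#' @param frame_rate_Hz compounded frame rate (Hz).
#' @param pixel_um in-plane pixel size (um).
#' @param plane_id optional plane identifier.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_Hz, pixel_um, plane_id = 1L) {
  stopifnot(length(dim(frames)) == 3L, frame_rate_Hz > 0, pixel_um > 0)
  if (!is.complex(frames)) frames <- frames + 0i
  if (!all(is.finite(Re(frames))) || !all(is.finite(Im(frames))))
    stop("frame stack contains non-finite values")
  structure(list(frames = frames, frame_rate_Hz = frame_rate_Hz,
                 pixel_um = pixel_um, plane_id = plane_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame stack: %d x %d px, %d frames at %g Hz (%g um/px)\n",
              d[1], d[2], d[3], x$frame_rate_Hz, x$pixel_um))
  invisible(x)
}

#' Ground-truth microbubble trajectories through a phantom
#'
#' Draws bubble arrivals on each vessel segment as a Poisson process with
#' rate proportional to the segment's volumetric flow (speed x cross
#' section), normalized so that `mb_rate` is the expected total number of
#' arrivals per second. Each bubble is advected along its segment at the
#' segment's mean speed, optionally with Brownian positional jitter, and
#' sampled at the frame clock until it exits the segment.
#'
#' @param phantom a [generate_phantom()] object.
#' @param frame_rate_Hz frame rate (Hz).
#' @param duration_s recording duration (s).
#' @param mb_rate expected bubble arrivals per second (whole field).
#' @param jitter_um Brownian jitter standard deviation per frame (um).
#' @param rate_weighting how arrivals distribute over segments: `"flow"`
#'   (proportional to speed x cross-section, the default), `"length"`
#'   (proportional to segment length, giving comparable coverage of all
#'   hierarchy levels), or `"uniform"`.
#' @param seed integer seed.
#' @return data.frame with columns `frame`, `track_id`, `x_um`, `z_um`,
#'   `amplitude`, `segment`, `level`, `speed_mm_s`.
#' @export
simulate_mb_truth <- function(phantom, frame_rate_Hz = 500, duration_s = 1,
                              mb_rate = 20, jitter_um = 0,
                              rate_weighting = c("flow", "length", "uniform"),
                              seed = 1L) {
  rate_weighting <- match.arg(rate_weighting)
  stopifnot(inherits(phantom, "vascular_phantom"), duration_s > 0,
            mb_rate >= 0, frame_rate_Hz > 0)
  empty <- data.frame(frame = integer(), track_id = integer(),
                      x_um = numeric(), z_um = numeric(),
                      amplitude = numeric(), segment = integer(),
                      level = integer(), speed_mm_s = numeric())
  if (mb_rate == 0) return(empty)
  s <- phantom$segments
  len <- segment_lengths(phantom)
  w <- switch(rate_weighting,
              flow = segment_flows(phantom),
              length = len,
              uniform = rep(1, nrow(s)))
  lam <- mb_rate * w / sum(w)              # arrivals / s per segment
  tfr <- (seq_len(ceiling(duration_s * frame_rate_Hz)) - 1) / frame_rate_Hz

  with_seed(derive_seed(seed, "mb_truth"), {
    rows <- list()
    tid <- 0L
    for (i in seq_len(nrow(s))) {
      n_arr <- stats::rpois(1, lam[i] * duration_s)
      if (n_arr == 0) next
      t0 <- stats::runif(n_arr, 0, duration_s)
      v_um_s <- s$mean_speed_mm_s[i] * 1000
      ux <- (s$x1_um[i] - s$x0_um[i]) / len[i]
      uz <- (s$z1_um[i] - s$z0_um[i]) / len[i]
      for (b in seq_len(n_arr)) {
        dist <- (tfr - t0[b]) * v_um_s
        k <- which(dist >= 0 & dist < len[i])
        if (!length(k)) next
        tid <- tid + 1L
        x <- s$x0_um[i] + ux * dist[k]
        z <- s$z0_um[i] + uz * dist[k]
        if (jitter_um > 0 && length(k) > 0) {
          x <- x + cumsum(stats::rnorm(length(k), 0, jitter_um))
          z <- z + cumsum(stats::rnorm(length(k), 0, jitter_um))
        }
        rows[[tid]] <- data.frame(
          frame = k, track_id = tid, x_um = x, z_um = z,
          amplitude = stats::runif(1, 0.8, 1.2), segment = i,
          level = s$level[i], speed_mm_s = s$mean_speed_mm_s[i])
      }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out <- out[out$x_um >= 0 & out$x_um <= phantom$extent_um[1] &
                 out$z_um >= 0 & out$z_um <= phantom$extent_um[2], ]
    rownames(out) <- NULL
    out
  })
}

# Add isotropic Gaussian spots (complex, per-track random phase) to a complex
# frame array in place. truth rows carry continuous um positions.
render_spots <- function(frames, truth, pixel_um, psf_sigma_um, phase) {
  d <- dim(frames)
  half <- ceiling(4 * psf_sigma_um / pixel_um)
  for (r in seq_len(nrow(truth))) {
    cx <- truth$x_um[r] / pixel_um + 0.5   # fractional pixel coords (1-based)
    cz <- truth$z_um[r] / pixel_um + 0.5
    i0 <- max(1L, floor(cz - half)); i1 <- min(d[1], ceiling(cz + half))
    j0 <- max(1L, floor(cx - half)); j1 <- min(d[2], ceiling(cx + half))
    if (i0 > i1 || j0 > j1) next
    zz <- (i0:i1 - cz) * pixel_um
    xx <- (j0:j1 - cx) * pixel_um
    g <- outer(exp(-zz^2 / (2 * psf_sigma_um^2)),
               exp(-xx^2 / (2 * psf_sigma_um^2)))
    amp <- truth$amplitude[r] * exp(1i * phase[truth$track_id[r]])
    frames[i0:i1, j0:j1, truth$frame[r]] <-
      frames[i0:i1, j0:j1, truth$frame[r]] + amp * g
  }
  frames
}

#' Simulate a microbubble acquisition
#'
#' Renders ground-truth bubble trajectories (see [simulate_mb_truth()]) as
#' isotropic Gaussian intensity spots with a per-track random echo phase,
#' adds low-rank tissue clutter and complex white noise, and returns both
#' the frame stack and the ground-truth localization/track table.
#'
#' @inheritParams simulate_mb_truth
#' @param psf_sigma_um Gaussian point-spread sigma (um).
#' @param pixel_um reconstruction pixel size (um).
#' @param clutter_rank,clutter_amplitude rank and amplitude of the additive
#'   low-rank tissue clutter (0 disables it).
#' @param noise_sigma standard deviation of the complex white noise magnitude
#'   (per-pixel `E|n|^2 = noise_sigma^2`).
#' @return list with `stack` (a [frame_stack()]) and `truth` (data.frame).
#' @export
simulate_mb_frames <- function(phantom, frame_rate_Hz = 500, duration_s = 1,
                               mb_rate = 20, psf_sigma_um = 50,
                               pixel_um = 10, clutter_rank = 0L,
                               clutter_amplitude = 0, noise_sigma = 0,
                               jitter_um = 0,
                               rate_weighting = "flow", seed = 1L) {
  stopifnot(psf_sigma_um > 0, pixel_um > 0)
  if (psf_sigma_um < pixel_um)
    warning("PSF sigma below the pixel size; localization is grid-limited")
  truth <- simulate_mb_truth(phantom, frame_rate_Hz, duration_s, mb_rate,
                             jitter_um = jitter_um,
                             rate_weighting = rate_weighting, seed = seed)
  nz <- ceiling(phantom$extent_um[2] / pixel_um)
  nx <- ceiling(phantom$extent_um[1] / pixel_um)
  nt <- ceiling(duration_s * frame_rate_Hz)
  frames <- array(0 + 0i, dim = c(nz, nx, nt))
  if (nrow(truth)) {
    phase <- with_seed(derive_seed(seed, "mb_phase"),
                       stats::runif(max(truth$track_id), 0, 2 * pi))
    frames <- render_spots(frames, truth, pixel_um, psf_sigma_um, phase)
  }
  if (clutter_rank > 0 && clutter_amplitude > 0) {
    cl <- simulate_clutter_frames(clutter_rank, clutter_amplitude,
                                  noise_sigma = 0, shape = c(nz, nx, nt),
                                  frame_rate_Hz = frame_rate_Hz,
                                  pixel_um = pixel_um,
                                  seed = derive_seed(seed, "clutter"))
    frames <- frames + cl$frames
  }
  if (noise_sigma > 0) {
    frames <- frames + with_seed(derive_seed(seed, "mb_noise"), {
      sd1 <- noise_sigma / sqrt(2)
      array(complex(real = stats::rnorm(nz * nx * nt, 0, sd1),
                    imaginary = stats::rnorm(nz * nx * nt, 0, sd1)),
            dim = c(nz, nx, nt))
    })
  }
  list(stack = frame_stack(frames, frame_rate_Hz, pixel_um), truth = truth)
}

#' Simulate low-rank tissue clutter frames
#'
#' Sum of `rank` separable components, each the outer product of a spatially
#' smooth complex field and a slowly varying temporal course (distinct
#' sub-hertz-scale frequencies relative to the stack length), plus complex
#' white noise. With zero noise the slow-time Casorati matrix has exactly
#' `rank` nonzero singular values.
#'
#' @param rank number of clutter components (>= 0).
#' @param amplitude component amplitude scale.
#' @param noise_sigma complex white-noise magnitude sd.
#' @param shape stack dimensions `c(nz, nx, nt)`.
#' @param frame_rate_Hz,pixel_um metadata for the returned stack.
#' @param seed integer seed.
#' @return a [frame_stack()].
#' @export
simulate_clutter_frames <- function(rank, amplitude = 1, noise_sigma = 0,
                                    shape = c(32, 32, 100),
                                    frame_rate_Hz = 500, pixel_um = 10,
                                    seed = 1L) {
  stopifnot(rank >= 0, length(shape) == 3L)
  nz <- shape[1]; nx <- shape[2]; nt <- shape[3]
  frames <- array(0 + 0i, dim = shape)
  if (rank > 0) {
    frames <- frames + with_seed(derive_seed(seed, "clutter_fields"), {
      acc <- array(0 + 0i, dim = shape)
      tt <- seq_len(nt) / nt
      for (k in seq_len(rank)) {
        # smooth spatial field: few random low-frequency Fourier modes
        sp <- matrix(0 + 0i, nz, nx)
        for (m in 1:3) {
          fz <- stats::runif(1, 0.2, 1.5); fx <- stats::runif(1, 0.2, 1.5)
          ph <- stats::runif(2, 0, 2 * pi)
          sp <- sp + outer(cos(2 * pi * fz * seq_len(nz) / nz + ph[1]),
                           cos(2 * pi * fx * seq_len(nx) / nx + ph[2])) *
            exp(1i * stats::runif(1, 0, 2 * pi))
        }
        # distinct slow temporal frequencies keep components independent
        g <- cos(2 * pi * (0.3 + 0.5 * (k - 1)) * tt +
                   stats::runif(1, 0, 2 * pi))
        acc <- acc + amplitude * outer(sp, g)
      }
      acc
    })
  }
  if (noise_sigma > 0) {
    frames <- frames + with_seed(derive_seed(seed, "clutter_noise"), {
      sd1 <- noise_sigma / sqrt(2)
      array(complex(real = stats::rnorm(prod(shape), 0, sd1),
                    imaginary = stats::rnorm(prod(shape), 0, sd1)),
            dim = shape)
    })
  }
  frame_stack(frames, frame_rate_Hz, pixel_um)
}

#' Stimulus indicator signal
#'
#' Box-car ON/OFF signal of a [stimulus_protocol()] evaluated at arbitrary
#' times (1 during ON blocks, 0 otherwise).
#'
#' @param protocol a [stimulus_protocol()].
#' @param times numeric vector of times (s).
#' @return 0/1 numeric vector.
#' @export
stimulus_signal <- function(protocol, times) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  s <- numeric(length(times))
  period <- protocol$on_s + protocol$off_s
  for (j in seq_len(protocol$n_repeats)) {
    t_on <- protocol$baseline_s + (j - 1) * period
    s[times >= t_on & times < t_on + protocol$on_s] <- 1
  }
  s
}

#' Simulate stimulus-locked power Doppler voxel time series
#'
#' Voxel baselines come from the phantom's flow-weighted vessel density
#' (plus a positive tissue floor); the evoked response multiplies each
#' baseline by `1 + A(v) x(t)` where `x` is the stimulus box-car convolved
#' with the hemodynamic response and rescaled to unit plateau, so `A(v)` is
#' the steady-state fractional CBV increase of voxel `v`. Multiplicative
#' Gaussian noise models Doppler power fluctuations.
#'
#' @param phantom a [generate_phantom()] object.
#' @param protocol a [stimulus_protocol()].
#' @param hrf a [hemodynamic_model()].
#' @param noise_sigma multiplicative noise sd (e.g. 0.05 for 5%).
#' @param dt volume sampling interval (s); 2.4 s for the 4-stop functional
#'   motor scheme.
#' @param voxel_um in-plane voxel size (um).
#' @param baseline_floor positive tissue background added to every voxel.
#' @param pd_scale amplitude of the vessel-density contribution to baseline.
#' @param effect_map optional `nz x nx` matrix of evoked fractions overriding
#'   the phantom-derived map.
#' @param seed integer seed.
#' @return an object of class `voxel_time_series`: list with `series`
#'   (`nt x nvox` matrix, voxels in column-major grid order), `dims`
#'   `c(nz, nx)`, `dt`, `voxel_um`, `times`, `regressor`, ground-truth
#'   `baseline_true` and `effect_true` matrices, and the protocol.
#' @export
simulate_fus_series <- function(phantom, protocol = stimulus_protocol(),
                                hrf = hemodynamic_model(),
                                noise_sigma = 0.05, dt = 2.4,
                                voxel_um = 100, baseline_floor = 1,
                                pd_scale = 10, effect_map = NULL,
                                seed = 1L) {
  stopifnot(inherits(phantom, "vascular_phantom"), dt > 0, voxel_um > 0,
            baseline_floor > 0, noise_sigma >= 0)
  nvx <- ceiling(phantom$extent_um[1] / voxel_um)
  nvz <- ceiling(phantom$extent_um[2] / voxel_um)

  # flow-weighted vessel density and evoked fraction per voxel
  dens <- matrix(0, nvz, nvx)
  evw <- matrix(0, nvz, nvx)
  s <- phantom$segments
  len <- segment_lengths(phantom)
  flow <- segment_flows(phantom)
  step <- voxel_um / 4
  for (i in seq_len(nrow(s))) {
    n_sub <- max(2L, ceiling(len[i] / step))
    f <- (seq_len(n_sub) - 0.5) / n_sub
    x <- s$x0_um[i] + f * (s$x1_um[i] - s$x0_um[i])
    z <- s$z0_um[i] + f * (s$z1_um[i] - s$z0_um[i])
    ix <- pmin(pmax(ceiling(x / voxel_um), 1L), nvx)
    iz <- pmin(pmax(ceiling(z / voxel_um), 1L), nvz)
    w <- flow[i] * len[i] / n_sub
    for (j in seq_len(n_sub)) {
      dens[iz[j], ix[j]] <- dens[iz[j], ix[j]] + w
      evw[iz[j], ix[j]] <- evw[iz[j], ix[j]] + w * s$evoked_fraction[i]
    }
  }
  B <- baseline_floor + if (max(dens) > 0) pd_scale * dens / max(dens) else dens
  A <- ifelse(dens > 0, evw / pmax(dens, .Machine$double.eps), 0)
  if (!is.null(effect_map)) {
    stopifnot(all(dim(effect_map) == c(nvz, nvx)), all(effect_map >= 0))
    A <- effect_map
  }

  total <- protocol_duration(protocol)
  n <- floor(total / dt) + 1L
  times <- (seq_len(n) - 1) * dt
  x_reg <- convolved_regressor(protocol, hrf, n, dt)

  series <- with_seed(derive_seed(seed, "fus_noise"), {
    base <- outer(x_reg, as.vector(A))        # nt x nvox
    pd <- sweep(1 + base, 2, as.vector(B), "*")
    if (noise_sigma > 0)
      pd <- pd * (1 + matrix(stats::rnorm(length(pd), 0, noise_sigma),
                             nrow = n))
    pd
  })
  floor_val <- 1e-6 * min(B)
  if (any(series <= 0)) {
    warning("negative simulated power Doppler values clipped at positive floor")
    series[series <= 0] <- floor_val
  }
  structure(list(series = series, dims = c(nvz, nvx), dt = dt,
                 voxel_um = voxel_um, times = times, regressor = x_reg,
                 baseline_true = B, effect_true = A, protocol = protocol),
            class = "voxel_time_series")
}

#' @export
print.voxel_time_series <- function(x, ...) {
  cat(sprintf("voxel time series: %d samples (dt %.2f s) x %d voxels (%d x %d grid, %g um)\n",
              nrow(x$series), x$dt, ncol(x$series), x$dims[1], x$dims[2],
              x$voxel_um))
  invisible(x)
}
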