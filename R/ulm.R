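# separable Gaussian blur with border renormalization (matched pre-filter
# for detection under noise)
gauss_blur <- function(mat, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  smooth1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (j in -r:r) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)
      w <- k[j + r + 1]
      out <- out + w * m[src, , drop = FALSE]
      norm <- norm + w
    }
    out / norm
  }
  t(smooth1(t(smooth1(mat))))
}

#' Localize microbubbles in one filtered frame
#'
#' Detects regional intensity maxima above a threshold — after an optional
#' matched Gaussian pre-filter that suppresses pixel noise — and refines
#' each to sub-pixel precision by a background-subtracted intensity-weighted
#' centroid over a square window. Maxima closer than the window size are
#' merged into the brighter one.
#'
#' @param intensity real non-negative matrix (`nz x nx`), e.g.
#'   `Mod(frames)^2` or `Mod(frames)` of a clutter-filtered stack.
#' @param detect_threshold detection threshold on the (pre-filtered)
#'   intensity (> 0).
#' @param window_px odd centroid window size in pixels.
#' @param pixel_um pixel size (um).
#' @param presmooth_sigma_px sigma of the Gaussian pre-filter in pixels
#'   (0 disables it). Note the filter lowers spot peaks, so thresholds apply
#'   to the smoothed image.
#' @return data.frame with `x_um`, `z_um`, `intensity` (peak value), one row
#'   per detected bubble (possibly empty).
#' @export
localize_mbs <- function(intensity, detect_threshold, window_px = 7L,
                         pixel_um = 10, presmooth_sigma_px = 1) {
  stopifnot(is.matrix(intensity), detect_threshold > 0,
            window_px %% 2 == 1, window_px >= 3, pixel_um > 0)
  if (presmooth_sigma_px > 0)
    intensity <- gauss_blur(intensity, presmooth_sigma_px)
  nz <- nrow(intensity); nx <- ncol(intensity)
  empty <- data.frame(x_um = numeric(), z_um = numeric(),
                      intensity = numeric())
  pad <- matrix(-Inf, nz + 2, nx + 2)
  pad[2:(nz + 1), 2:(nx + 1)] <- intensity
  ctr <- pad[2:(nz + 1), 2:(nx + 1)]
  ismax <- ctr >= detect_threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & ctr >= pad[(2 + di):(nz + 1 + di), (2 + dj):(nx + 1 + dj)]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)

  # merge near-duplicate maxima: keep the brighter of any pair closer than
  # the window
  ord <- order(intensity[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    if (!keep[k]) next
    if (k < nrow(idx)) {
      later <- (k + 1):nrow(idx)
      d2 <- (idx[later, 1] - idx[k, 1])^2 + (idx[later, 2] - idx[k, 2])^2
      keep[later][d2 < window_px^2] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]

  half <- (window_px - 1L) %/% 2L
  out <- matrix(0, nrow(idx), 3)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    i0 <- max(1L, i - half); i1 <- min(nz, i + half)
    j0 <- max(1L, j - half); j1 <- min(nx, j + half)
    w <- intensity[i0:i1, j0:j1, drop = FALSE]
    w <- pmax(w - min(w), 0)
    sw <- sum(w)
    if (sw == 0) { ci <- i; cj <- j } else {
      ci <- sum(rowSums(w) * (i0:i1)) / sw
      cj <- sum(colSums(w) * (j0:j1)) / sw
    }
    out[k, ] <- c((cj - 0.5) * pixel_um, (ci - 0.5) * pixel_um,
                  intensity[i, j])
  }
  data.frame(x_um = out[, 1], z_um = out[, 2], intensity = out[, 3])
}

#' Localize microbubbles across a frame stack
#'
#' Applies [localize_mbs()] to the magnitude of every frame.
#'
#' @param stack a (clutter-filtered) [frame_stack()].
#' @param detect_threshold threshold on `Mod(frame)`.
#' @param window_px odd centroid window (px).
#' @param presmooth_sigma_px Gaussian pre-filter sigma (px), see
#'   [localize_mbs()].
#' @return data.frame with `frame`, `x_um`, `z_um`, `intensity`.
#' @export
localize_stack <- function(stack, detect_threshold, window_px = 7L,
                           presmooth_sigma_px = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- dim(stack$frames)[3]
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    loc <- localize_mbs(Mod(stack$frames[, , k]), detect_threshold,
                        window_px, stack$pixel_um, presmooth_sigma_px)
    if (nrow(loc)) out[[k]] <- cbind(frame = k, loc)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), z_um = numeric(),
                      intensity = numeric())
  rownames(res) <- NULL
  res
}

#' Link localizations into microbubble tracks
#'
#' Frame-to-frame association by optimal (Hungarian) assignment minimizing
#' total displacement. Links beyond `max_link_um` per frame of gap are
#' rejected; a track missing detections for more than `max_gap_frames`
#' frames is closed; tracks shorter than `min_track_length` localizations
#' are discarded.
#'
#' @param locs data.frame with `frame`, `x_um`, `z_um` (and optionally
#'   `intensity`), as from [localize_stack()].
#' @param max_link_um gating radius per frame of gap (um).
#' @param max_gap_frames allowed missed detections before a track closes.
#' @param min_track_length minimum localizations per retained track.
#' @return data.frame with `track_id`, `frame`, `x_um`, `z_um`, `intensity`,
#'   ordered by track then frame.
#' @export
link_tracks <- function(locs, max_link_um = 20, max_gap_frames = 2L,
                        min_track_length = 5L) {
  stopifnot(all(c("frame", "x_um", "z_um") %in% names(locs)),
            max_link_um > 0, max_gap_frames >= 0, min_track_length >= 1)
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), z_um = numeric(),
                      intensity = numeric())
  if (!nrow(locs)) return(empty)
  if (is.null(locs$intensity)) locs$intensity <- NA_real_
  locs <- locs[order(locs$frame), ]
  BIG <- 1e9

  tracks <- list()          # closed + open track row-lists
  open <- integer()         # indices into `tracks` of open tracks
  last_frame <- numeric(); last_x <- numeric(); last_z <- numeric()
  for (f in sort(unique(locs$frame))) {
    det <- locs[locs$frame == f, , drop = FALSE]
    nd <- nrow(det)
    # close stale tracks
    if (length(open)) {
      stale <- f - last_frame > max_gap_frames + 1
      open <- open[!stale]
      last_frame <- last_frame[!stale]
      last_x <- last_x[!stale]; last_z <- last_z[!stale]
    }
    na <- length(open)
    assigned_det <- rep(FALSE, nd)
    if (na > 0 && nd > 0) {
      gaps <- f - last_frame
      d <- sqrt(outer(last_x, det$x_um, "-")^2 +
                  outer(last_z, det$z_um, "-")^2)
      gate <- d <= max_link_um * gaps
      cost <- ifelse(gate, d, BIG)
      nn <- max(na, nd)
      sq <- matrix(BIG, nn, nn)
      sq[seq_len(na), seq_len(nd)] <- cost
      a <- solve_assignment(sq)
      for (ti in seq_len(na)) {
        j <- a[ti]
        if (j <= nd && gate[ti, j]) {
          tk <- open[ti]
          tracks[[tk]] <- rbind(tracks[[tk]],
                                data.frame(frame = f, x_um = det$x_um[j],
                                           z_um = det$z_um[j],
                                           intensity = det$intensity[j]))
          last_frame[ti] <- f
          last_x[ti] <- det$x_um[j]; last_z[ti] <- det$z_um[j]
          assigned_det[j] <- TRUE
        }
      }
    }
    # unassigned detections start new tracks
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <-
        data.frame(frame = f, x_um = det$x_um[j], z_um = det$z_um[j],
                   intensity = det$intensity[j])
      open <- c(open, length(tracks))
      last_frame <- c(last_frame, f)
      last_x <- c(last_x, det$x_um[j]); last_z <- c(last_z, det$z_um[j])
    }
  }
  keep <- vapply(tracks, nrow, 1L) >= min_track_length
  tracks <- tracks[keep]
  if (!length(tracks)) return(empty)
  out <- do.call(rbind, Map(function(tr, id) cbind(track_id = id, tr),
                            tracks, seq_along(tracks)))
  rownames(out) <- NULL
  out
}

#' Per-step and mean speed of a track
#'
#' Step speed is the Euclidean displacement between consecutive
#' localizations times the frame rate, divided by the frame gap; reported
#' in mm/s.
#'
#' Optional centered moving-average position smoothing reduces the upward
#' bias that localization jitter induces on slow flows; for a
#' constant-velocity track the average preserves the velocity exactly.
#' Smoothing trims `(smooth_frames - 1) / 2` localizations at each end.
#'
#' @param track data.frame of one track (`frame`, `x_um`, `z_um`), frames
#'   strictly increasing.
#' @param frame_rate_Hz frame rate (Hz).
#' @param smooth_frames odd moving-average window on positions (1 = none).
#' @return list with `step_speeds_mm_s`, `mean_speed_mm_s`, and the
#'   (possibly trimmed) `frames`, `x_um`, `z_um` the steps connect.
#' @export
track_speed <- function(track, frame_rate_Hz, smooth_frames = 1L) {
  stopifnot(frame_rate_Hz > 0, smooth_frames >= 1, smooth_frames %% 2 == 1)
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 2) stop("track has fewer than 2 localizations; speed undefined")
  x <- track$x_um; z <- track$z_um; fr <- track$frame
  if (smooth_frames > 1 && n > smooth_frames) {
    k <- rep(1 / smooth_frames, smooth_frames)
    xs <- stats::filter(x, k, sides = 2)
    zs <- stats::filter(z, k, sides = 2)
    ok <- !is.na(xs)
    x <- as.numeric(xs[ok]); z <- as.numeric(zs[ok]); fr <- fr[ok]
  }
  gaps <- diff(fr)
  stopifnot(all(gaps > 0))
  d_um <- sqrt(diff(x)^2 + diff(z)^2)
  v <- d_um * frame_rate_Hz / gaps / 1000
  list(step_speeds_mm_s = v, mean_speed_mm_s = mean(v),
       frames = fr, x_um = x, z_um = z)
}

#' Rasterize tracks into super-resolved density and speed maps
#'
#' Each track step is resampled by linear interpolation at the grid
#' resolution (so fast bubbles leave no gaps); every interpolated sample
#' increments the density count of its pixel and contributes its step speed
#' to the pixel's mean-speed estimate. Speed is defined only where density
#' is positive.
#'
#' @param tracks data.frame from [link_tracks()].
#' @param frame_rate_Hz frame rate (Hz), for step speeds.
#' @param grid_um output grid pitch (um); 5 um for super-resolved maps.
#' @param extent_um field extent `c(x, z)` in um.
#' @param speed_smooth_frames odd position-smoothing window passed to
#'   [track_speed()] (1 = none).
#' @return an object of class `ulm_maps`: list with integer `density`,
#'   `speed` (mm/s, NA where empty), `grid_um`, `extent_um`, `n_samples`.
#' @export
rasterize_tracks <- function(tracks, frame_rate_Hz, grid_um = 5,
                             extent_um, speed_smooth_frames = 1L) {
  stopifnot(grid_um > 0, length(extent_um) == 2)
  nx <- ceiling(extent_um[1] / grid_um)
  nz <- ceiling(extent_um[2] / grid_um)
  dens <- matrix(0L, nz, nx)
  vsum <- matrix(0, nz, nx)
  total <- 0L
  if (nrow(tracks)) {
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, ]
      tr <- tr[order(tr$frame), ]
      tsp <- track_speed(tr, frame_rate_Hz, speed_smooth_frames)
      sp <- tsp$step_speeds_mm_s
      for (k in seq_along(sp)) {
        dx <- tsp$x_um[k + 1] - tsp$x_um[k]
        dz <- tsp$z_um[k + 1] - tsp$z_um[k]
        n_sub <- max(1L, ceiling(sqrt(dx^2 + dz^2) / grid_um))
        fr <- (seq_len(n_sub) - 0.5) / n_sub
        xs <- tsp$x_um[k] + fr * dx
        zs <- tsp$z_um[k] + fr * dz
        ix <- pmin(pmax(ceiling(xs / grid_um), 1L), nx)
        iz <- pmin(pmax(ceiling(zs / grid_um), 1L), nz)
        for (q in seq_len(n_sub)) {
          dens[iz[q], ix[q]] <- dens[iz[q], ix[q]] + 1L
          vsum[iz[q], ix[q]] <- vsum[iz[q], ix[q]] + sp[k]
        }
        total <- total + n_sub
      }
    }
  }
  speed <- ifelse(dens > 0, vsum / pmax(dens, 1L), NA_real_)
  structure(list(density = dens, speed = speed, grid_um = grid_um,
                 extent_um = extent_um, n_samples = total),
            class = "ulm_maps")
}

#' @export
print.ulm_maps <- function(x, ...) {
  cat(sprintf("ULM maps: %d x %d px at %g um; %d samples, %d occupied px\n",
              nrow(x$density), ncol(x$density), x$grid_um, x$n_samples,
              sum(x$density > 0)))
  if (any(x$density > 0))
    cat(sprintf("  speed range %.2f - %.2f mm/s\n",
                min(x$speed, na.rm = TRUE), max(x$speed, na.rm = TRUE)))
  invisible(x)
}
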