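#' Generate a hierarchical vascular phantom
#'
#' Builds a ground-truth set of straight vessel segments grouped into
#' hierarchy levels (1 = capillary-like, `L` = large arteriole). Each level
#' draws segment diameters and mean flow speeds uniformly within its range;
#' ranges are non-decreasing with level by default so that level-mean speeds
#' are monotone, mirroring the speed hierarchy of arterial compartments.
#' Each segment carries an evoked fraction: the steady-state fractional CBV
#' increase it contributes under stimulation.
#'
#' @param n_per_level integer vector, segments per hierarchy level.
#' @param speed_ranges matrix `L x 2` (mm/s) or NULL for defaults spanning
#'   1.5-24 mm/s across four levels.
#' @param diameter_ranges matrix `L x 2` (um) or NULL for defaults spanning
#'   10-160 um.
#' @param evoked_fraction per-level evoked fractional CBV increase, recycled;
#'   default 0.15 for all levels.
#' @param extent_um field of view `c(x, z)` in um.
#' @param seed integer seed; the phantom is bit-reproducible given it.
#' @return an object of class `vascular_phantom`: a list with `segments`
#'   (data.frame: x0_um, z0_um, x1_um, z1_um, diameter_um, level,
#'   mean_speed_mm_s, evoked_fraction), `extent_um`, `n_levels`, `seed`.
#' @export
generate_phantom <- function(n_per_level = c(6L, 6L, 6L, 6L),
                             speed_ranges = NULL, diameter_ranges = NULL,
                             evoked_fraction = 0.15,
                             extent_um = c(2000, 2000), seed = 1L) {
  if (length(n_per_level) < 1L || sum(n_per_level) < 1L)
    stop("empty phantom specification")
  L <- length(n_per_level)
  if (is.null(speed_ranges))
    speed_ranges <- cbind(1.5 * 2^(seq_len(L) - 1), 3 * 2^(seq_len(L) - 1))
  if (is.null(diameter_ranges))
    diameter_ranges <- cbind(10 * 2^(seq_len(L) - 1), 20 * 2^(seq_len(L) - 1))
  speed_ranges <- matrix(speed_ranges, nrow = L)
  diameter_ranges <- matrix(diameter_ranges, nrow = L)
  stopifnot(all(speed_ranges > 0), all(diameter_ranges > 0),
            all(evoked_fraction >= 0))
  ev <- rep_len(evoked_fraction, L)

  segs <- with_seed(derive_seed(seed, "phantom"), {
    out <- vector("list", L)
    for (l in seq_len(L)) {
      n <- n_per_level[l]
      if (n == 0L) next
      # random chords: a random anchor plus a random direction, length scaled
      # to the field so segments stay mostly in view
      len <- stats::runif(n, 0.25, 0.6) * min(extent_um)
      ang <- stats::runif(n, 0, pi)
      x0 <- stats::runif(n, 0.05, 0.95) * extent_um[1]
      z0 <- stats::runif(n, 0.05, 0.95) * extent_um[2]
      x1 <- pmin(pmax(x0 + len * cos(ang), 0), extent_um[1])
      z1 <- pmin(pmax(z0 + len * sin(ang), 0), extent_um[2])
      out[[l]] <- data.frame(
        x0_um = x0, z0_um = z0, x1_um = x1, z1_um = z1,
        diameter_um = stats::runif(n, diameter_ranges[l, 1], diameter_ranges[l, 2]),
        level = l,
        mean_speed_mm_s = stats::runif(n, speed_ranges[l, 1], speed_ranges[l, 2]),
        evoked_fraction = ev[l])
    }
    do.call(rbind, out)
  })
  rownames(segs) <- NULL
  structure(list(segments = segs, extent_um = extent_um, n_levels = L,
                 seed = seed),
            class = "vascular_phantom")
}

#' @export
print.vascular_phantom <- function(x, ...) {
  cat(sprintf("vascular phantom: %d segments over %d levels, %g x %g um\n",
              nrow(x$segments), x$n_levels, x$extent_um[1], x$extent_um[2]))
  agg <- stats::aggregate(cbind(mean_speed_mm_s, diameter_um) ~ level,
                          data = x$segments, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

# Segment lengths in um.
segment_lengths <- function(phantom) {
  s <- phantom$segments
  sqrt((s$x1_um - s$x0_um)^2 + (s$z1_um - s$z0_um)^2)
}

# Relative volumetric flow proxy per segment: speed x cross-section.
segment_flows <- function(phantom) {
  s <- phantom$segments
  s$mean_speed_mm_s * (s$diameter_um / 2)^2
}
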