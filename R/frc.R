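#' Split localization events into two disjoint halves
#'
#' Random (default) or time-block (odd/even frame) split of a localization
#' table into two sub-sets whose sizes differ by at most one, from which two
#' sub-images are rasterized for Fourier ring correlation.
#'
#' @param locs data.frame of localization events (any columns; `frame`
#'   required for `method = "blocks"`).
#' @param seed integer seed for the random split.
#' @param method `"random"` (uniform random split) or `"blocks"` (odd/even
#'   frame parity).
#' @return list of two disjoint data.frames whose union is `locs`.
#' @export
split_events <- function(locs, seed = 1L, method = c("random", "blocks")) {
  method <- match.arg(method)
  n <- nrow(locs)
  if (is.null(n) || n < 2) stop("need at least 2 events to split")
  if (method == "random") {
    idx <- with_seed(derive_seed(seed, "frc_split"), sample.int(n))
    a <- sort(idx[seq_len(ceiling(n / 2))])
  } else {
    stopifnot(!is.null(locs$frame))
    a <- which(locs$frame %% 2 == 1)
    if (length(a) %in% c(0L, n)) a <- seq(1L, n, by = 2L)
  }
  list(locs[a, , drop = FALSE], locs[setdiff(seq_len(n), a), , drop = FALSE])
}

#' Rasterize localization events into a count map
#'
#' Simple 2D histogram of event positions on a square grid; the sub-image
#' primitive for Fourier ring correlation.
#'
#' @param locs data.frame with `x_um`, `z_um`.
#' @param grid_um grid pitch (um).
#' @param extent_um field extent `c(x, z)` (um).
#' @return integer matrix (`nz x nx`).
#' @export
count_map <- function(locs, grid_um = 5, extent_um) {
  nx <- ceiling(extent_um[1] / grid_um)
  nz <- ceiling(extent_um[2] / grid_um)
  m <- matrix(0L, nz, nx)
  if (nrow(locs)) {
    ix <- pmin(pmax(ceiling(locs$x_um / grid_um), 1L), nx)
    iz <- pmin(pmax(ceiling(locs$z_um / grid_um), 1L), nz)
    for (k in seq_along(ix)) m[iz[k], ix[k]] <- m[iz[k], ix[k]] + 1L
  }
  m
}

# Ring index (0 = DC) for every FFT bin of an nz x nx spectrum, using the
# normalized radial frequency in cycles/pixel binned at ring_width / max(n).
ring_index <- function(nz, nx, ring_width = 1) {
  qz <- c(0:floor(nz / 2), -(ceiling(nz / 2) - 1):-1)[seq_len(nz)] / nz
  qx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1)[seq_len(nx)] / nx
  r <- sqrt(outer(qz^2, qx^2, "+"))
  w <- ring_width / max(nz, nx)
  list(idx = round(r / w), bin_width = w)
}

#' Fourier ring correlation curve
#'
#' Correlates the spectra of two statistically independent sub-images along
#' iso-spatial-frequency rings:
#' `FRC(r) = Re sum(F_A conj(F_B)) / sqrt(sum|F_A|^2 sum|F_B|^2)` over the
#' FFT bins of ring `r`. Rings run from DC to the Nyquist frequency
#' `0.5 / pixel_um`; rings with zero energy in either image are marked
#' missing.
#'
#' @param img_a,img_b real matrices of identical shape.
#' @param pixel_um pixel size (um).
#' @param ring_width ring width in FFT bins.
#' @return an object of class `frc_curve`: data.frame with `freq_per_um`,
#'   `frc`, `n_bins`; attributes `pixel_um`, `ring_width`.
#' @export
frc_curve <- function(img_a, img_b, pixel_um = 5, ring_width = 1) {
  stopifnot(is.matrix(img_a), all(dim(img_a) == dim(img_b)),
            pixel_um > 0, ring_width > 0)
  fa <- stats::fft(img_a)
  fb <- stats::fft(img_b)
  ri <- ring_index(nrow(img_a), ncol(img_a), ring_width)
  keep <- ri$idx * ri$bin_width <= 0.5 + 1e-12
  idx <- ri$idx[keep]
  num <- as.vector(tapply(Re(fa[keep] * Conj(fb[keep])), idx, sum))
  ea <- as.vector(tapply(Mod(fa[keep])^2, idx, sum))
  eb <- as.vector(tapply(Mod(fb[keep])^2, idx, sum))
  nb <- as.vector(tapply(idx, idx, length))
  rings <- sort(unique(idx))
  den <- sqrt(ea * eb)
  frc <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(freq_per_um = rings * ri$bin_width / pixel_um,
                    frc = frc, n_bins = nb)
  attr(out, "pixel_um") <- pixel_um
  attr(out, "ring_width") <- ring_width
  class(out) <- c("frc_curve", "data.frame")
  out
}

# Independent direct-summation reference used by tests: explicit double loop
# over FFT bins, no tapply, no vectorized ring machinery.
frc_curve_brute <- function(img_a, img_b, pixel_um = 5, ring_width = 1) {
  nz <- nrow(img_a); nx <- ncol(img_a)
  fa <- stats::fft(img_a); fb <- stats::fft(img_b)
  w <- ring_width / max(nz, nx)
  qz <- c(0:floor(nz / 2), -(ceiling(nz / 2) - 1):-1)[seq_len(nz)] / nz
  qx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1)[seq_len(nx)] / nx
  acc <- list()
  for (i in seq_len(nz)) for (j in seq_len(nx)) {
    r <- sqrt(qz[i]^2 + qx[j]^2)
    k <- round(r / w)
    if (k * w > 0.5 + 1e-12) next
    key <- as.character(k)
    if (is.null(acc[[key]])) acc[[key]] <- c(0, 0, 0, 0)
    acc[[key]] <- acc[[key]] + c(Re(fa[i, j] * Conj(fb[i, j])),
                                 Mod(fa[i, j])^2, Mod(fb[i, j])^2, 1)
  }
  ks <- sort(as.integer(names(acc)))
  vals <- t(vapply(as.character(ks), function(k) acc[[k]], numeric(4)))
  den <- sqrt(vals[, 2] * vals[, 3])
  data.frame(freq_per_um = ks * w / pixel_um,
             frc = ifelse(den > 0, vals[, 1] / den, NA_real_),
             n_bins = vals[, 4])
}

#' Resolution limit from an FRC curve
#'
#' The resolution is the reciprocal of the first frequency at which the
#' smoothed curve drops below the criterion threshold: either the fixed 1/7
#' level or the half-bit curve (which depends on the number of bins per
#' ring). The crossing frequency is linearly interpolated between rings. If
#' the curve never crosses, the estimate is grid-limited and `2 x pixel_um`
#' is returned with a flag.
#'
#' @param curve an [frc_curve()].
#' @param criterion `"oneseventh"` or `"halfbit"`.
#' @param smooth_rings moving-average window (rings) applied before the
#'   crossing search.
#' @return list with `resolution_um`, `freq_cross_per_um`, `criterion`,
#'   `grid_limited`.
#' @export
frc_resolution <- function(curve, criterion = c("oneseventh", "halfbit"),
                           smooth_rings = 3L) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "frc_curve"), nrow(curve) > 0)
  px <- attr(curve, "pixel_um")
  v <- curve$frc
  if (smooth_rings > 1) {
    sm <- v
    h <- smooth_rings %/% 2
    for (k in seq_along(v)) {
      w <- v[max(1, k - h):min(length(v), k + h)]
      sm[k] <- mean(w, na.rm = TRUE)
    }
    v <- sm
  }
  thr <- if (criterion == "oneseventh") rep(1 / 7, nrow(curve)) else {
    s <- sqrt(pmax(curve$n_bins, 1))
    (0.2071 + 1.9102 / s) / (1.2071 + 0.9102 / s)
  }
  diffv <- v - thr
  below <- which(diffv < 0 & curve$freq_per_um > 0 & is.finite(diffv))
  if (!length(below)) {
    return(list(resolution_um = 2 * px, freq_cross_per_um = 0.5 / px,
                criterion = criterion, grid_limited = TRUE))
  }
  k <- below[1]
  if (k == 1 || !is.finite(diffv[k - 1])) {
    f_cross <- curve$freq_per_um[k]
  } else {
    f0 <- curve$freq_per_um[k - 1]; f1 <- curve$freq_per_um[k]
    d0 <- diffv[k - 1]; d1 <- diffv[k]
    f_cross <- f0 + (f1 - f0) * d0 / (d0 - d1)
  }
  list(resolution_um = 1 / f_cross, freq_cross_per_um = f_cross,
       criterion = criterion, grid_limited = FALSE)
}

#' FRC resolution of a localization data set
#'
#' Convenience pipeline: split the events in two, rasterize both halves on
#' the analysis grid, compute the FRC curve and its resolution limit.
#'
#' @param locs localization data.frame (`x_um`, `z_um`, optionally `frame`).
#' @param extent_um field extent (um).
#' @param grid_um rasterization grid (um).
#' @param seed split seed.
#' @param method split method, see [split_events()].
#' @param criterion see [frc_resolution()].
#' @param ring_width see [frc_curve()].
#' @return list with `curve`, `resolution` and the two count maps.
#' @export
frc_from_localizations <- function(locs, extent_um, grid_um = 5, seed = 1L,
                                   method = "random",
                                   criterion = "oneseventh",
                                   ring_width = 1) {
  halves <- split_events(locs, seed = seed, method = method)
  a <- count_map(halves[[1]], grid_um, extent_um)
  b <- count_map(halves[[2]], grid_um, extent_um)
  curve <- frc_curve(a, b, pixel_um = grid_um, ring_width = ring_width)
  list(curve = curve, resolution = frc_resolution(curve, criterion),
       map_a = a, map_b = b)
}

#' @export
plot.frc_curve <- function(x, criterion = "oneseventh", ...) {
  graphics::plot(x$freq_per_um, x$frc, type = "l", xlab = "frequency (1/um)",
                 ylab = "FRC", ylim = c(min(0, min(x$frc, na.rm = TRUE)), 1),
                 ...)
  graphics::abline(h = 1 / 7, lty = 2)
  invisible(x)
}
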