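#' SVD clutter filter
#'
#' Removes slowly varying tissue signal from a slow-time ensemble by
#' truncated singular value decomposition of the space x time Casorati
#' matrix: the `rank_cut` largest singular components (the coherent,
#' high-energy tissue subspace) are zeroed and the remainder reshaped back
#' into frames. `rank_cut = 0` returns the input unchanged.
#'
#' @param stack a [frame_stack()].
#' @param rank_cut number of leading singular components to remove; default
#'   10% of the ensemble length.
#' @return a filtered [frame_stack()] of identical shape.
#' @export
svd_clutter_filter <- function(stack, rank_cut = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  nt <- d[3]
  if (is.null(rank_cut)) rank_cut <- max(1L, floor(0.1 * nt))
  rank_cut <- as.integer(rank_cut)
  if (rank_cut >= nt) stop("rank_cut must be smaller than the frame count")
  if (rank_cut == 0L) return(stack)
  cas <- matrix(stack$frames, nrow = d[1] * d[2], ncol = nt)
  sv <- svd(cas, nu = rank_cut, nv = rank_cut)
  clutter <- sv$u %*% (sv$d[seq_len(rank_cut)] * Conj(t(sv$v)))
  out <- cas - clutter
  stack$frames <- array(out, dim = d)
  stack
}

#' Power Doppler image
#'
#' Per-pixel temporal mean of the squared magnitude of the (clutter
#' filtered) slow-time signal — the standard cerebral-blood-volume proxy.
#' Values are linear; use [to_db()] for display scaling.
#'
#' @param stack a [frame_stack()].
#' @return an object of class `power_doppler`: list with `image`
#'   (non-negative `nz x nx` matrix), `pixel_um`, `plane_id`.
#' @export
power_doppler <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[3] < 1L) stop("empty frame stack")
  img <- matrix(rowMeans(matrix(Mod(stack$frames)^2, nrow = d[1] * d[2])),
                d[1], d[2])
  structure(list(image = img, pixel_um = stack$pixel_um,
                 plane_id = stack$plane_id),
            class = "power_doppler")
}

#' @export
print.power_doppler <- function(x, ...) {
  cat(sprintf("power Doppler image: %d x %d px (%g um), dynamic range %.1f dB\n",
              nrow(x$image), ncol(x$image), x$pixel_um,
              -min(to_db(x$image)[x$image > 0], na.rm = TRUE)))
  invisible(x)
}

#' Decibel display scaling
#'
#' `10 log10(P / ref)` with `ref` defaulting to the image maximum, so the
#' brightest pixel maps to 0 dB. Stored images stay linear; this is a
#' render-time transform only.
#'
#' @param x `power_doppler` object or non-negative numeric array.
#' @param ref reference power; default `max(x)`.
#' @return numeric array in dB (`-Inf` where power is 0).
#' @export
to_db <- function(x, ref = NULL) {
  p <- if (inherits(x, "power_doppler")) x$image else x
  stopifnot(all(p >= 0, na.rm = TRUE))
  if (is.null(ref)) ref <- max(p, na.rm = TRUE)
  stopifnot(ref > 0)
  10 * log10(p / ref)
}

#' @export
plot.power_doppler <- function(x, db = TRUE, ...) {
  img <- if (db) pmax(to_db(x), -40) else x$image
  graphics::image(t(img)[, nrow(img):1], axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "inferno"),
                  main = if (db) "power Doppler (dB)" else "power Doppler", ...)
  invisible(x)
}
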