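#' Pearson correlation over masked pixels
#'
#' @param map_a,map_b numeric maps of identical shape.
#' @param mask logical map selecting the analysis pixels (>= 3 required).
#' @return Pearson r.
#' @export
masked_correlation <- function(map_a, map_b, mask) {
  stopifnot(all(dim(map_a) == dim(map_b)),
            all(dim(map_a) == dim(mask)))
  a <- map_a[mask]; b <- map_b[mask]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("fewer than 3 masked pixels")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate (zero-variance) map within the mask")
  stats::cor(a, b)
}

#' Fisher z transform of a correlation coefficient
#'
#' `z = atanh(r)`, the variance-stabilizing transform that makes
#' correlations approximately normal and averageable across acquisitions.
#' Values at exactly +-1 are clamped to `+-(1 - 1e-12)` with a warning.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return z value(s).
#' @export
fisher_transform <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  clamped <- abs(r) >= 1
  if (any(clamped)) {
    warning("|r| = 1 clamped before the Fisher transform")
    r[clamped] <- sign(r[clamped]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Group-level test of zero median
#'
#' Two-sided Wilcoxon signed-rank test of the hypothesis that the Fisher z
#' values have zero median. Uses the exact null distribution for n <= 25
#' without ties among the nonzero absolute differences, and the normal
#' approximation with continuity correction otherwise; zero differences are
#' dropped (mid-rank tie handling).
#'
#' @param z_values numeric vector of per-acquisition Fisher z values.
#' @return list with `statistic` (V), `p`, `n_used`, `exact`, `flag`.
#' @export
group_test <- function(z_values) {
  stopifnot(is.numeric(z_values), length(z_values) >= 1)
  nz <- z_values[z_values != 0]
  if (!length(nz))
    return(list(statistic = NA_real_, p = 1, n_used = 0L, exact = NA,
                flag = "all-zero sample"))
  exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(z_values, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_used = length(nz), exact = exact, flag = NA_character_)
}

# Nearest-neighbor block resampling: each fine-grid (ULM) pixel inherits the
# value of the coarse-grid (fUS) voxel enclosing its center.
resample_to_grid <- function(coarse, coarse_um, fine_dims, fine_um) {
  nz <- fine_dims[1]; nx <- fine_dims[2]
  zi <- pmin(pmax(ceiling(((seq_len(nz) - 0.5) * fine_um) / coarse_um), 1L),
             nrow(coarse))
  xi <- pmin(pmax(ceiling(((seq_len(nx) - 0.5) * fine_um) / coarse_um), 1L),
             ncol(coarse))
  coarse[zi, xi, drop = FALSE]
}

#' Pair a functional acquisition with its ULM speed map
#'
#' Resamples the GLM maps (dcbv, rcbv, t) from the functional voxel grid
#' onto the super-resolved ULM grid by nearest-neighbor block assignment
#' and builds the analysis mask: pixels that are Bonferroni-significant in
#' the GLM and carry at least one ULM track sample.
#'
#' @param glm_fit a [fit_voxelwise()] result with grid `dims`.
#' @param ulm an [rasterize_tracks()] result.
#' @param voxel_um functional voxel size (um).
#' @param alpha significance level for the activation mask.
#' @param mask_mode `"activated"` (default: significant AND vascularized) or
#'   `"all"` (all pixels with defined speed).
#' @return an object of class `acquisition_pair`: list of co-registered maps
#'   `dcbv`, `rcbv`, `t`, `speed` and logical `mask`, all on the ULM grid.
#' @export
acquisition_pair <- function(glm_fit, ulm, voxel_um, alpha = 0.05,
                             mask_mode = c("activated", "all")) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(inherits(glm_fit, "fus_glm"), !is.null(glm_fit$dims),
            inherits(ulm, "ulm_maps"))
  fd <- dim(ulm$density)
  res <- function(m) resample_to_grid(m, voxel_um, fd, ulm$grid_um)
  sig <- significance_mask(glm_fit$p_map, alpha = alpha,
                           n_tests = sum(!glm_fit$excluded))
  mask <- ulm$density > 0
  if (mask_mode == "activated") mask <- mask & res(sig)
  structure(list(dcbv = res(glm_fit$dcbv), rcbv = res(glm_fit$rcbv),
                 t = res(glm_fit$t_map), speed = ulm$speed, mask = mask,
                 grid_um = ulm$grid_um),
            class = "acquisition_pair")
}

#' Group-level correlation of functional response with microbubble speed
#'
#' For each acquisition, correlates the chosen functional metric with the
#' ULM speed map over the analysis mask; Fisher-transforms the
#' per-acquisition correlations and tests them for zero median with the
#' Wilcoxon signed-rank test.
#'
#' @param pairs list of [acquisition_pair()] objects.
#' @param metric `"dcbv"`, `"rcbv"` or `"t"`.
#' @return an object of class `group_result`: list with `r` (per
#'   acquisition), `z`, `mean_z`, `mean_r` (back-transformed), `statistic`,
#'   `p`, `n`, `metric`.
#' @export
group_speed_correlation <- function(pairs, metric = c("dcbv", "rcbv", "t")) {
  metric <- match.arg(metric)
  stopifnot(length(pairs) >= 1)
  r <- vapply(pairs, function(p) {
    stopifnot(inherits(p, "acquisition_pair"))
    masked_correlation(p[[metric]], p$speed, p$mask)
  }, numeric(1))
  z <- fisher_transform(r)
  wt <- group_test(z)
  structure(list(r = r, z = z, mean_z = mean(z), mean_r = tanh(mean(z)),
                 statistic = wt$statistic, p = wt$p, n = length(r),
                 exact = wt$exact, metric = metric),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("group %s-speed correlation (n = %d acquisitions)\n",
              x$metric, x$n))
  cat(sprintf("  mean Fisher z = %.4f (r = %.4f)\n", x$mean_z, x$mean_r))
  cat(sprintf("  Wilcoxon signed-rank V = %g, two-sided p = %.4g%s\n",
              x$statistic, x$p,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}
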