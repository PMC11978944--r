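#' Hemodynamic response model
#'
#' Gamma-variate impulse response of cerebral blood volume to a stimulus,
#' `h(t) proportional to (t/tau)^alpha exp(-t/tau)`, which peaks at
#' `t = alpha * tau` (1.5 s at the defaults alpha = 3, tau = 0.5 s, typical
#' of mouse cortical fUS responses). The discretized kernel is normalized to
#' unit sum so convolution preserves the plateau of long stimulus blocks.
#'
#' @param alpha shape parameter (> 0).
#' @param tau_s timescale (s, > 0).
#' @param duration_s kernel support (s).
#' @return an object of class `hemodynamic_model`.
#' @export
hemodynamic_model <- function(alpha = 3, tau_s = 0.5, duration_s = 8) {
  stopifnot(alpha > 0, tau_s > 0, duration_s > 0)
  structure(list(alpha = alpha, tau_s = tau_s, duration_s = duration_s),
            class = "hemodynamic_model")
}

#' Discretized hemodynamic response kernel
#'
#' Samples the gamma-variate response on the acquisition time grid and
#' normalizes it to unit sum.
#'
#' @param model a [hemodynamic_model()].
#' @param dt sampling interval (s, > 0).
#' @return numeric kernel summing to 1.
#' @export
hrf_kernel <- function(model, dt) {
  stopifnot(inherits(model, "hemodynamic_model"), dt > 0)
  if (model$duration_s < model$tau_s)
    stop("kernel duration shorter than the response timescale tau")
  t <- seq(0, model$duration_s, by = dt)
  h <- (t / model$tau_s)^model$alpha * exp(-t / model$tau_s)
  if (sum(h) == 0) {
    # grid too coarse to hit the response: fall back to nearest-sample impulse
    h[which.min(abs(t - model$alpha * model$tau_s))] <- 1
  }
  h / sum(h)
}

# Stimulus box-car convolved with the HRF, rescaled to unit plateau.
convolved_regressor <- function(protocol, hrf, n_samples, dt) {
  times <- (seq_len(n_samples) - 1) * dt
  s <- stimulus_signal(protocol, times)
  h <- hrf_kernel(hrf, dt)
  # causal discrete convolution x[k] = sum_j h[j] s[k - j + 1]
  x <- numeric(n_samples)
  for (j in seq_along(h)) {
    idx <- j:n_samples
    x[idx] <- x[idx] + h[j] * s[idx - j + 1]
  }
  if (max(x) > 0) x <- x / max(x)
  x
}

#' Build a GLM design matrix for a stimulus protocol
#'
#' Columns: (1) the stimulus box-car convolved with the hemodynamic response
#' and rescaled to unit plateau, (2) a centered linear drift ramp, (3) an
#' intercept. Samples sit at `t = k dt`, `k = 0 .. n-1`, on the stimulus
#' clock; by default `n = floor(duration / dt) + 1` (138 rows for the 330 s
#' protocol sampled every 2.4 s).
#'
#' @param protocol a [stimulus_protocol()].
#' @param hrf a [hemodynamic_model()].
#' @param dt sampling interval (s).
#' @param n_samples number of rows; default covers the protocol duration.
#' @return matrix with columns `stimulus`, `drift`, `intercept` and
#'   attributes `dt` and `times`.
#' @export
build_design <- function(protocol, hrf = hemodynamic_model(), dt = 2.4,
                         n_samples = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"), dt > 0)
  if (is.null(n_samples))
    n_samples <- floor(protocol_duration(protocol) / dt) + 1L
  stopifnot(n_samples >= 4)
  x <- convolved_regressor(protocol, hrf, n_samples, dt)
  ramp <- seq_len(n_samples) - (n_samples + 1) / 2
  X <- cbind(stimulus = x, drift = ramp, intercept = 1)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design: no stimulus variation in the sampled window")
  attr(X, "dt") <- dt
  attr(X, "times") <- (seq_len(n_samples) - 1) * dt
  X
}

#' Voxel-wise GLM activation analysis
#'
#' Fits ordinary least squares per voxel against the design matrix and
#' derives activation statistics and hemodynamic quantification maps:
#' the stimulus-regressor effect `beta1` with its t statistic, two-sided p
#' (Student t, `df = n - 3`) and signed z score; a baseline map (temporal
#' mean of the series, or the pre-stimulus mean); a stimulation map
#' (baseline + beta1, the fitted plateau level); the absolute evoked change
#' `dcbv = beta1`; the relative change `rcbv = beta1 / baseline`; and the
#' raw `cbv_ratio = stimulation / baseline`. Zero-variance voxels are
#' flagged and excluded from the maps.
#'
#' @param series a `voxel_time_series` or an `n x V` numeric matrix.
#' @param design a [build_design()] matrix with the same number of rows.
#' @param baseline `"mean"` (whole-series temporal mean, the default) or
#'   `"prestim"` (mean of samples before the first ON block).
#' @param z_cap cap on |z| for numerically zero p-values.
#' @return an object of class `fus_glm` with per-voxel vectors (`beta`,
#'   `t`, `z`, `p`), maps (`baseline`, `stimulation`, `dcbv`, `rcbv`,
#'   `cbv_ratio`), the `excluded` flag vector, grid `dims` (if known), and
#'   fit metadata.
#' @export
fit_voxelwise <- function(series, design, baseline = c("mean", "prestim"),
                          z_cap = 8) {
  baseline <- match.arg(baseline)
  dims <- NULL
  protocol <- NULL
  if (inherits(series, "voxel_time_series")) {
    dims <- series$dims
    protocol <- series$protocol
    Y <- series$series
  } else {
    Y <- as.matrix(series)
  }
  stopifnot(nrow(Y) == nrow(design), ncol(design) == 3L)
  n <- nrow(Y); V <- ncol(Y); df <- n - 3L
  stopifnot(df > 0)

  excluded <- apply(Y, 2, stats::var) <= 0
  fit <- stats::lm.fit(design, Y)
  beta <- t(fit$coefficients)                      # V x 3
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(design)))
  se1 <- sqrt(sigma2 * XtXinv[1, 1])
  tstat <- beta[, 1] / se1
  tstat[se1 == 0] <- sign(beta[se1 == 0, 1]) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  z <- sign(tstat) * pmin(stats::qnorm(p / 2, lower.tail = FALSE), z_cap)
  z[tstat == 0] <- 0

  b0 <- if (baseline == "mean") {
    colMeans(Y)
  } else {
    if (!is.null(protocol) && protocol$baseline_s > 0) {
      pre <- attr(design, "times") < protocol$baseline_s
    } else {
      pre <- design[, "stimulus"] <= 0
    }
    if (!any(pre)) stop("no pre-stimulus samples for baseline = 'prestim'")
    colMeans(Y[pre, , drop = FALSE])
  }
  mask_na <- function(v) { v[excluded] <- NA_real_; v }
  as_map <- function(v) if (is.null(dims)) v else matrix(v, dims[1], dims[2])

  out <- list(
    beta = beta, t = mask_na(tstat), z = mask_na(z), p = mask_na(p),
    baseline = as_map(mask_na(b0)),
    stimulation = as_map(mask_na(b0 + beta[, 1])),
    dcbv = as_map(mask_na(beta[, 1])),
    rcbv = as_map(mask_na(beta[, 1] / b0)),
    cbv_ratio = as_map(mask_na((b0 + beta[, 1]) / b0)),
    z_map = as_map(mask_na(z)), p_map = as_map(mask_na(p)),
    t_map = as_map(mask_na(tstat)),
    excluded = excluded, df = df, n = n, n_voxels = V, dims = dims,
    baseline_mode = baseline, z_cap = z_cap)
  class(out) <- "fus_glm"
  out
}

#' @export
print.fus_glm <- function(x, ...) {
  cat(sprintf("voxel-wise GLM fit: %d voxels, %d samples (df = %d)\n",
              x$n_voxels, x$n, x$df))
  sig <- significance_mask(x$p, n_tests = sum(!x$excluded))
  cat(sprintf("  Bonferroni-significant voxels (alpha 0.05): %d\n",
              sum(sig, na.rm = TRUE)))
  cat(sprintf("  baseline mode: %s; max |z| cap: %g\n", x$baseline_mode,
              x$z_cap))
  invisible(x)
}

#' @export
summary.fus_glm <- function(object, alpha = 0.05, ...) {
  sig <- significance_mask(object$p, alpha = alpha,
                           n_tests = sum(!object$excluded))
  rc <- object$rcbv[sig & !is.na(object$rcbv)]
  out <- list(n_voxels = object$n_voxels, n_excluded = sum(object$excluded),
              n_significant = sum(sig, na.rm = TRUE), alpha = alpha,
              median_rcbv_significant = if (length(rc)) stats::median(rc) else NA_real_,
              max_z = max(abs(object$z), na.rm = TRUE))
  class(out) <- "summary.fus_glm"
  out
}

#' @export
print.summary.fus_glm <- function(x, ...) {
  cat(sprintf("GLM summary: %d voxels (%d excluded), %d significant at Bonferroni alpha %.3g\n",
              x$n_voxels, x$n_excluded, x$n_significant, x$alpha))
  if (is.finite(x$median_rcbv_significant))
    cat(sprintf("  median rCBV over significant voxels: %.3f (%.1f%%)\n",
                x$median_rcbv_significant, 100 * x$median_rcbv_significant))
  cat(sprintf("  max |z|: %.2f\n", x$max_z))
  invisible(x)
}

#' @export
coef.fus_glm <- function(object, ...) object$beta

#' Bonferroni significance mask
#'
#' Marks voxels with `p < alpha / n_tests`, the Bonferroni-corrected
#' threshold for `n_tests` simultaneous comparisons.
#'
#' @param p_map numeric vector or matrix of p-values (NA allowed).
#' @param alpha family-wise error level.
#' @param n_tests number of tests; default = number of finite p-values.
#' @return logical map of the same shape (FALSE where p is NA).
#' @export
significance_mask <- function(p_map, alpha = 0.05, n_tests = NULL) {
  if (is.null(n_tests)) n_tests <- sum(is.finite(p_map))
  stopifnot(n_tests >= 1, alpha > 0)
  m <- p_map < alpha / n_tests
  m[!is.finite(p_map)] <- FALSE
  m
}
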