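#' Ground-truth effective connectivity from weights
#'
#' Closed-form causal effect of one presynaptic spike on the
#' postsynaptic spike probability, calibrated for refractoriness:
#' \eqn{\beta_{ij} = \alpha\,(\sigma(W_{ij} - b) - \sigma(-b))}.
#' The slope \eqn{\alpha} (default 0.9477) absorbs the window
#' arithmetic and refractory losses of the trial-based estimators and
#' can be re-derived with [calibrate_alpha()].
#'
#' @param weights weight matrix (or numeric vector of weights).
#' @param bias bias `b` (default 5).
#' @param alpha_cal calibration slope (default 0.9477).
#' @return Ground-truth `beta` with the same shape as `weights`.
#' @export
ground_truth_beta <- function(weights, bias = 5, alpha_cal = 0.9477) {
  alpha_cal * (plogis(unclass(weights) - bias) - plogis(-bias))
}

#' Calibrate the ground-truth slope on two-neuron simulations
#'
#' For each weight in `weight_grid`, simulates a two-neuron network
#' (presynaptic neuron 2 driving postsynaptic neuron 1) for `n_steps`
#' 1-ms bins, twice: once with the full refractory kernel and once
#' with refractoriness disabled (\eqn{r = 0}).  The presynaptic neuron
#' is stimulated on a regular onset grid with a strong pulse
#' (`gamma_s`, default 8, hit rate near 100% outside refractoriness)
#' and the OLS conditional-difference estimate is computed per weight
#' from the standard trial windows.  The returned slope is the
#' least-squares fit through the origin of the refractory-block
#' estimates against the closed form \eqn{\sigma(W-b) - \sigma(-b)};
#' the \eqn{r = 0} block is the sanity side-condition, whose slope
#' should be close to 1.
#'
#' With the package defaults this yields a slope of about 0.95; the
#' constant is weakly sensitive (few percent) to the stimulus
#' amplitude through the within-window timing of treated spikes.  See
#' the methods vignette.
#'
#' @param weight_grid numeric weights (at least 3 distinct values).
#' @param spec a [network_spec()] for 2 neurons.
#' @param n_steps steps per simulation (default 1e6).
#' @param onset_period regular trial spacing (ms, default 50).
#' @param gamma_s stimulus amplitude on the presynaptic neuron
#'   (default 8).
#' @param windows a [window_spec()].
#' @param seed optional integer seed.
#' @return An `alpha_calibration`: list with `alpha` (refractory-block
#'   slope), `alpha_r0` (side condition), and `estimates`, a tibble
#'   with per-weight columns `weight`, `beta_closed`, `ols_refractory`,
#'   `ols_r0`.
#' @export
calibrate_alpha <- function(weight_grid,
                            spec = network_spec(2),
                            n_steps = 1e6,
                            onset_period = 50,
                            gamma_s = 8,
                            windows = window_spec(),
                            seed = NULL) {
  if (length(unique(weight_grid)) < 3) {
    abort("`weight_grid` must span at least 3 distinct values.",
          class = "refractiv_config_error")
  }
  if (all(weight_grid == 0)) {
    abort("`weight_grid` must contain nonzero weights.",
          class = "refractiv_config_error")
  }
  spec_r0 <- spec
  spec_r0$refractory_abs <- 0
  spec_r0$refractory_rel <- 0
  onsets <- seq(onset_period, n_steps - onset_period, by = onset_period)
  proto <- drive_protocol(stimulated = 2L, gamma_s = gamma_s,
                          lambda_s = onset_period,
                          lambda_s_min = onset_period,
                          lambda_s_max = onset_period)
  seeds <- derive_seeds(seed, 2L * length(weight_grid))
  one_block <- function(w, s, sp) {
    wm <- matrix(c(0, 0, w, 0), 2, 2)  # wm[1,2] = w: neuron 2 -> neuron 1
    dr <- drive_trace(proto, 2L, n_steps, onsets = list(s = onsets,
                                                        ex = integer(0),
                                                        `in` = integer(0)))
    r <- simulate_network(sp, wm, dr, n_steps = n_steps, seed = s)
    tt <- extract_trials(r, onsets, upstream = 2L, downstream = 1L, windows)
    ols_estimate(tt)
  }
  est <- purrr::imap_dfr(weight_grid, function(w, i) {
    tibble(
      weight = w,
      beta_closed = plogis(w - spec$bias) - plogis(-spec$bias),
      ols_refractory = one_block(w, seeds[[2 * i - 1]], spec),
      ols_r0 = one_block(w, seeds[[2 * i]], spec_r0)
    )
  })
  slope0 <- function(x, y) sum(x * y, na.rm = TRUE) / sum(x^2, na.rm = TRUE)
  structure(
    list(alpha = slope0(est$beta_closed, est$ols_refractory),
         alpha_r0 = slope0(est$beta_closed, est$ols_r0),
         estimates = est, n_steps = n_steps),
    class = "alpha_calibration"
  )
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat("<alpha_calibration> slope alpha =", format(x$alpha, digits = 4),
      "( r = 0 side condition:", format(x$alpha_r0, digits = 4), ")\n")
  invisible(x)
}

#' @export
tidy.alpha_calibration <- function(x, ...) x$estimates

#' @export
glance.alpha_calibration <- function(x, ...) {
  tibble(alpha = x$alpha, alpha_r0 = x$alpha_r0,
         n_weights = nrow(x$estimates), n_steps = x$n_steps)
}

#' @export
autoplot.alpha_calibration <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(.data$beta_closed, .data$ols_refractory)) +
    ggplot2::geom_abline(slope = object$alpha, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(sigma(W - b) - sigma(-b)),
                  y = "OLS estimate") +
    ggplot2::theme_minimal()
}

#' Per-pair errors against ground truth
#'
#' Signed errors `estimate - beta` per pair, with missing estimates
#' excluded (and counted) from the aggregates.
#'
#' @param estimates numeric vector of estimates.
#' @param truth numeric vector of ground-truth `beta`, same length.
#' @param weights optional true weights for the sign split.
#' @return A tibble with columns `estimate`, `beta`, `error`, and
#'   optionally `weight`.
#' @seealso [summarize_errors()]
#' @export
pair_errors <- function(estimates, truth, weights = NULL) {
  stopifnot(length(estimates) == length(truth))
  out <- tibble(estimate = as.numeric(estimates), beta = as.numeric(truth),
                error = estimate - beta)
  if (!is.null(weights)) out$weight <- as.numeric(weights)
  out
}

#' Mean absolute error, split by connection sign
#'
#' @param errors tibble from [pair_errors()].
#' @return One-row tibble: `mae`, `mae_pos_w`, `mae_neg_w` (splits by
#'   `weight >= 0` / `weight <= 0` when weights are present),
#'   `n_excluded` (missing estimates).
#' @export
summarize_errors <- function(errors) {
  has_w <- "weight" %in% names(errors)
  ok <- !is.na(errors$error)
  tibble(
    mae = mean(abs(errors$error[ok])),
    mae_pos_w = if (has_w) mean(abs(errors$error[ok & errors$weight >= 0]))
                else NA_real_,
    mae_neg_w = if (has_w) mean(abs(errors$error[ok & errors$weight <= 0]))
                else NA_real_,
    n_excluded = sum(!ok)
  )
}

#' Condition number of the population spike covariance
#'
#' Ratio of extreme singular values of the neuron-by-neuron covariance
#' of the binary spike matrix, treating time bins as samples.  Large
#' values signal multicollinearity of population states -- shared,
#' confounding drive -- which destabilizes pairwise inference.
#'
#' @param raster a `spike_raster` (at least 2 neurons).
#' @return Numeric condition number with attribute `degenerate`
#'   (`TRUE` when the covariance is rank-deficient to machine
#'   precision, in which case `Inf` is returned).
#' @export
condition_number <- function(raster) {
  if (raster$n_neurons < 2) {
    abort("need at least 2 neurons.", class = "refractiv_config_error")
  }
  m <- as.matrix(raster, sparse = TRUE)
  tt <- raster$n_steps
  mu <- Matrix::rowMeans(m)
  cv <- as.matrix(Matrix::tcrossprod(m)) / tt - outer(mu, mu)
  sv <- svd(cv, nu = 0, nv = 0)$d
  eps <- .Machine$double.eps * max(sv, 1)
  degenerate <- min(sv) <= eps
  kappa <- if (degenerate) Inf else max(sv) / min(sv)
  structure(kappa, degenerate = degenerate)
}

#' Area under the ROC curve for connection classification
#'
#' Probability that a randomly chosen true connection outranks a
#' randomly chosen non-connection under the scores, with ties counted
#' half (the Mann-Whitney identity).  Scores are the signed estimates
#' for excitatory screens; negate them for inhibitory screens or take
#' absolute values for mixed screens.  Missing scores are excluded.
#'
#' @param scores numeric estimator scores.
#' @param labels logical (or 0/1): `TRUE` for a true connection.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
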