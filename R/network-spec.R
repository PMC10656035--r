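#' Specify a binomial-GLM spiking network
#'
#' Collects the parameters of the discrete-time binomial-GLM network
#' model: each neuron spikes in a 1-ms bin with probability
#' \eqn{\sigma(x)} where the drive \eqn{x} sums a refractory kernel over
#' the neuron's own spike history, a coupling kernel over presynaptic
#' spike histories weighted by the connectivity matrix, a constant bias
#' \eqn{-b}, and external input.
#'
#' The refractory kernel is a large negative constant (default -100) on
#' the first `refractory_abs_span` lags -- an absolute refractory period
#' that no bounded input can overcome -- followed by a decaying relative
#' term \eqn{-30\,e^{-(l+4)/2}}.
#'
#' The coupling kernel is supported on `coupling_support` consecutive
#' lags starting at lag `coupling_delay` (default 2: one bin of
#' synaptic transmission delay beyond the intrinsic one-step update,
#' so a spike at bin \eqn{t} first raises the partner's intensity at
#' bin \eqn{t + 2}) and decays exponentially at rate `coupling_alpha`.
#' With `coupling_first_tap_one = TRUE` (default) the first active lag
#' carries the full weight \eqn{W_{ij}} and the decay starts
#' thereafter, which makes the closed-form single-spike effect
#' \eqn{\sigma(W-b)-\sigma(-b)} attainable and is required for the
#' \eqn{r = 0} calibration side-condition to recover slope 1; with
#' `FALSE` the first tap is \eqn{e^{-\alpha}}.  Setting
#' `coupling_delay = 1` and `coupling_first_tap_one = FALSE` gives the
#' plain kernel \eqn{c(l) = e^{-\alpha l}} on lags 1..5.  The default
#' two-bin delay aligns the first postsynaptic response to a
#' during-stimulus spike with the post-stimulus detection window; see
#' the methods vignette for the full argument.
#'
#' @param n_neurons number of neurons.
#' @param bias baseline bias \eqn{b}; spike probability at rest is
#'   \eqn{\sigma(-b)} per ms (default 5, about 6.6 Hz before
#'   refractoriness).
#' @param history history length \eqn{H} in time steps (default 10).
#' @param coupling_alpha decay rate of the coupling kernel (default 0.2).
#' @param coupling_support number of lags with nonzero coupling
#'   (default 5).
#' @param coupling_delay first lag (ms) at which a presynaptic spike
#'   acts (default 2).
#' @param coupling_first_tap_one logical; see Details.
#' @param refractory_abs value of the absolute refractory term
#'   (default -100).
#' @param refractory_abs_span number of absolutely refractory lags
#'   (default 3).
#' @param refractory_rel scale of the relative refractory term
#'   (default -30).
#' @param refractory_rel_rate decay rate of the relative refractory term
#'   (default 0.5).
#'
#' @return An object of class `network_spec`.
#' @examples
#' spec <- network_spec(3)
#' coupling_filter(1:10, spec)
#' refractory_filter(1:10, spec)
#' @export
network_spec <- function(n_neurons,
                         bias = 5,
                         history = 10L,
                         coupling_alpha = 0.2,
                         coupling_support = 5L,
                         coupling_delay = 2L,
                         coupling_first_tap_one = TRUE,
                         refractory_abs = -100,
                         refractory_abs_span = 3L,
                         refractory_rel = -30,
                         refractory_rel_rate = 0.5) {
  n_neurons <- as.integer(n_neurons)
  history <- as.integer(history)
  coupling_support <- as.integer(coupling_support)
  if (is.na(n_neurons) || n_neurons < 1L) {
    abort("`n_neurons` must be a positive integer.", class = "refractiv_config_error")
  }
  if (history < 1L) {
    abort("`history` must be a positive integer.", class = "refractiv_config_error")
  }
  if (coupling_support + as.integer(coupling_delay) - 1L > history) {
    abort("`history` must cover `coupling_support + coupling_delay - 1`.",
          class = "refractiv_config_error")
  }
  structure(
    list(
      n_neurons = n_neurons,
      bias = bias,
      history = history,
      dt = 1,
      coupling_alpha = coupling_alpha,
      coupling_support = coupling_support,
      coupling_delay = as.integer(coupling_delay),
      coupling_first_tap_one = isTRUE(coupling_first_tap_one),
      refractory_abs = refractory_abs,
      refractory_abs_span = as.integer(refractory_abs_span),
      refractory_rel = refractory_rel,
      refractory_rel_rate = refractory_rel_rate
    ),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$n_neurons, "neurons, b =", x$bias,
      ", H =", x$history, "\n")
  cat("  coupling: exp decay alpha =", x$coupling_alpha,
      "on lags", x$coupling_delay, "..",
      x$coupling_delay + x$coupling_support - 1L,
      if (x$coupling_first_tap_one) "(first tap 1)" else "(first tap exp(-alpha))",
      "\n")
  cat("  refractory:", x$refractory_abs, "on lags 1..", x$refractory_abs_span,
      "then", x$refractory_rel, "* exp(-", x$refractory_rel_rate, "(l+4))\n")
  invisible(x)
}

#' Coupling filter
#'
#' Exponentially decaying synaptic coupling kernel, nonzero on
#' `coupling_support` lags starting at `coupling_delay`, zero
#' elsewhere up to the history length.  The lag is the number of bins
#' elapsed since the presynaptic spike.  See [network_spec()] for the
#' indexing conventions.
#'
#' @param lag integer lag(s) in time steps, within `[1, history]`.
#' @param spec a [network_spec()].
#' @return Numeric kernel value(s).
#' @export
coupling_filter <- function(lag, spec) {
  check_lag(lag, spec$history)
  delay <- spec$coupling_delay %||% 2L
  shift <- if (spec$coupling_first_tap_one) delay else delay - 1L
  out <- exp(-spec$coupling_alpha * (lag - shift))
  out[lag < delay | lag > spec$coupling_support + delay - 1L] <- 0
  out
}

#' Refractory filter
#'
#' Post-spike self-history kernel: a large negative constant on the
#' absolutely refractory lags followed by a decaying relative term.
#' With defaults, -100 for lags 1..3 and \eqn{-30 e^{-(l+4)/2}} for
#' lags 4..H.
#'
#' @inheritParams coupling_filter
#' @return Numeric kernel value(s).
#' @export
refractory_filter <- function(lag, spec) {
  check_lag(lag, spec$history)
  out <- spec$refractory_rel * exp(-spec$refractory_rel_rate * (lag + 4))
  out[lag <= spec$refractory_abs_span] <- spec$refractory_abs
  out
}

check_lag <- function(lag, history) {
  if (any(lag != round(lag)) || any(lag < 1) || any(lag > history)) {
    abort(sprintf("`lag` must be an integer in [1, %d].", history),
          class = "refractiv_domain_error")
  }
  invisible(lag)
}

# kernels as dense vectors over lags 1..H, as consumed by the simulator
coupling_kernel <- function(spec) coupling_filter(seq_len(spec$history), spec)
refractory_kernel <- function(spec) refractory_filter(seq_len(spec$history), spec)
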