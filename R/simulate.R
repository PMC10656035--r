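#' Simulate a binomial-GLM spiking network
#'
#' Runs the discrete-time network model: at each 1-ms bin every neuron
#' spikes Bernoulli with probability \eqn{\sigma(x_i(t))}, where
#' \eqn{x_i(t)} sums the refractory kernel over the neuron's own recent
#' spikes, the coupling kernel over presynaptic spikes weighted by
#' `weights`, the negative bias, and the external drive.  History
#' before the first bin is silent; an optional burn-in is simulated and
#' discarded.
#'
#' @param spec a [network_spec()].
#' @param weights `n x n` weight matrix (`weights[i, j]` from neuron `j`
#'   onto neuron `i`); `NULL` for an unconnected population.
#' @param drive a [drive_trace()] covering `n_steps + burn_in` steps,
#'   or `NULL` for no external input.
#' @param n_steps number of 1-ms steps to keep.
#' @param seed optional integer seed; identical seeds give identical
#'   rasters.
#' @param burn_in steps simulated before time zero and discarded
#'   (default 0; the drive trace, if any, must cover them).
#' @return A `spike_raster`: spike times per neuron at 1-ms resolution.
#' @examples
#' spec <- network_spec(1)
#' r <- simulate_network(spec, n_steps = 10000, seed = 1)
#' firing_rates(r)
#' @export
simulate_network <- function(spec, weights = NULL, drive = NULL, n_steps,
                             seed = NULL, burn_in = 0L) {
  n <- spec$n_neurons
  n_steps <- as.integer(n_steps)
  burn_in <- as.integer(burn_in)
  total <- n_steps + burn_in
  if (is.null(weights)) weights <- matrix(0, n, n)
  if (!is.matrix(weights) || nrow(weights) != n || ncol(weights) != n) {
    abort("`weights` must be an n_neurons x n_neurons matrix.",
          class = "refractiv_config_error")
  }
  if (any(!is.finite(weights))) {
    abort("`weights` must be finite.", class = "refractiv_config_error")
  }
  if (is.null(drive)) {
    common <- numeric(0); stim <- numeric(0); gains <- numeric(n)
  } else {
    if (drive$horizon < total) {
      abort("`drive` does not cover `n_steps` + `burn_in`.",
            class = "refractiv_config_error")
    }
    common <- drive$common; stim <- drive$stim; gains <- drive$gains
    if (length(gains) != n) {
      abort("drive gains length must equal `n_neurons`.",
            class = "refractiv_config_error")
    }
  }
  times <- with_seed_if(seed, {
    simulate_glm_cpp(n, total, unclass(weights),
                     coupling_kernel(spec), refractory_kernel(spec),
                     common, stim, gains, spec$bias)
  })
  if (burn_in > 0L) {
    times <- lapply(times, function(tt) tt[tt > burn_in] - burn_in)
  }
  new_spike_raster(times, n, n_steps)
}

new_spike_raster <- function(times, n_neurons, n_steps) {
  structure(
    list(times = lapply(times, as.integer), n_neurons = n_neurons,
         n_steps = as.integer(n_steps)),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("<spike_raster>", x$n_neurons, "neurons x", x$n_steps, "ms,",
      sum(lengths(x$times)), "spikes (",
      format(mean(firing_rates(x)), digits = 3), "Hz mean )\n")
  invisible(x)
}

#' Per-neuron firing rates of a raster
#'
#' @param raster a `spike_raster`.
#' @return Numeric vector of rates in Hz.
#' @export
firing_rates <- function(raster) {
  lengths(raster$times) / raster$n_steps * 1000
}

#' Spike times of one neuron
#'
#' @param raster a `spike_raster`.
#' @param neuron neuron id.
#' @return Integer vector of spike times (ms, 1-based bins).
#' @export
spike_times <- function(raster, neuron) {
  raster$times[[neuron]]
}

#' @describeIn simulate_network long-format spikes as a tibble with
#'   columns `neuron_id` and `time_ms`.
#' @param x a `spike_raster`.
#' @param ... unused.
#' @export
tidy.spike_raster <- function(x, ...) {
  tibble(
    neuron_id = rep.int(seq_len(x$n_neurons), lengths(x$times)),
    time_ms = unlist(x$times, use.names = FALSE) %||% integer(0)
  )
}

#' Dense binary spike matrix of a raster
#'
#' @param x a `spike_raster`.
#' @param sparse return a `Matrix::sparseMatrix` instead of a dense
#'   base matrix.
#' @param ... unused.
#' @return `n_neurons x n_steps` binary matrix.
#' @export
as.matrix.spike_raster <- function(x, sparse = FALSE, ...) {
  ev <- tidy(x)
  m <- Matrix::sparseMatrix(i = ev$neuron_id, j = ev$time_ms, x = 1,
                            dims = c(x$n_neurons, x$n_steps))
  if (sparse) m else as.matrix(m)
}

#' Read or write spike events as plain-text CSV
#'
#' One row per spike with header `time_ms,neuron_id`.
#'
#' @param raster a `spike_raster`.
#' @param path file path.
#' @param n_neurons,n_steps raster dimensions when reading (inferred
#'   from the data if omitted).
#' @return `write_spike_events()` returns `path` invisibly;
#'   `read_spike_events()` returns a `spike_raster`.
#' @export
write_spike_events <- function(raster, path) {
  ev <- tidy(raster)[, c("time_ms", "neuron_id")]
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path, n_neurons = NULL, n_steps = NULL) {
  ev <- utils::read.csv(path)
  n_neurons <- n_neurons %||% max(ev$neuron_id, 1L)
  n_steps <- n_steps %||% max(ev$time_ms, 1L)
  times <- lapply(seq_len(n_neurons), function(i)
    sort(ev$time_ms[ev$neuron_id == i]))
  new_spike_raster(times, n_neurons, n_steps)
}

#' Raster plot of simulated spikes
#'
#' @param object a `spike_raster`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.spike_raster <- function(object, ...) {
  ev <- tidy(object)
  ggplot2::ggplot(ev, ggplot2::aes(.data$time_ms, .data$neuron_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}
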