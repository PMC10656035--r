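#' Sample stimulus onset times from a clipped Poisson process
#'
#' Inter-onset intervals are drawn Poisson with the given mean period
#' and then clipped: intervals below `min_period` are replaced by
#' `min_period` and intervals above `max_period` by `max_period`.
#' Onsets are the cumulative sums, truncated at `horizon`.
#'
#' @param mean_period mean inter-onset interval (ms).
#' @param min_period,max_period clipping bounds (ms).
#' @param horizon simulation length (ms); onsets beyond it are dropped.
#' @param seed optional integer seed.
#' @return Integer vector of strictly increasing onset times (ms).
#' @examples
#' sample_onsets(50, 10, 200, 1000, seed = 1)
#' @export
sample_onsets <- function(mean_period, min_period, max_period, horizon,
                          seed = NULL) {
  if (!(min_period <= mean_period && mean_period <= max_period)) {
    abort("need `min_period` <= `mean_period` <= `max_period`.",
          class = "refractiv_config_error")
  }
  if (horizon <= 0) return(integer(0))
  with_seed_if(seed, {
    onsets <- integer(0)
    last <- 0
    # draw in batches until the horizon is passed
    repeat {
      n_draw <- max(16L, ceiling((horizon - last) / max(mean_period, 1) * 1.5))
      iv <- rpois(n_draw, mean_period)
      iv <- pmin(pmax(iv, min_period), max_period)
      cum <- last + cumsum(iv)
      onsets <- c(onsets, cum)
      last <- cum[length(cum)]
      if (last > horizon) break
    }
    as.integer(onsets[onsets <= horizon])
  })
}

#' Describe the external drive of a simulation
#'
#' The external input sums three pulse trains: an optogenetic stimulus
#' applied to a subset of neurons (amplitude `gamma_s`, 2-ms pulses),
#' and excitatory and inhibitory confounders applied to every neuron
#' (amplitudes `gamma_ex >= 0 >= gamma_in`, 10-ms pulses).  Onsets of
#' each train follow a clipped Poisson schedule (see [sample_onsets()]).
#'
#' @param stimulated integer ids of stimulated neurons.
#' @param gamma_s stimulus amplitude.
#' @param stim_duration stimulus pulse length in ms (default 2,
#'   matching the 2-ms spike-detection window; 3 treats the printed
#'   closed onset interval as three bins).
#' @param lambda_s,lambda_s_min,lambda_s_max stimulus mean/min/max
#'   period (ms).
#' @param gamma_ex,tau_ex,lambda_ex,lambda_ex_min,lambda_ex_max
#'   excitatory confounder amplitude, pulse length and periods.
#' @param gamma_in,tau_in,lambda_in,lambda_in_min,lambda_in_max
#'   inhibitory confounder amplitude, pulse length and periods.
#' @param gains optional per-neuron stimulus gain in `[0, 1]`
#'   (from [assign_stimulus_gains()]); default uniform gain 1 on
#'   stimulated neurons.
#' @return A `drive_protocol` object.
#' @export
drive_protocol <- function(stimulated = integer(0),
                           gamma_s = 0, stim_duration = 2L,
                           lambda_s = 50, lambda_s_min = 10, lambda_s_max = 200,
                           gamma_ex = 0, tau_ex = 10,
                           lambda_ex = 100, lambda_ex_min = 30, lambda_ex_max = 400,
                           gamma_in = 0, tau_in = 10,
                           lambda_in = 100, lambda_in_min = 30, lambda_in_max = 400,
                           gains = NULL) {
  if (gamma_ex < 0 || gamma_in > 0) {
    abort("confounder sign convention: `gamma_ex` >= 0 >= `gamma_in`.",
          class = "refractiv_config_error")
  }
  if (stim_duration < 1 || tau_ex < 1 || tau_in < 1) {
    abort("pulse durations must be >= 1 ms.", class = "refractiv_config_error")
  }
  structure(
    list(stimulated = as.integer(stimulated),
         gamma_s = gamma_s, stim_duration = as.integer(stim_duration),
         lambda_s = lambda_s, lambda_s_min = lambda_s_min,
         lambda_s_max = lambda_s_max,
         gamma_ex = gamma_ex, tau_ex = tau_ex, lambda_ex = lambda_ex,
         lambda_ex_min = lambda_ex_min, lambda_ex_max = lambda_ex_max,
         gamma_in = gamma_in, tau_in = tau_in, lambda_in = lambda_in,
         lambda_in_min = lambda_in_min, lambda_in_max = lambda_in_max,
         gains = gains),
    class = "drive_protocol"
  )
}

#' Read a drive protocol from a YAML configuration file
#'
#' Field names mirror [drive_protocol()] arguments (`gamma_s`,
#' `lambda_s`, `lambda_s_min`, `tau_ex`, ...).
#'
#' @param path YAML file path.
#' @return A `drive_protocol`.
#' @export
read_drive_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the 'yaml' package.")
  }
  cfg <- yaml::read_yaml(path)
  do.call(drive_protocol, cfg)
}

#' Realize a drive protocol as per-time input series
#'
#' Samples (or accepts) the three onset schedules and lays out the
#' pulse trains over the horizon.  A pulse holds its amplitude for its
#' duration starting at the onset bin; overlapping pulses add.  The
#' result separates the shared confounder series from the stimulus
#' series so that `U_i(t) = common(t) + gain_i * stim(t)`.
#'
#' @param protocol a [drive_protocol()].
#' @param n_neurons number of neurons the trace applies to.
#' @param horizon number of 1-ms steps.
#' @param seed optional integer seed (three sub-streams: stimulus,
#'   excitatory, inhibitory onsets).
#' @param onsets optional list with elements `s`, `ex`, `in` of
#'   pre-sampled onset times, bypassing sampling.
#' @return A `drive_trace` with elements `common` (length `horizon`),
#'   `stim` (length `horizon`), `gains` (length `n_neurons`) and
#'   `onsets`.
#' @export
drive_trace <- function(protocol, n_neurons, horizon, seed = NULL,
                        onsets = NULL) {
  horizon <- as.integer(horizon)
  if (is.null(onsets)) {
    seeds <- derive_seeds(seed, 3L)
    onsets <- list(
      s = if (protocol$gamma_s != 0 && length(protocol$stimulated) > 0)
        sample_onsets(protocol$lambda_s, protocol$lambda_s_min,
                      protocol$lambda_s_max, horizon, seeds[[1]])
      else integer(0),
      ex = if (protocol$gamma_ex != 0)
        sample_onsets(protocol$lambda_ex, protocol$lambda_ex_min,
                      protocol$lambda_ex_max, horizon, seeds[[2]])
      else integer(0),
      `in` = if (protocol$gamma_in != 0)
        sample_onsets(protocol$lambda_in, protocol$lambda_in_min,
                      protocol$lambda_in_max, horizon, seeds[[3]])
      else integer(0)
    )
  }
  stim <- pulse_train(onsets$s, protocol$stim_duration, protocol$gamma_s, horizon)
  common <- pulse_train(onsets$ex, protocol$tau_ex, protocol$gamma_ex, horizon) +
    pulse_train(onsets$`in`, protocol$tau_in, protocol$gamma_in, horizon)
  gains <- numeric(n_neurons)
  if (length(protocol$stimulated) > 0) {
    g <- protocol$gains %||% rep(1, length(protocol$stimulated))
    gains[protocol$stimulated] <- g
  }
  structure(
    list(common = common, stim = stim, gains = gains, onsets = onsets,
         n_neurons = n_neurons, horizon = horizon),
    class = "drive_trace"
  )
}

# additive rectangular pulse train over 1..horizon
pulse_train <- function(onsets, duration, amplitude, horizon) {
  out <- numeric(horizon)
  if (length(onsets) == 0 || amplitude == 0) return(out)
  for (k in seq_len(duration)) {
    idx <- onsets + k - 1L
    idx <- idx[idx >= 1L & idx <= horizon]
    out[idx] <- out[idx] + amplitude
  }
  out
}

#' @export
as.matrix.drive_trace <- function(x, ...) {
  outer(x$gains, x$stim) + matrix(x$common, x$n_neurons, x$horizon, byrow = TRUE)
}

#' @export
print.drive_trace <- function(x, ...) {
  cat("<drive_trace>", x$n_neurons, "neurons x", x$horizon, "ms;",
      length(x$onsets$s), "stimulus,", length(x$onsets$ex), "excitatory,",
      length(x$onsets$`in`), "inhibitory pulses\n")
  invisible(x)
}
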