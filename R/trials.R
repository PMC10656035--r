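#' Spike-detection windows around stimulus onsets
#'
#' Three half-open windows relative to each stimulus onset define the
#' binary trial variables for an upstream/downstream pair: `Z` (pre,
#' default `[-2, 0)`, the refractoriness instrument), `X` (during,
#' default `[0, 2)`, the treatment) and `Y` (post, default `[2, 4)`,
#' the outcome).  The starred baseline windows used by the
#' difference-in-differences correction are each window shifted one
#' window width backward in time, so with defaults `Y*` coincides with
#' the stimulation window and `X*` with the `Z` window.
#'
#' Windows are half-open `[offset, offset + width)` so that with the
#' defaults Z, X and Y tile the time axis without overlap at 1-ms
#' resolution.
#'
#' @param offsets named numeric vector of window starts relative to
#'   stimulus onset (ms), names `z`, `x`, `y`.
#' @param width common window width (ms), default 2.
#' @param star_shift backward shift of the starred baseline windows
#'   (ms); defaults to `width`.
#' @return A `window_spec`.
#' @export
window_spec <- function(offsets = c(z = -2, x = 0, y = 2), width = 2,
                        star_shift = width) {
  if (width <= 0) abort("`width` must be > 0.", class = "refractiv_config_error")
  if (!all(c("z", "x", "y") %in% names(offsets))) {
    abort("`offsets` must name `z`, `x` and `y`.",
          class = "refractiv_config_error")
  }
  structure(list(offsets = offsets, width = width, star_shift = star_shift),
            class = "window_spec")
}

# number of spikes of a sorted train in [a, b) for vectors a, b
count_in_window <- function(times, a, b) {
  findInterval(b - 0.5, times) - findInterval(a - 0.5, times)
}

#' Extract stimulus-aligned trial variables for a neuron pair
#'
#' For each stimulus onset \eqn{t_i}, computes the binary indicators
#' `z` (upstream spiked in the pre window -- the neuron enters the
#' stimulus refractory), `x` (upstream spiked during the stimulus
#' window), `y` (downstream spiked in the post window), and the
#' backward-shifted baselines `x_star`, `y_star`.  Onsets whose
#' windows would cross the raster boundaries are dropped.
#'
#' Under the default windows and an absolute refractory period of at
#' least 2 ms, `x` is 0 whenever `z` is 1: a pre-stimulus spike makes
#' the neuron unable to comply with the stimulus.
#'
#' @param raster a `spike_raster`.
#' @param onsets integer vector of stimulus onset times (ms).
#' @param upstream,downstream neuron ids (upstream provides `z`/`x`,
#'   downstream `y`).
#' @param windows a [window_spec()].
#' @param allow_self allow `upstream == downstream` (used for
#'   hit-rate-only extraction).
#' @return A `trial_table`: a tibble with columns `onset`, `z`, `x`,
#'   `y`, `x_star`, `y_star` and attributes `upstream`, `downstream`,
#'   `n_dropped`.
#' @export
extract_trials <- function(raster, onsets, upstream, downstream,
                           windows = window_spec(), allow_self = FALSE) {
  if (upstream == downstream && !allow_self) {
    abort("`upstream` and `downstream` must differ.",
          class = "refractiv_config_error")
  }
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0) {
    warn("empty onset list; returning an empty trial table.")
  }
  off <- windows$offsets; w <- windows$width
  shift <- windows$star_shift %||% w
  lo <- min(off) - shift      # earliest star-window start
  hi <- max(off) + w          # latest window end
  keep <- onsets + lo >= 1 & onsets + hi - 1 <= raster$n_steps
  n_dropped <- sum(!keep)
  onsets <- onsets[keep]
  up <- raster$times[[upstream]]
  down <- raster$times[[downstream]]
  ind <- function(times, o) {
    as.integer(count_in_window(times, onsets + o, onsets + o + w) > 0)
  }
  out <- tibble(
    onset = onsets,
    z = ind(up, off[["z"]]),
    x = ind(up, off[["x"]]),
    y = ind(down, off[["y"]]),
    x_star = ind(up, off[["x"]] - shift),
    y_star = ind(down, off[["y"]] - shift)
  )
  structure(out, upstream = upstream, downstream = downstream,
            n_dropped = n_dropped,
            class = c("trial_table", class(out)))
}
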