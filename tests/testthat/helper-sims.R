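# Shared fixtures, computed lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# two-neuron raster with a single directed connection w (2 -> 1)
two_neuron_raster <- function(w, n_steps = 1e5, seed = 1, spec = network_spec(2)) {
  wm <- matrix(c(0, 0, w, 0), 2, 2)
  simulate_network(spec, wm, n_steps = n_steps, seed = seed)
}

# full-size calibration shared between acceptance blocks
cached_calibration <- function() {
  cached("calibration", calibrate_alpha(0:7, n_steps = 1e6, seed = 42))
}

# three-neuron confounded circuit at ~1e5 stimulation trials
cached_fig1 <- function() {
  cached("fig1", {
    spec <- network_spec(3)
    w <- matrix(0, 3, 3); w[3, 2] <- 7
    proto <- drive_protocol(stimulated = c(1L, 2L), gamma_s = 5,
                            gamma_ex = 2, gamma_in = -5)
    n_steps <- 5.6e6
    dr <- drive_trace(proto, 3L, n_steps, seed = 101)
    raster <- simulate_network(spec, w, dr, n_steps, seed = 101)
    list(raster = raster, onsets = dr$onsets$s, w_cb = 7, spec = spec)
  })
}

# standard errors by splitting trials into K contiguous blocks
block_se <- function(trials, estimator, K = 20) {
  idx <- cut(seq_len(nrow(trials)), K, labels = FALSE)
  ests <- vapply(seq_len(K), function(k) estimator(trials[idx == k, ]),
                 numeric(1))
  stats::sd(ests) / sqrt(K)
}

# random binary trial tables for estimator oracles
random_trial_table <- function(n = 40) {
  tibble::tibble(
    z = stats::rbinom(n, 1, 0.3),
    x = stats::rbinom(n, 1, 0.5),
    y = stats::rbinom(n, 1, 0.5),
    x_star = stats::rbinom(n, 1, 0.3),
    y_star = stats::rbinom(n, 1, 0.4)
  )
}
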