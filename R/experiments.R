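#' Standard drive protocol used by the simulated experiments
#'
#' [drive_protocol()] with the study's standard timing: 2-ms stimulus
#' pulses at a clipped-Poisson period of 50 ms (clip 10-200 ms) and
#' 10-ms confounder pulses at 100 ms (clip 30-400 ms).
#'
#' @param stimulated stimulated neuron ids.
#' @param gamma_s,gamma_ex,gamma_in drive amplitudes.
#' @param gains optional per-neuron stimulus gains.
#' @return A `drive_protocol`.
#' @export
standard_protocol <- function(stimulated, gamma_s, gamma_ex = 0, gamma_in = 0,
                              gains = NULL) {
  drive_protocol(
    stimulated = stimulated, gamma_s = gamma_s, gains = gains,
    gamma_ex = gamma_ex, gamma_in = gamma_in
  )
}

#' Simulate one experimental network condition
#'
#' Builds a Dale's-law network, optionally sparsifies it, runs the
#' binomial-GLM simulation under the standard drive protocol, and
#' returns everything needed for estimation.
#'
#' @param n_neurons network size (even).
#' @param sigma weight scale of the half-size Gaussian draw.
#' @param n_stimulated number of stimulated neurons.
#' @param stimulate which class to stimulate (`"excitatory"`,
#'   `"inhibitory"`, or `"all"` for class-blind illumination).
#' @param gamma_s,gamma_ex,gamma_in drive amplitudes.
#' @param sparsity fraction of connections removed (default 0).
#' @param gains optional per-neuron stimulus gain vector of length
#'   `n_stimulated` (distance-distributed stimulation); default
#'   uniform.
#' @param n_steps simulation length (ms).
#' @param spec optional [network_spec()]; default standard parameters.
#' @param seed integer seed.
#' @return A list with `raster`, `onsets`, `weights`, `stimulated`,
#'   `spec`, `protocol`.
#' @export
simulate_condition <- function(n_neurons, sigma = 1, n_stimulated = 5,
                               stimulate = c("excitatory", "inhibitory", "all"),
                               gamma_s = 6, gamma_ex = 0, gamma_in = 0,
                               sparsity = 0, gains = NULL,
                               n_steps = 1e5, spec = NULL, seed = NULL) {
  stimulate <- match.arg(stimulate)
  seeds <- derive_seeds(seed, 4L)
  half <- gaussian_weights(n_neurons / 2, sigma, seed = seeds[[1]])
  w <- dale_split(half)
  if (sparsity > 0) w <- sparsify(w, sparsity, seed = seeds[[2]])
  pool <- if (stimulate == "all") seq_len(n_neurons)
          else which(neuron_sign(w) == stimulate)
  stim <- if (n_stimulated >= length(pool)) pool
          else with_seed_if(seeds[[3]], sample(pool, n_stimulated))
  spec <- spec %||% network_spec(n_neurons)
  proto <- standard_protocol(stim, gamma_s, gamma_ex, gamma_in, gains = gains)
  dr <- drive_trace(proto, n_neurons, n_steps, seed = seeds[[4]])
  raster <- simulate_network(spec, w, dr, n_steps, seed = seeds[[4]])
  list(raster = raster, onsets = dr$onsets$s, weights = w,
       stimulated = stim, spec = spec, protocol = proto)
}

#' Per-pair estimates for the stimulated neurons of a condition
#'
#' Runs all four trial-based estimators plus the cross-correlogram
#' baseline from every stimulated neuron to every other neuron, and
#' attaches the ground truth, the stimulation hit rate, and the
#' raster's condition number.
#'
#' @param cond a condition from [simulate_condition()], or a list with
#'   `raster`, `onsets`, `weights`, `stimulated`, `spec`.
#' @param targets downstream neuron ids (default all non-stimulated).
#' @param alpha_cal ground-truth calibration slope.
#' @param windows a [window_spec()].
#' @param max_lag correlogram half-width for the CCH baseline.
#' @return A wide tibble, one row per pair: `upstream`, `downstream`,
#'   `weight`, `beta`, `n_trials`, `hit_rate`, `ols`, `ols_did`, `iv`,
#'   `iv_did`, `cch`, `cch_significant`, `condition_number`.
#' @export
pair_results <- function(cond, targets = NULL, alpha_cal = 0.9477,
                         windows = window_spec(), max_lag = 50L) {
  raster <- cond$raster
  targets <- targets %||% setdiff(seq_len(raster$n_neurons), cond$stimulated)
  pairs <- tidyr::expand_grid(upstream = cond$stimulated,
                              downstream = targets) |>
    dplyr::filter(.data$upstream != .data$downstream)
  est <- estimate_pairs(raster, cond$onsets, pairs, windows)
  cchres <- cch_estimate(raster, pairs, max_lag = max_lag)
  kappa <- as.numeric(condition_number(raster))
  est |>
    dplyr::left_join(
      dplyr::select(cchres, "upstream", "downstream", "cch",
                    cch_significant = "significant"),
      by = c("upstream", "downstream")
    ) |>
    dplyr::mutate(
      weight = unclass(cond$weights)[cbind(.data$downstream, .data$upstream)],
      beta = ground_truth_beta(.data$weight, cond$spec$bias, alpha_cal),
      condition_number = kappa,
      .after = "downstream"
    )
}

estimator_cols <- c("ols", "ols_did", "iv", "iv_did", "cch")

#' Long-format results table
#'
#' Pivots the wide per-pair table of [pair_results()] to one row per
#' (pair, estimator), with the signed error against ground truth.
#'
#' @param wide tibble from [pair_results()] (possibly with extra
#'   grid-parameter columns).
#' @return Long tibble with columns `estimator`, `estimate`,
#'   `error = estimate - beta` added.
#' @export
results_long <- function(wide) {
  wide |>
    tidyr::pivot_longer(dplyr::all_of(estimator_cols),
                        names_to = "estimator", values_to = "estimate") |>
    dplyr::mutate(error = .data$estimate - .data$beta)
}

#' Summarize a results table by estimator
#'
#' Mean absolute error (overall and split by connection sign), AUROC,
#' and exclusion counts per estimator within the given grouping.
#'
#' @param results long tibble from [results_long()].
#' @param ... grouping columns (besides `estimator`).
#' @param auroc_direction `"excitatory"` (signed scores),
#'   `"inhibitory"` (negated scores) or `"mixed"` (absolute scores)
#'   for the classification screen.
#' @return Grouped summary tibble with `mae`, `mae_pos_w`,
#'   `mae_neg_w`, `auroc`, `n_pairs`, `n_excluded`.
#' @export
summarize_results <- function(results, ...,
                              auroc_direction = c("excitatory", "inhibitory",
                                                  "mixed")) {
  auroc_direction <- match.arg(auroc_direction)
  score_of <- switch(auroc_direction,
    excitatory = identity,
    inhibitory = function(s) -s,
    mixed = abs
  )
  results |>
    dplyr::group_by(..., .data$estimator) |>
    dplyr::summarise(
      mae = mean(abs(.data$error), na.rm = TRUE),
      mae_pos_w = mean(abs(.data$error[.data$weight >= 0]), na.rm = TRUE),
      mae_neg_w = mean(abs(.data$error[.data$weight <= 0]), na.rm = TRUE),
      auroc = auroc(score_of(.data$estimate), .data$weight != 0),
      n_pairs = dplyr::n(),
      n_excluded = sum(is.na(.data$estimate)),
      .groups = "drop"
    )
}

#' Three-neuron confounding experiment
#'
#' The minimal confounded circuit: neurons A and B both receive the
#' optogenetic stimulus, but only B drives C (`W_CA = 0`,
#' `W_CB` swept over a grid).  Slow excitatory and inhibitory
#' confounder pulses drive all three neurons.  Correlational
#' estimators (OLS, CCH) report a spurious A-to-C connection; the
#' refractoriness IV with the DiD correction does not.
#'
#' @param w_cb_grid ground-truth weights B-to-C to sweep.
#' @param gamma_s,gamma_ex,gamma_in drive amplitudes (defaults: the
#'   three-neuron study condition 5, 2, -5).
#' @param n_steps steps per grid point (default 2e5, about 4000
#'   trials).
#' @param seed integer seed.
#' @return Long results table (columns of [results_long()] plus
#'   `w_cb` and `pair` = `"AC"` or `"BC"`).
#' @export
run_three_neuron <- function(w_cb_grid = 0:7,
                             gamma_s = 5, gamma_ex = 2, gamma_in = -5,
                             n_steps = 2e5, seed = NULL) {
  seeds <- derive_seeds(seed, length(w_cb_grid))
  spec <- network_spec(3)
  purrr::imap_dfr(w_cb_grid, function(w_cb, i) {
    w <- matrix(0, 3, 3)
    w[3, 2] <- w_cb  # B -> C
    proto <- standard_protocol(c(1L, 2L), gamma_s, gamma_ex, gamma_in)
    dr <- drive_trace(proto, 3L, n_steps, seed = seeds[[i]])
    raster <- simulate_network(spec, w, dr, n_steps, seed = seeds[[i]])
    cond <- list(raster = raster, onsets = dr$onsets$s,
                 weights = new_weight_matrix(w, rep("unconstrained", 3)),
                 stimulated = c(1L, 2L), spec = spec)
    pair_results(cond, targets = 3L) |>
      dplyr::mutate(w_cb = w_cb,
                    pair = ifelse(.data$upstream == 1L, "AC", "BC"),
                    .before = 1) |>
      results_long()
  })
}

#' Confounder drive sweep on a recurrent network
#'
#' Sweeps the excitatory and inhibitory confounder amplitudes on a
#' fully connected Dale's-law network with a fixed stimulated set,
#' tracking how the condition number and the estimator errors grow
#' with shared drive.
#'
#' @param n_neurons network size (default 100 at desk scale).
#' @param gamma_ex_grid,gamma_in_grid amplitude grids; settings pair a
#'   varying amplitude on one axis with 0 on the other, plus the joint
#'   baseline.
#' @param gamma_s stimulus amplitude (default 6).
#' @param sigma weight scale.
#' @param n_steps steps per setting.
#' @param seed integer seed.
#' @return Long results table with `gamma_ex`, `gamma_in` columns.
#' @export
run_drive_sweep <- function(n_neurons = 40, gamma_ex_grid = c(0, 2, 4, 7),
                            gamma_in_grid = c(0, -2, -4, -7), gamma_s = 6,
                            sigma = 3, n_steps = 6e5, seed = NULL) {
  grid <- dplyr::bind_rows(
    tibble(gamma_ex = gamma_ex_grid, gamma_in = 0),
    tibble(gamma_ex = 0, gamma_in = gamma_in_grid)
  ) |> dplyr::distinct()
  seeds <- derive_seeds(seed, nrow(grid))
  purrr::pmap_dfr(
    list(grid$gamma_ex, grid$gamma_in, seq_len(nrow(grid))),
    function(gex, gin, i) {
      cond <- simulate_condition(n_neurons, sigma = sigma, gamma_s = gamma_s,
                                 gamma_ex = gex, gamma_in = gin,
                                 n_steps = n_steps, seed = seeds[[i]])
      pair_results(cond) |>
        dplyr::mutate(gamma_ex = gex, gamma_in = gin, .before = 1) |>
        results_long()
    }
  )
}

#' Network size, stimulation strength and weight-scale sweep
#'
#' Unconfounded Dale networks over a grid of sizes, stimulus
#' amplitudes and weight scales; the grid cells with strong stimuli
#' and strong weights are where the condition number grows and the
#' estimators separate.
#'
#' @param sizes network sizes.
#' @param gamma_s_grid stimulus amplitudes.
#' @param sigma_grid weight scales.
#' @param n_steps steps per cell.
#' @param seed integer seed.
#' @return Long results table with `n_neurons`, `gamma_s`, `sigma`
#'   columns.
#' @export
run_size_stim_weight_sweep <- function(sizes = c(50, 100),
                                       gamma_s_grid = c(2, 5, 8),
                                       sigma_grid = c(3, 5),
                                       n_steps = 2e5, seed = NULL) {
  grid <- tidyr::expand_grid(n_neurons = sizes, gamma_s = gamma_s_grid,
                             sigma = sigma_grid)
  seeds <- derive_seeds(seed, nrow(grid))
  purrr::pmap_dfr(
    list(grid$n_neurons, grid$gamma_s, grid$sigma, seq_len(nrow(grid))),
    function(n, gs, sg, i) {
      cond <- simulate_condition(n, sigma = sg, gamma_s = gs,
                                 n_steps = n_steps, seed = seeds[[i]])
      pair_results(cond) |>
        dplyr::mutate(n_neurons = n, gamma_s = gs, sigma = sg, .before = 1) |>
        results_long()
    }
  )
}

#' Sparsity and stimulated-fraction sweep
#'
#' Two sub-sweeps on unconfounded Dale networks: connection sparsity
#' at a fixed small stimulated set, and the fraction of stimulated
#' neurons at fixed full connectivity.  Sparser networks are easier
#' (lower error); stimulating more of the network is harder.
#'
#' @param n_neurons network size.
#' @param sparsity_grid zeroed-connection fractions.
#' @param stim_fraction_grid fractions of neurons stimulated.
#' @param gamma_s stimulus amplitude.
#' @param sigma weight scale.
#' @param n_steps steps per setting.
#' @param seed integer seed.
#' @return Long results table with `sweep`, `sparsity`,
#'   `stim_fraction` columns.
#' @export
run_sparsity_stim_fraction <- function(n_neurons = 100,
                                       sparsity_grid = c(0, 0.5, 0.9),
                                       stim_fraction_grid = c(0.05, 0.1, 0.25),
                                       gamma_s = 8, sigma = 5,
                                       n_steps = 4e5, seed = NULL) {
  grid <- dplyr::bind_rows(
    tibble(sweep = "sparsity", sparsity = sparsity_grid,
           stim_fraction = 0.05),
    tibble(sweep = "stim_fraction", sparsity = 0,
           stim_fraction = stim_fraction_grid)
  ) |> dplyr::distinct(.data$sparsity, .data$stim_fraction, .keep_all = TRUE)
  seeds <- derive_seeds(seed, nrow(grid))
  purrr::pmap_dfr(
    list(grid$sweep, grid$sparsity, grid$stim_fraction,
         seq_len(nrow(grid))),
    function(sw, sp, sf, i) {
      k <- max(1L, round(sf * n_neurons))
      cond <- simulate_condition(n_neurons, sigma = sigma, n_stimulated = k,
                                 gamma_s = gamma_s, sparsity = sp,
                                 n_steps = n_steps, seed = seeds[[i]])
      pair_results(cond) |>
        dplyr::mutate(sweep = sw, sparsity = sp, stim_fraction = sf,
                      .before = 1) |>
        results_long()
    }
  )
}

#' Distance-distributed optogenetic stimulation sweep
#'
#' Every neuron receives the stimulus with a gain set by its random
#' distance from the fiber through the light-transport and
#' photocurrent model; network size is swept.  Larger networks recruit
#' more stimulated neurons, raising hit rates, condition numbers and
#' errors.
#'
#' @param sizes network sizes.
#' @param gamma_s_max stimulus amplitude reaching the nearest neuron
#'   (default 10, well past threshold at `b = 5`).
#' @param sigma weight scale.
#' @param gamma_ex,gamma_in confounder amplitudes (defaults 2, -5).
#' @param fiber,opsin light model parameters.
#' @param n_steps steps per network.
#' @param seed integer seed.
#' @return Long results table with an `n_neurons` column.
#' @export
run_distance_stim <- function(sizes = c(100, 300, 500), gamma_s_max = 10,
                              sigma = 3, gamma_ex = 2, gamma_in = -5,
                              fiber = fiber_spec(), opsin = opsin_spec(),
                              n_steps = 2e5, seed = NULL) {
  seeds <- derive_seeds(seed, 2L * length(sizes))
  purrr::imap_dfr(sizes, function(n, i) {
    gains <- assign_stimulus_gains(n, fiber, opsin, seed = seeds[[2 * i - 1]])
    cond <- simulate_condition(
      n, sigma = sigma, n_stimulated = n, stimulate = "all",
      gamma_s = gamma_s_max, gamma_ex = gamma_ex, gamma_in = gamma_in,
      gains = gains, n_steps = n_steps, seed = seeds[[2 * i]]
    )
    # every neuron is (weakly) stimulated; report the 5 nearest as upstream
    up <- order(attr(gains, "distance_mm"))[1:5]
    cond$stimulated <- up
    pair_results(cond) |>
      dplyr::mutate(n_neurons = n, .before = 1) |>
      results_long()
  })
}

#' Inhibitory stimulation experiment
#'
#' Stimulates inhibitory neurons of a balanced Dale network and scores
#' the estimators on the outgoing (nonpositive) weights; the
#' inhibitory screen negates scores for AUROC.
#'
#' @param n_neurons network size (default 120).
#' @param gamma_s stimulus amplitude (default 3).
#' @param sigma_grid weight scales swept.
#' @param gamma_ex,gamma_in confounder amplitudes.
#' @param n_steps steps per setting.
#' @param seed integer seed.
#' @return Long results table with a `sigma` column.
#' @export
run_inhibitory <- function(n_neurons = 120, gamma_s = 3,
                           sigma_grid = c(1, 3, 5), gamma_ex = 2,
                           gamma_in = -5, n_steps = 2e5, seed = NULL) {
  seeds <- derive_seeds(seed, length(sigma_grid))
  purrr::imap_dfr(sigma_grid, function(sg, i) {
    cond <- simulate_condition(n_neurons, sigma = sg,
                               stimulate = "inhibitory",
                               gamma_s = gamma_s, gamma_ex = gamma_ex,
                               gamma_in = gamma_in,
                               n_steps = n_steps, seed = seeds[[i]])
    pair_results(cond) |>
      dplyr::mutate(sigma = sg, .before = 1) |>
      results_long()
  })
}

#' Error-versus-condition-number overview plot
#'
#' @param results long results table from any `run_*()` experiment.
#' @return A ggplot: absolute error by estimator, colored by condition
#'   number.
#' @export
plot_error_overview <- function(results) {
  ggplot2::ggplot(
    dplyr::filter(results, !is.na(.data$estimate)),
    ggplot2::aes(.data$estimator, abs(.data$error),
                 colour = log10(.data$condition_number))
  ) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", colour = "black",
                          width = 0.5) +
    ggplot2::labs(x = NULL, y = "|estimate - beta|",
                  colour = "log10 kappa") +
    ggplot2::theme_minimal()
}
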