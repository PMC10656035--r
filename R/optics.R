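#' Optical fiber and tissue parameters
#'
#' Parameters of one-photon light delivery through brain tissue from an
#' optical fiber: Kubelka-Munk scattering coefficient, fiber radius and
#' numerical aperture, tissue refractive index, source intensity at the
#' fiber tip, implantation depth, and neuron density.  Defaults are
#' typical mouse-cortex values.
#'
#' @param scattering_S scattering coefficient (1/mm), default 10.3.
#' @param fiber_radius fiber radius (mm), default 0.1 (a 0.2-mm fiber;
#'   the value is sometimes quoted in micrometres by mistake, but a
#'   0.2-um fiber is physically implausible and the geometric-loss
#'   formula uses the fiber diameter in mm).
#' @param NA_fiber numerical aperture, default 0.37.
#' @param refraction_n refractive index of gray matter, default 1.36.
#' @param source_intensity intensity at the fiber tip (mW/mm^2),
#'   default 10.
#' @param depth implantation depth (mm), default 0.7.
#' @param neuron_density neurons per mm^3, default 1960.
#' @return A `fiber_spec`.
#' @export
fiber_spec <- function(scattering_S = 10.3, fiber_radius = 0.1,
                       NA_fiber = 0.37, refraction_n = 1.36,
                       source_intensity = 10, depth = 0.7,
                       neuron_density = 1960) {
  if (NA_fiber >= refraction_n) {
    abort("`NA_fiber` must be smaller than `refraction_n`.",
          class = "refractiv_config_error")
  }
  if (any(c(scattering_S, fiber_radius, NA_fiber, refraction_n,
            source_intensity, depth, neuron_density) <= 0)) {
    abort("all fiber parameters must be positive.",
          class = "refractiv_config_error")
  }
  structure(list(scattering_S = scattering_S, fiber_radius = fiber_radius,
                 NA_fiber = NA_fiber, refraction_n = refraction_n,
                 source_intensity = source_intensity, depth = depth,
                 neuron_density = neuron_density),
            class = "fiber_spec")
}

#' Opsin photocurrent parameters (Hill equation)
#'
#' @param I_max maximum photocurrent (pA), default 642 (ChR2).
#' @param hill_n Hill coefficient, default 0.76.
#' @param half_sat_K half-saturating intensity (mW/mm^2), default 0.84.
#' @return An `opsin_spec`.
#' @export
opsin_spec <- function(I_max = 642, hill_n = 0.76, half_sat_K = 0.84) {
  if (any(c(I_max, hill_n, half_sat_K) <= 0)) {
    abort("all opsin parameters must be positive.",
          class = "refractiv_config_error")
  }
  structure(list(I_max = I_max, hill_n = hill_n, half_sat_K = half_sat_K),
            class = "opsin_spec")
}

#' Kubelka-Munk tissue transmission
#'
#' Diffuse-scattering transmission fraction `T = 1 / (S r + 1)` at
#' distance `r` from the source, neglecting absorption.
#'
#' @param distance distance(s) from the fiber tip (mm), `>= 0`.
#' @param fiber a [fiber_spec()].
#' @return Transmission fraction in `(0, 1]`.
#' @export
light_transmission <- function(distance, fiber = fiber_spec()) {
  if (any(distance < 0)) {
    abort("`distance` must be >= 0.", class = "refractiv_domain_error")
  }
  1 / (fiber$scattering_S * distance + 1)
}

# half-divergence length of the emission cone
fiber_rho <- function(fiber) {
  fiber$fiber_radius * sqrt((fiber$refraction_n / fiber$NA_fiber)^2 - 1)
}

#' Relative light intensity with distance
#'
#' Combines Kubelka-Munk scattering with conical geometric loss:
#' `I(r)/I(0) = rho^2 / ((S r + 1) (r + rho)^2)` where
#' `rho = radius * sqrt((n/NA)^2 - 1)`.  Equals 1 at the fiber tip and
#' decays slightly faster than `1/r^2` at depth.
#'
#' @inheritParams light_transmission
#' @return Intensity relative to the fiber tip, in `(0, 1]`.
#' @export
relative_intensity <- function(distance, fiber = fiber_spec()) {
  if (any(distance < 0)) {
    abort("`distance` must be >= 0.", class = "refractiv_domain_error")
  }
  rho <- fiber_rho(fiber)
  rho^2 / ((fiber$scattering_S * distance + 1) * (distance + rho)^2)
}

#' Opsin photocurrent from light intensity
#'
#' Hill equation `P = I_max * I^n / (K^n + I^n)`: monotone increasing
#' and saturating at `I_max`, with half-saturation at `I = K`.
#'
#' @param intensity light intensity (mW/mm^2), `>= 0`.
#' @param opsin an [opsin_spec()].
#' @return Peak photocurrent (pA).
#' @export
photocurrent <- function(intensity, opsin = opsin_spec()) {
  if (any(intensity < 0)) {
    abort("`intensity` must be >= 0.", class = "refractiv_domain_error")
  }
  with(opsin, I_max * intensity^hill_n / (half_sat_K^hill_n + intensity^hill_n))
}

#' Per-shell light and activation profile
#'
#' Distributes neurons uniformly over spherical shells of equal
#' thickness inside the cone of light (half-angle `asin(NA/n)`), and
#' evaluates intensity and photocurrent at each shell midpoint.  The
#' per-shell total photocurrent (count x photocurrent) grows with
#' distance because the neuron count grows like `r^2` while the
#' sublinear Hill response decays slower than the intensity.
#'
#' @param fiber a [fiber_spec()].
#' @param opsin an [opsin_spec()].
#' @param n_shells number of shells (default 15).
#' @param max_depth outer radius of the last shell (mm, default 1).
#' @return A tibble with one row per shell: `distance_mm` (midpoint),
#'   `intensity_rel`, `intensity` (mW/mm^2), `neuron_count`,
#'   `photocurrent_pA`, `shell_total`.
#' @export
shell_activation_profile <- function(fiber = fiber_spec(),
                                     opsin = opsin_spec(),
                                     n_shells = 15L, max_depth = 1) {
  n_shells <- as.integer(n_shells)
  if (is.na(n_shells) || n_shells < 1L) {
    abort("`n_shells` must be >= 1.", class = "refractiv_config_error")
  }
  edges <- seq(0, max_depth, length.out = n_shells + 1L)
  r_in <- edges[-length(edges)]
  r_out <- edges[-1]
  r_mid <- (r_in + r_out) / 2
  # solid angle of the light cone bounds the shell to a spherical cap
  theta <- asin(fiber$NA_fiber / fiber$refraction_n)
  omega <- 2 * pi * (1 - cos(theta))
  volume <- omega * (r_out^3 - r_in^3) / 3
  count <- fiber$neuron_density * volume
  irel <- relative_intensity(r_mid, fiber)
  inten <- fiber$source_intensity * irel
  pc <- photocurrent(inten, opsin)
  tibble(
    shell = seq_len(n_shells), distance_mm = r_mid,
    intensity_rel = irel, intensity = inten,
    neuron_count = count, photocurrent_pA = pc,
    shell_total = count * pc
  )
}

#' Assign distance-dependent stimulus gains to neurons
#'
#' Places each neuron at a random distance from the fiber tip (uniform
#' over the cone volume, i.e. density proportional to `r^2` up to
#' `max_depth`) and computes the opsin photocurrent at that distance,
#' expressed relative to the photocurrent at the fiber tip, so a
#' hypothetical neuron at distance 0 has gain 1.  In larger
#' populations the nearest neurons sit closer to the fiber, so top
#' gains grow with population size.  The returned gains multiply the
#' stimulus amplitude in [drive_protocol()]; choose the amplitude
#' (ceiling) so a neuron at the fiber tip is driven well past
#' threshold, e.g. with [calibrate_stim_ceiling()].
#'
#' @param n_neurons number of neurons.
#' @param fiber a [fiber_spec()].
#' @param opsin an [opsin_spec()].
#' @param max_depth maximum distance (mm, default 1).
#' @param seed optional integer seed.
#' @return Numeric vector of gains in `[0, 1]` with attribute
#'   `distance_mm`.
#' @export
assign_stimulus_gains <- function(n_neurons, fiber = fiber_spec(),
                                  opsin = opsin_spec(), max_depth = 1,
                                  seed = NULL) {
  r <- with_seed_if(seed, max_depth * stats::runif(n_neurons)^(1 / 3))
  pc <- photocurrent(fiber$source_intensity * relative_intensity(r, fiber),
                     opsin)
  g <- pc / photocurrent(fiber$source_intensity, opsin)
  attr(g, "distance_mm") <- r
  g
}

#' Calibrate the stimulus amplitude for a target hit rate
#'
#' Bisects on the stimulus amplitude until the most strongly driven
#' neuron responds within the 2-ms stimulus window on at least
#' `target` of trials, using short single-neuron simulations.
#'
#' @param spec a [network_spec()] (only the bias and refractory kernel
#'   matter).
#' @param target hit-rate target for the maximal-gain neuron
#'   (default 0.99).
#' @param n_steps steps per probe simulation (default 2e4).
#' @param seed optional integer seed.
#' @return The calibrated stimulus amplitude.
#' @export
calibrate_stim_ceiling <- function(spec = network_spec(1), target = 0.99,
                                   n_steps = 2e4, seed = NULL) {
  probe <- function(amp, s) {
    spec1 <- spec; spec1$n_neurons <- 1L
    proto <- drive_protocol(stimulated = 1L, gamma_s = amp,
                            lambda_s = 50, lambda_s_min = 50, lambda_s_max = 50)
    dr <- drive_trace(proto, 1L, n_steps, seed = s)
    r <- simulate_network(spec1, n_steps = n_steps, drive = dr, seed = s)
    tr <- extract_trials(r, dr$onsets$s, upstream = 1L, downstream = 1L,
                         allow_self = TRUE)
    hit_rate(tr)
  }
  seeds <- derive_seeds(seed, 2L)
  lo <- 0; hi <- spec$bias + 10
  for (k in 1:12) {
    mid <- (lo + hi) / 2
    if (probe(mid, seeds[[1]]) >= target) hi <- mid else lo <- mid
  }
  hi
}
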