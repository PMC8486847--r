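# Seeded generators for every input the pipeline consumes: staircase
# sensing runs, association/dissociation specificity runs, and 20-bit OOK
# transmission traces. Noise-free outputs coincide with the forward models
# to floating precision, so the generators double as ground truth for the
# fitting and detection tests. The noise model is additive Gaussian current
# noise with optional slow linear drift — a deliberate simplification of
# real FET noise (no 1/f structure, no temperature or nonspecific-binding
# effects).

#' Measurement-noise model
#'
#' @param sigma_uA additive Gaussian noise sd in uA (default 0.05, which
#'   after 21-s filtering leaves roughness of roughly 0.15% of a ~31 uA
#'   baseline)
#' @param drift_uA_s slow linear baseline drift in uA/s (default 0)
#' @param seed integer RNG seed
#' @return an object of class `noise_model`
#' @export
noise_model <- function(sigma_uA = 0.05, drift_uA_s = 0, seed = 1) {
  if (sigma_uA < 0) stop("noise sd must be non-negative")
  structure(list(sigma = sigma_uA, drift = drift_uA_s,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' @noRd
apply_noise <- function(times, currents, noise) {
  if (is.null(noise)) return(currents)
  stopifnot(inherits(noise, "noise_model"))
  set.seed(noise$seed)
  currents + noise$drift * times +
    if (noise$sigma > 0) stats::rnorm(length(times), 0, noise$sigma) else 0
}

#' Pseudorandom binary sequence
#'
#' Reproducible fair-coin 0/1 sequence for OOK payloads.
#'
#' @param length number of bits (>= 1)
#' @param seed integer RNG seed
#' @return integer 0/1 vector
#' @export
prbs <- function(length, seed = 1) {
  if (length < 1) stop("length must be >= 1")
  set.seed(as.integer(seed))
  sample(c(0L, 1L), length, replace = TRUE)
}

#' Synthetic staircase sensing run
#'
#' Emulates flowing successively higher target concentrations over the
#' receiver, each held until the response settles to within `settle` of its
#' step equilibrium. Each step is an exponential transient restarted from
#' the occupancy reached at the previous step; the plateaus trace out the
#' Langmuir isotherm.
#'
#' @param concs_M increasing concentrations in M
#' @param rates a [kinetic_rates()]
#' @param delta_i_sat_uA saturation response in uA (signed)
#' @param baseline_uA baseline current in uA added to the response
#' @param noise a [noise_model()] or NULL
#' @param settle relative distance from step equilibrium at which the next
#'   concentration is introduced (default 0.01)
#' @param dt_s sampling interval in s
#' @return a list with `trace` (a [fet_trace()] of absolute current),
#'   `plateaus` (data.frame of concentration, plateau dI), and
#'   `step_times` (s)
#' @export
gen_sensing_staircase <- function(concs_M, rates, delta_i_sat_uA,
                                  baseline_uA = 31.25, noise = NULL,
                                  settle = 0.01, dt_s = 1) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (is.unsorted(concs_M, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  theta <- 0
  t0 <- 0
  times <- numeric(0); occ <- numeric(0)
  step_times <- numeric(length(concs_M))
  plateaus <- numeric(length(concs_M))
  for (j in seq_along(concs_M)) {
    cc <- concs_M[j]
    th_eq <- langmuir_equilibrium(cc, rates$k_d)
    k_obs <- rates$k_on * cc + rates$k_off
    # dwell until |theta - th_eq| <= settle * th_eq
    gap <- abs(th_eq - theta)
    dwell <- if (gap <= settle * th_eq) 10 * dt_s else
      ceiling(log(gap / (settle * th_eq)) / k_obs / dt_s) * dt_s
    tt <- seq(dt_s, dwell, by = dt_s)
    th <- th_eq + (theta - th_eq) * exp(-k_obs * tt)
    step_times[j] <- t0
    times <- c(times, t0 + tt)
    occ <- c(occ, th)
    theta <- th[length(th)]
    plateaus[j] <- theta * delta_i_sat_uA
    t0 <- t0 + dwell
  }
  cur <- baseline_uA + occ * delta_i_sat_uA
  list(trace = fet_trace(times, apply_noise(times, cur, noise)),
       plateaus = data.frame(conc_M = concs_M, delta_i_uA = plateaus),
       step_times = step_times)
}

#' Synthetic specificity (association/dissociation) run
#'
#' Target solution applied from t = 0, replaced with plain buffer at `t_d_s`
#' (~1800 s in the reference experiments) so the bound targets dissociate.
#'
#' @param rates a [kinetic_rates()]
#' @param c_in_M applied concentration in M
#' @param delta_i_sat_uA saturation response in uA (signed)
#' @param t_d_s buffer-switch time in s
#' @param duration_s total trace length in s (> t_d_s)
#' @param baseline_uA baseline current in uA
#' @param noise a [noise_model()] or NULL
#' @param dt_s sampling interval in s
#' @return a [fet_trace()] of absolute current (uA)
#' @export
gen_specificity_trace <- function(rates, c_in_M, delta_i_sat_uA,
                                  t_d_s = 1800, duration_s = 3600,
                                  baseline_uA = 31.25, noise = NULL,
                                  dt_s = 1) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (t_d_s >= duration_s) stop("t_d_s must be below duration_s")
  times <- seq(0, duration_s, by = dt_s)
  eq <- delta_i_sat_uA * langmuir_equilibrium(c_in_M, rates$k_d)
  di <- ifelse(times <= t_d_s,
               association_response(times, rates, c_in_M, eq),
               dissociation_response(
                 pmax(times, t_d_s), t_d_s, rates$k_off,
                 association_response(t_d_s, rates, c_in_M, eq)))
  fet_trace(times, apply_noise(times, baseline_uA + di, noise))
}

#' Synthetic OOK transmission trace
#'
#' LTI superposition of pulse responses for a bit sequence, plus baseline
#' and noise; returns the ground-truth bits alongside so end-to-end
#' detection studies need no bookkeeping.
#'
#' @param spec a [transmission_spec()]
#' @param model a [pulse_model()]
#' @param baseline_uA baseline current in uA
#' @param noise a [noise_model()] or NULL
#' @param dt_s sampling interval in s
#' @param tail_s extra time after the last bit interval, in s
#' @param mode "lti" (default) or "ode"; see [received_signal()]
#' @return a list with `trace` (absolute current, uA), `bits`, and `spec`
#' @export
gen_transmission_trace <- function(spec, model, baseline_uA = 31.25,
                                   noise = NULL, dt_s = 1, tail_s = 0,
                                   mode = "lti") {
  stopifnot(inherits(spec, "transmission_spec"))
  t_end <- spec$t_transmit +
    length(spec$bits) * spec$bit_interval + tail_s
  times <- seq(0, t_end, by = dt_s)
  rx <- received_signal(spec, model, times, mode = mode)
  cur <- apply_noise(times, baseline_uA + rx$current, noise)
  list(trace = fet_trace(times, cur), bits = spec$bits, spec = spec)
}
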