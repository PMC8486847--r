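# Ligand-receptor (probe-target hybridisation) dynamics on the sensor
# surface. Three model layers, each the small-signal limit of the next:
# the equilibrium Langmuir isotherm, the pure-kinetics exponential
# association/dissociation transients, and the transport-limited
# finite-pulse response in closed form via the principal Lambert-W branch.
#
# The closed form is the exact solution of the quasi-steady two-compartment
# model in which the surface-adjacent concentration c_s equilibrates
# instantaneously with the net binding flux:
#     k_T (c_b - c_s) = dN/dt = k+ c_s (N_max - N) - k- N
# which collapses to
#     dN/dt = k_T [k+ c_b (N_max - N) - k- N] / (k_T + k+ (N_max - N)).
# `ode_reference_response()` integrates that right-hand side numerically and
# is the independent oracle the closed form is tested against.
#
# Internal state is the bound-receptor count N(t); conversion to current is
# a single multiplication by the (signed) transduction factor Q at the
# boundary, which keeps every sign convention out of the kinetics.

#' Association/dissociation rate constants
#'
#' @param k_on association rate constant in 1/(M s)
#' @param k_off dissociation rate constant in 1/s
#' @return an object of class `kinetic_rates`; `$k_d` holds the derived
#'   dissociation constant k_off/k_on in M
#' @examples
#' tdna_rates <- kinetic_rates(k_on = 1814.9, k_off = 13.538e-4)
#' tdna_rates$k_d  # ~7.46e-7 M
#' @export
kinetic_rates <- function(k_on, k_off) {
  if (!is.finite(k_on) || !is.finite(k_off) || k_on <= 0 || k_off <= 0)
    stop("rate constants must be strictly positive")
  structure(list(k_on = k_on, k_off = k_off, k_d = k_off / k_on),
            class = "kinetic_rates")
}

#' Signed response scale of the receiver
#'
#' @param delta_i_eq equilibrium current change at the working
#'   concentration, in uA (signed; negative for an n-doping response)
#' @param delta_i_sat saturation current change in uA (same sign, larger
#'   magnitude)
#' @param q_factor per-molecule transduction factor in uA (same sign)
#' @return an object of class `response_scale`
#' @export
response_scale <- function(delta_i_eq, delta_i_sat, q_factor) {
  if (abs(delta_i_eq) > abs(delta_i_sat) + 1e-12)
    stop("|delta_i_eq| cannot exceed |delta_i_sat|")
  if (sign(delta_i_eq) * sign(delta_i_sat) < 0)
    stop("delta_i_eq and delta_i_sat must share sign")
  if (q_factor == 0 || sign(q_factor) * sign(delta_i_eq) < 0)
    stop("q_factor must be nonzero and share the response sign")
  structure(list(delta_i_eq = delta_i_eq, delta_i_sat = delta_i_sat,
                 q_factor = q_factor),
            class = "response_scale")
}

#' Finite-pulse response model
#'
#' Bundles everything the closed-form pulse response needs: kinetics, the
#' average concentration over the surface during the pulse, the lumped
#' transport coefficient, the signed response scale, and the pulse window.
#'
#' @param rates a [kinetic_rates()]
#' @param c_avg_M average target concentration over the receiver during the
#'   pulse, in M (plug-flow default: the inlet pulse concentration)
#' @param k_t lumped transport coefficient coupling bulk to surface, in
#'   molecules/(M s); see [leveque_transport_rate()] for a boundary-layer
#'   default
#' @param response a [response_scale()]
#' @param t_a association (pulse arrival) start time in s
#' @param t_d dissociation start time in s (> t_a)
#' @return an object of class `pulse_model`
#' @export
pulse_model <- function(rates, c_avg_M, k_t, response, t_a = 0, t_d) {
  stopifnot(inherits(rates, "kinetic_rates"),
            inherits(response, "response_scale"))
  if (!is.finite(c_avg_M) || c_avg_M <= 0)
    stop("c_avg_M must be strictly positive")
  if (!is.finite(k_t) || k_t <= 0) stop("k_t must be strictly positive")
  if (t_d <= t_a) stop("t_d must exceed t_a")
  structure(list(rates = rates, c_avg = c_avg_M, k_t = k_t,
                 response = response, t_a = t_a, t_d = t_d),
            class = "pulse_model")
}

#' Equilibrium Langmuir occupancy
#'
#' theta = 1 / (1 + K_D / c) = c / (c + K_D): the equilibrium fraction of
#' occupied receptors at concentration c. Multiply by the saturation
#' response to obtain the equilibrium current change.
#'
#' @param c_M concentration(s) in M (>= 0)
#' @param k_d_M dissociation constant in M (> 0)
#' @return fractional occupancy in `[0, 1)`
#' @examples
#' langmuir_equilibrium(1e-6, 730e-9) * 1.393  # |dI_eq| ~ 0.805 uA
#' @export
langmuir_equilibrium <- function(c_M, k_d_M) {
  if (any(c_M < 0)) stop("concentration must be non-negative")
  if (k_d_M <= 0) stop("dissociation constant must be strictly positive")
  c_M / (c_M + k_d_M)
}

#' Association transient
#'
#' dI(t) = dI_eq (1 - exp(-(k_on c + k_off) t)): exponential approach to
#' equilibrium with the observed rate k_obs = k_on c + k_off, time
#' referenced to the arrival of the target solution.
#'
#' @param t time(s) since association start, in s (>= 0)
#' @param rates a [kinetic_rates()]
#' @param c_in_M applied target concentration in M
#' @param delta_i_eq equilibrium response at `c_in_M`, in uA (signed)
#' @return current change(s) in uA
#' @export
association_response <- function(t, rates, c_in_M, delta_i_eq) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (any(t < 0)) stop("time must be non-negative")
  k_obs <- rates$k_on * c_in_M + rates$k_off
  delta_i_eq * (1 - exp(-k_obs * t))
}

#' Dissociation transient
#'
#' dI(t) = dI(t_d) exp(-k_off (t - t_d)) for t >= t_d: first-order decay
#' re-referenced to the dissociation start so the composite curve is
#' continuous at t_d.
#'
#' @param t time(s) in s (>= t_d)
#' @param t_d dissociation start time in s
#' @param k_off dissociation rate constant in 1/s
#' @param delta_i_at_td response at t_d, in uA (signed)
#' @return current change(s) in uA
#' @export
dissociation_response <- function(t, t_d, k_off, delta_i_at_td) {
  if (any(t < t_d)) stop("dissociation phase requires t >= t_d")
  delta_i_at_td * exp(-k_off * (t - t_d))
}

#' Principal-branch Lambert W with domain guard
#'
#' Arguments below -1/e (the branch point) by more than a tiny numerical
#' margin raise an error; arguments within the margin are clamped to the
#' branch point, with a warning when the clamp exceeds 1e-9.
#' @noRd
lambert_w0 <- function(x) {
  lim <- -exp(-1)
  bad <- x < lim
  if (any(bad)) {
    worst <- lim - min(x)
    if (worst > 1e-6)
      stop(sprintf(
        "Lambert-W argument %.6g below branch point -1/e by %.3g", min(x), worst))
    if (worst > 1e-9)
      warning(sprintf("Lambert-W argument clamped to -1/e (by %.3g)", worst))
    x[bad] <- lim
  }
  vapply(x, pracma::lambertWp, numeric(1))
}

#' Dimensionless pulse-shape parameters
#'
#' The three constants of the closed-form finite-pulse response, in the
#' receptor-count domain:
#' alpha = k_on c N_eq / (k_off N_eq + k_T c),
#' beta  = (k_on c + k_off) / (1 + k_off N_eq / (k_T c)),
#' gamma = N_max + k_T / k_on.
#' In the fast-transport limit k_T -> Inf these reduce to alpha -> 0,
#' beta -> k_on c + k_off, and gamma -> Inf, recovering the pure-kinetics
#' transients.
#'
#' @param model a [pulse_model()]
#' @return named list with `alpha`, `beta`, `gamma`, plus the receptor-count
#'   scales `n_eq` and `n_max`
#' @export
pulse_params <- function(model) {
  stopifnot(inherits(model, "pulse_model"))
  r <- model$rates
  n_eq <- model$response$delta_i_eq / model$response$q_factor
  n_max <- n_r_max(model$c_avg, r$k_d, n_eq)
  denom <- r$k_off * n_eq + model$k_t * model$c_avg
  if (denom == 0) stop("degenerate model: alpha denominator is zero")
  list(alpha = r$k_on * model$c_avg * n_eq / denom,
       beta = (r$k_on * model$c_avg + r$k_off) /
         (1 + r$k_off * n_eq / (model$k_t * model$c_avg)),
       gamma = n_max + model$k_t / r$k_on,
       n_eq = n_eq, n_max = n_max)
}

#' Closed-form finite-pulse response
#'
#' Evaluates the transport-limited pulse response on a time grid: zero
#' before the pulse arrives at `t_a`; during association (t_a <= t <= t_d)
#' N(t) = N_eq (1 - W0[alpha exp(alpha - beta (t - t_a))] / alpha);
#' after `t_d`
#' N(t) = -gamma W0[-(N_0/gamma) exp((-k_on N_0 - k_T k_off (t - t_d)) /
#' (k_on gamma))], with N_0 = N(t_d). The branch assignment is half-open
#' (association on `[t_a, t_d]`, dissociation on `(t_d, Inf)`), which makes
#' the curve continuous at the pulse edges. Output is converted to current
#' by the model's transduction factor.
#'
#' @param t_grid sorted time grid in s
#' @param model a [pulse_model()]
#' @return current changes in uA, same length as `t_grid`
#' @export
pulse_response <- function(t_grid, model) {
  stopifnot(inherits(model, "pulse_model"))
  if (is.unsorted(t_grid)) stop("t_grid must be sorted")
  model$response$q_factor * pulse_response_counts(t_grid, model)
}

# Receptor-count domain workhorse shared by pulse_response and the
# superposition code. For alpha below ~1e-8 the association branch uses its
# analytic small-alpha limit exp(alpha - beta tau) to avoid 0/0.
#' @noRd
pulse_response_counts <- function(t_grid, model) {
  p <- pulse_params(model)
  r <- model$rates
  n <- numeric(length(t_grid))

  assoc_shape <- function(tau) {
    if (abs(p$alpha) < 1e-8) {
      1 - exp(p$alpha - p$beta * tau)
    } else {
      1 - lambert_w0(p$alpha * exp(p$alpha - p$beta * tau)) / p$alpha
    }
  }

  ia <- t_grid >= model$t_a & t_grid <= model$t_d
  if (any(ia)) n[ia] <- p$n_eq * assoc_shape(t_grid[ia] - model$t_a)

  id <- t_grid > model$t_d
  if (any(id)) {
    n0 <- p$n_eq * assoc_shape(model$t_d - model$t_a)
    tau <- t_grid[id] - model$t_d
    arg <- -(n0 / p$gamma) *
      exp((-r$k_on * n0 - model$k_t * r$k_off * tau) / (r$k_on * p$gamma))
    n[id] <- -p$gamma * lambert_w0(arg)
  }
  n
}

#' Numerically integrated reference pulse response
#'
#' Independent oracle for [pulse_response()]: integrates the quasi-steady
#' two-compartment system
#' dN/dt = k_T (k_on c_b(t) (N_max - N) - k_off N) / (k_T + k_on (N_max - N))
#' with `c_b(t)` following the pulse schedule (c_avg inside `[t_a, t_d]`,
#' zero outside), using a stiff solver. Intended for tests and for
#' quantifying the LTI superposition error; the closed form is the
#' production path.
#'
#' @param t_grid sorted time grid in s
#' @param model a [pulse_model()]
#' @param schedule optional data.frame with columns `on`, `off` (s) giving
#'   multiple pulse windows; defaults to the model's single `[t_a, t_d]`
#' @return current changes in uA on `t_grid`
#' @export
ode_reference_response <- function(t_grid, model, schedule = NULL) {
  stopifnot(inherits(model, "pulse_model"))
  if (is.unsorted(t_grid)) stop("t_grid must be sorted")
  if (is.null(schedule))
    schedule <- data.frame(on = model$t_a, off = model$t_d)
  p <- pulse_params(model)
  r <- model$rates

  c_bulk <- function(t) {
    active <- any(t >= schedule$on & t <= schedule$off)
    if (active) model$c_avg else 0
  }
  rhs <- function(t, y, parms) {
    nn <- y[1]
    cb <- c_bulk(t)
    num <- model$k_t * (r$k_on * cb * (p$n_max - nn) - r$k_off * nn)
    list(num / (model$k_t + r$k_on * (p$n_max - nn)))
  }
  # solver grid: the supplied grid plus exact pulse edges, so the switch
  # times are not smeared by interpolation
  edges <- sort(unique(c(t_grid, schedule$on, schedule$off)))
  edges <- edges[edges >= t_grid[1] & edges <= t_grid[length(t_grid)]]
  sol <- deSolve::ode(y = c(N = 0), times = edges, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  n <- approx(sol[, "time"], sol[, "N"], xout = t_grid, rule = 2)$y
  if (any(n < -1e-6 * abs(p$n_max)) || any(n > p$n_max * (1 + 1e-6)))
    stop("ODE solution violates occupancy bounds")
  model$response$q_factor * n
}

#' Boundary-layer estimate of the lumped transport coefficient
#'
#' A Leveque-type laminar mass-transfer estimate used as a documented
#' default when the transport coefficient has not been fitted: the local
#' mass-transfer coefficient k_c = 0.81 (gdot D^2 / L)^(1/3) with wall shear
#' rate gdot = 6 u / h, converted to molecule-flux units by
#' k_T = k_c A_sensor (1000 N_A). Treat as an order-of-magnitude stand-in;
#' fit it from pulse data when shape accuracy matters.
#'
#' @param fl a [fluid()]
#' @param geometry a [channel_geometry()]
#' @param probe an [oligo_probe()] (supplies the diffusion coefficient)
#' @param sensor_area_um2 sensor area in um^2
#' @param sensor_length_um sensor length along the flow in um
#' @return transport coefficient in molecules/(M s)
#' @export
leveque_transport_rate <- function(fl, geometry, probe,
                                   sensor_area_um2 = 4e3,
                                   sensor_length_um = 100) {
  u <- fl$volumetric_rate / geometry$area          # m/s
  shear <- 6 * u / geometry$height                  # 1/s
  kc <- 0.81 * (shear * probe$diffusion^2 / (sensor_length_um * 1e-6))^(1 / 3)
  kc * sensor_area_um2 * 1e-12 * 1e3 * AVOGADRO
}
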