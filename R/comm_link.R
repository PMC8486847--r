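# Concentration-encoded binary transmission over the microfluidic link.
# Bit-1 is a finite concentration pulse at the start of its bit interval,
# bit-0 is buffer only; the received current is modelled as the LTI
# superposition of shifted single-pulse responses. The LTI assumption is an
# approximation (binding kinetics are nonlinear in occupancy); the
# sequential-ODE mode quantifies the error it introduces.

#' Current time-series container
#'
#' @param times sample times in s, strictly increasing
#' @param currents currents in uA (or dimensionless when normalised)
#' @param normalised logical; `TRUE` after [normalize_signal()]
#' @return a data.frame of class `fet_trace` with columns `time`, `current`
#' @export
fet_trace <- function(times, currents, normalised = FALSE) {
  if (length(times) != length(currents))
    stop("times and currents must have equal length")
  if (length(times) < 1) stop("trace must be non-empty")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  structure(data.frame(time = as.numeric(times),
                       current = as.numeric(currents)),
            normalised = normalised,
            class = c("fet_trace", "data.frame"))
}

#' Read / write a trace as two-column delimited text
#'
#' Plain whitespace- or comma-delimited text with two columns (time in s,
#' current in uA); lines starting with `#` are comments.
#'
#' @param path file path
#' @return a [fet_trace()] (`read_trace`) or `path`, invisibly
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          sep = "", col.names = c("time", "current"))
  fet_trace(df$time, df$current)
}

#' @rdname read_trace
#' @param trace a [fet_trace()]
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fet_trace"))
  utils::write.table(format(trace[, c("time", "current")], digits = 10,
                            scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' On-off-keyed transmission specification
#'
#' @param bits 0/1 integer vector, or a string such as "10110"
#' @param bit_interval_s bit interval T_b in s
#' @param pulse_width_s concentration pulse width T_p in s
#'   (<= bit_interval_s)
#' @param t_transmit_s transmission start time in s
#' @param on_concentration_M pulse concentration for bit-1, in M
#' @return an object of class `transmission_spec`
#' @examples
#' transmission_spec(prbs(20, seed = 7), bit_interval_s = 360,
#'                   pulse_width_s = 30)
#' @export
transmission_spec <- function(bits, bit_interval_s, pulse_width_s,
                              t_transmit_s = 0, on_concentration_M = 1e-6) {
  if (is.character(bits))
    bits <- as.integer(strsplit(bits, "")[[1]])
  bits <- as.integer(bits)
  if (length(bits) < 1 || !all(bits %in% c(0L, 1L)))
    stop("bits must be a non-empty 0/1 sequence")
  if (pulse_width_s > bit_interval_s)
    stop("pulse width cannot exceed the bit interval")
  if (pulse_width_s <= 0 || bit_interval_s <= 0)
    stop("pulse width and bit interval must be positive")
  structure(list(bits = bits, bit_interval = bit_interval_s,
                 pulse_width = pulse_width_s, t_transmit = t_transmit_s,
                 on_concentration = on_concentration_M),
            class = "transmission_spec")
}

#' Received signal by LTI superposition
#'
#' R(t) = sum_i s[i] dI(t - t_transmit - (i-1) T_b), the sum of shifted
#' copies of the single-pulse response for every transmitted bit-1; bit-0
#' intervals contribute nothing. With `mode = "ode"` the full multi-pulse
#' schedule is integrated by [ode_reference_response()] instead, which
#' retains the occupancy nonlinearity the superposition neglects.
#'
#' @param spec a [transmission_spec()]
#' @param model a [pulse_model()]; its `t_a`/`t_d` are ignored — the
#'   schedule comes from `spec`
#' @param t_grid sorted time grid in s
#' @param mode "lti" (default) or "ode"
#' @return a [fet_trace()] of current changes (uA) on `t_grid`
#' @export
received_signal <- function(spec, model, t_grid, mode = c("lti", "ode")) {
  stopifnot(inherits(spec, "transmission_spec"),
            inherits(model, "pulse_model"))
  mode <- match.arg(mode)
  base <- pulse_model(model$rates, spec$on_concentration, model$k_t,
                      model$response, t_a = 0, t_d = spec$pulse_width)
  if (mode == "ode") {
    on <- spec$t_transmit + (which(spec$bits == 1L) - 1) * spec$bit_interval
    if (length(on) == 0)
      return(fet_trace(t_grid, numeric(length(t_grid))))
    sched <- data.frame(on = on, off = on + spec$pulse_width)
    return(fet_trace(t_grid,
                     ode_reference_response(t_grid, base, schedule = sched)))
  }
  total <- numeric(length(t_grid))
  for (i in which(spec$bits == 1L)) {
    shift <- spec$t_transmit + (i - 1) * spec$bit_interval
    total <- total + pulse_response(pmax(t_grid - shift, 0), base)
  }
  fet_trace(t_grid, total)
}

#' Normalise a current trace by the baseline
#'
#' I_hat(t) = (I_baseline + dI(t)) / I_baseline, so a flat response maps to
#' exactly 1 and an n-doping (current-lowering) response dips below 1.
#' [denormalize_signal()] is the exact inverse.
#'
#' @param trace a [fet_trace()] of current changes (uA)
#' @param baseline_uA baseline current in uA (> 0)
#' @return a dimensionless [fet_trace()]
#' @export
normalize_signal <- function(trace, baseline_uA) {
  stopifnot(inherits(trace, "fet_trace"))
  if (!is.finite(baseline_uA) || baseline_uA <= 0)
    stop("baseline must be strictly positive")
  fet_trace(trace$time, (baseline_uA + trace$current) / baseline_uA,
            normalised = TRUE)
}

#' @rdname normalize_signal
#' @export
denormalize_signal <- function(trace, baseline_uA) {
  stopifnot(inherits(trace, "fet_trace"))
  if (!is.finite(baseline_uA) || baseline_uA <= 0)
    stop("baseline must be strictly positive")
  fet_trace(trace$time, trace$current * baseline_uA - baseline_uA)
}
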