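# Receiver-side processing: low-pass moving-mean filtering, constant-delay
# synchronisation, difference-based decoding, and bit error rate. The
# difference detector compares the current at the start and end of each bit
# interval: hybridisation lowers the drain-source current, so a drop across
# an interval decodes as bit-1. Because only difference signs are used, the
# detector is immune to baseline offset and to any positive rescaling —
# which is why it survives the heavy intersymbol interference that defeats
# constant-threshold detection on this channel.

#' Moving-mean filter
#'
#' Averages over a window of `round(window_s / dt)` samples; shrinking
#' windows are used at the edges, so the output has the same length as the
#' input and a constant trace passes through unchanged.
#'
#' The default centred alignment (window rounded up to an odd sample count)
#' matches offline denoising of a recorded trace, but it is non-causal:
#' near a pulse onset it averages future samples into the present, which
#' on an otherwise perfectly flat noiseless signal can pull a decision
#' sample below its tie value and flip an exact-tie bit. For decoding, the
#' `"trailing"` alignment (window ending at the sample, as any real-time
#' receiver must use) has no such leak-back and preserves noiseless
#' decisions.
#'
#' @param trace a [fet_trace()], uniformly sampled
#' @param window_s window length in seconds (default 21)
#' @param align `"center"` (default) or `"trailing"` (causal)
#' @return the filtered [fet_trace()]
#' @export
moving_mean <- function(trace, window_s = 21,
                        align = c("center", "trailing")) {
  stopifnot(inherits(trace, "fet_trace"))
  align <- match.arg(align)
  if (window_s <= 0) stop("window must be positive")
  dt <- median(diff(trace$time))
  k <- round(window_s / dt)
  if (k <= 1) {
    if (window_s < dt)
      warning("window shorter than the sampling interval; returning input")
    return(trace)
  }
  x <- trace$current
  n <- length(x)
  cs <- cumsum(c(0, x))
  if (align == "center") {
    if (k %% 2 == 0) k <- k + 1
    half <- (k - 1) / 2
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
  } else {
    lo <- pmax(seq_len(n) - k + 1, 1)
    hi <- seq_len(n)
  }
  fet_trace(trace$time, (cs[hi + 1] - cs[lo]) / (hi - lo + 1),
            normalised = isTRUE(attr(trace, "normalised")))
}

#' Sample the decision instants of a bit stream
#'
#' Takes L+1 samples at t_transmit + delay + (i-1) T_b for i = 1..L+1 —
#' both endpoints of every bit interval, shifted by the constant
#' propagation delay — using nearest-grid-point lookup.
#'
#' @param trace a [fet_trace()] covering all decision instants
#' @param spec a [transmission_spec()]
#' @param delay_s constant propagation delay in s (receiver-side
#'   synchronisation; ~55 s for the reference device)
#' @return an object of class `decision_samples` with `$times`, `$values`,
#'   `$delay`
#' @export
sample_decisions <- function(trace, spec, delay_s = 0) {
  stopifnot(inherits(trace, "fet_trace"),
            inherits(spec, "transmission_spec"))
  l <- length(spec$bits)
  want <- spec$t_transmit + delay_s + (seq_len(l + 1) - 1) * spec$bit_interval
  rng <- range(trace$time)
  dt <- median(diff(trace$time))
  if (any(want < rng[1] - dt / 2) || any(want > rng[2] + dt / 2))
    stop("decision instants fall outside the trace")
  idx <- vapply(want, function(w) which.min(abs(trace$time - w)), integer(1))
  structure(list(times = trace$time[idx], values = trace$current[idx],
                 delay = delay_s),
            class = "decision_samples")
}

#' Difference-based bit decoding
#'
#' s_hat[i] = 1 iff r[i+1] - r[i] < 0: a current drop across a bit interval
#' signals binding, hence bit-1. Exact ties decode to 0 (no evidence of
#' binding). Depends only on difference signs, so it is invariant to any
#' strictly positive affine rescaling of the signal.
#'
#' @param samples a `decision_samples` from [sample_decisions()], or a bare
#'   numeric vector of L+1 samples
#' @return integer 0/1 vector of L decoded bits
#' @export
difference_detect <- function(samples) {
  vals <- if (inherits(samples, "decision_samples")) samples$values
          else as.numeric(samples)
  if (length(vals) < 2) stop("need at least two samples to decode")
  as.integer(diff(vals) < 0)
}

#' Bit error rate
#'
#' @param sent transmitted 0/1 bits
#' @param decoded decoded 0/1 bits, same length
#' @return fraction of mismatched bits in `[0, 1]`
#' @export
bit_error_rate <- function(sent, decoded) {
  if (length(sent) != length(decoded))
    stop("bit sequences must have equal length")
  mean(as.integer(sent) != as.integer(decoded))
}

#' Estimate the propagation delay by cross-correlation
#'
#' Slides the noiseless model prediction of the received signal over the
#' measured trace and returns the delay minimising the sum of squared
#' differences (after removing each side's mean). Off by default in the
#' decoding pipeline — the constant delay is normally supplied by the user.
#'
#' @param trace a measured [fet_trace()] of current changes (uA)
#' @param spec a [transmission_spec()]
#' @param model a [pulse_model()]
#' @param delays candidate delays in s
#' @return the best delay in s
#' @export
estimate_delay <- function(trace, spec, model, delays = 0:120) {
  stopifnot(inherits(trace, "fet_trace"))
  score <- vapply(delays, function(d) {
    shifted <- transmission_spec(spec$bits, spec$bit_interval,
                                 spec$pulse_width, spec$t_transmit + d,
                                 spec$on_concentration)
    pred <- received_signal(shifted, model, trace$time)$current
    sum((scale(trace$current, scale = FALSE) -
           scale(pred, scale = FALSE))^2)
  }, numeric(1))
  delays[which.min(score)]
}
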