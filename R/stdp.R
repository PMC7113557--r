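#' Spike timing-dependent plasticity window
#'
#' Parameters of the canonical double-exponential STDP rule. When presynaptic
#' activity repeatedly precedes postsynaptic activity by a few milliseconds the
#' synaptic gain is potentiated (LTP); when the order is reversed it is
#' depressed (LTD); the effect magnitude decays exponentially with the timing
#' offset.
#'
#' @param a_plus potentiation amplitude per pairing (dimensionless gain
#'   increment at zero-plus offset).
#' @param a_minus depression amplitude per pairing.
#' @param tau_plus_ms decay constant of the potentiation branch (ms).
#' @param tau_minus_ms decay constant of the depression branch (ms).
#' @param effect_floor magnitude below which the predicted per-pair effect is
#'   classified as "none" by [predict_effect()].
#' @return an object of class `stdp_window`.
#' @seealso [stdp_delta()], [predict_effect()]
#' @export
stdp_window <- function(a_plus = 1e-4, a_minus = 1e-4,
                        tau_plus_ms = 20, tau_minus_ms = 20,
                        effect_floor = 1e-6) {
  stopifnot(is.numeric(a_plus), length(a_plus) == 1L, a_plus >= 0,
            is.numeric(a_minus), length(a_minus) == 1L, a_minus >= 0,
            is.numeric(tau_plus_ms), length(tau_plus_ms) == 1L, tau_plus_ms > 0,
            is.numeric(tau_minus_ms), length(tau_minus_ms) == 1L, tau_minus_ms > 0,
            is.numeric(effect_floor), length(effect_floor) == 1L, effect_floor >= 0)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus_ms = tau_plus_ms, tau_minus_ms = tau_minus_ms,
                 effect_floor = effect_floor),
            class = "stdp_window")
}

#' @export
print.stdp_window <- function(x, ...) {
  cat(sprintf("STDP window: A+ = %g (tau+ = %g ms), A- = %g (tau- = %g ms), floor = %g\n",
              x$a_plus, x$tau_plus_ms, x$a_minus, x$tau_minus_ms, x$effect_floor))
  invisible(x)
}

#' Per-pairing synaptic gain change under an STDP rule
#'
#' Evaluates the double-exponential STDP rule at a signed timing offset.
#' `dt_ms > 0` means the presynaptic volley arrived before the postsynaptic
#' one (pre-before-post), yielding `a_plus * exp(-dt/tau_plus)`; `dt_ms < 0`
#' yields `-a_minus * exp(dt/tau_minus)`. The rule is discontinuous at zero in
#' general; `dt_ms == 0` returns 0 by convention (simultaneous arrival is
#' treated as producing no consistent order).
#'
#' @param dt_ms signed timing offset(s) in ms, positive when the presynaptic
#'   volley leads. Vectorized.
#' @param window an [stdp_window()].
#' @return signed gain change(s), bounded in magnitude by
#'   `max(a_plus, a_minus)`.
#' @export
#' @examples
#' w <- stdp_window(a_plus = 0.01, tau_plus_ms = 20)
#' stdp_delta(10, w)  # 0.01 * exp(-0.5)
stdp_delta <- function(dt_ms, window) {
  stopifnot(inherits(window, "stdp_window"), is.numeric(dt_ms), all(is.finite(dt_ms)))
  out <- numeric(length(dt_ms))
  pos <- dt_ms > 0
  neg <- dt_ms < 0
  out[pos] <- window$a_plus * exp(-dt_ms[pos] / window$tau_plus_ms)
  out[neg] <- -window$a_minus * exp(dt_ms[neg] / window$tau_minus_ms)
  out
}
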