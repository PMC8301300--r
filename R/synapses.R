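# Short-term depression (STD) and postsynaptic waveform kernels.
#
# Each presynaptic neuron carries one resource fraction x in [0, 1] (all of
# its outgoing synapses share the axonal pool).  Between spikes x relaxes to
# 1 with time constant tau_rec:  dx/dt = (1 - x)/tau_rec.  At a presynaptic
# spike a constant portion U of the current resources is released,
# x <- (1 - U) x, and the released amount U*x (sampled before depletion)
# scales the postsynaptic waveform: excitatory synapses inject a square
# pulse of width t_max and peak V0d * U * x; inhibitory synapses inject a
# jump to V0h * U * x followed by exponential decay with constant tau2.

#' STD resource recovery between spikes
#'
#' Closed form of `dx/dt = (1 - x)/tau_rec` over an interval `dt` with no
#' presynaptic spikes: `1 - (1 - x0) * exp(-dt/tau_rec)`.  `tau_rec = 0` is
#' the static (no-depression) limit in which resources recover instantly.
#'
#' @param x0 Resource fraction(s) in \[0, 1\] at the start of the interval.
#' @param dt Interval length, ms (> 0).
#' @param tau_rec Recovery time constant, ms (>= 0).
#' @return Resource fraction(s) after `dt`.
#' @export
std_recover <- function(x0, dt, tau_rec) {
  stopifnot(all(x0 >= 0 & x0 <= 1))
  if (any(dt < 0)) stop("dt must be >= 0")
  if (tau_rec < 0) stop("tau_rec must be >= 0")
  if (tau_rec == 0) return(rep(1, length(x0)) + 0 * x0)
  1 - (1 - x0) * exp(-dt / tau_rec)
}

#' Resource release at a presynaptic spike
#'
#' A fixed portion `U` of the available resources is released; the released
#' amount (which scales the postsynaptic amplitude) is `U * x` with `x`
#' sampled before depletion, and the synapse is left with `(1 - U) * x`.
#'
#' @param x Resource fraction(s) in \[0, 1\] at the spike instant.
#' @param U Release probability in (0, 1\].
#' @return List with `released` (`U * x`) and `x_after` (`(1 - U) * x`).
#' @export
std_on_spike <- function(x, U) {
  stopifnot(all(x >= 0 & x <= 1), U > 0, U <= 1)
  list(released = U * x, x_after = (1 - U) * x)
}

#' Excitatory postsynaptic waveform (square pulse)
#'
#' Depression-scaled EPSP: `V0d * released` for
#' `0 <= t_since_spike < t_max`, zero afterwards (half-open pulse).
#'
#' @param t_since_spike Time since the presynaptic spike, ms (>= 0).
#' @param released Released resource amount `U * x` at the spike.
#' @param V0d Maximal excitatory amplitude, mV (> 0).
#' @param t_max Pulse width, ms.
#' @return Contribution in mV (>= 0).
#' @export
epsp_contribution <- function(t_since_spike, released, V0d, t_max) {
  stopifnot(all(t_since_spike >= 0))
  ifelse(t_since_spike < t_max, V0d * released, 0)
}

#' Inhibitory postsynaptic waveform (exponential decay)
#'
#' Depression-scaled IPSP: `V0h * released * exp(-t_since_spike/tau2)`,
#' always <= 0 since `V0h < 0`.
#'
#' @param t_since_spike Time since the presynaptic spike, ms (>= 0).
#' @param released Released resource amount `U * x` at the spike.
#' @param V0h Maximal inhibitory amplitude, mV (< 0).
#' @param tau2 Decay time constant, ms (> 0).
#' @return Contribution in mV (<= 0).
#' @export
ipsp_contribution <- function(t_since_spike, released, V0h, tau2) {
  stopifnot(all(t_since_spike >= 0))
  V0h * released * exp(-t_since_spike / tau2)
}

#' Steady-state resource fraction under periodic driving
#'
#' Fixed point of recovery over an inter-spike interval `T` followed by
#' release: `x* = (1 - exp(-T/tau_rec)) / (1 - (1 - U) exp(-T/tau_rec))`
#' (value just before each spike).
#'
#' @param T Inter-spike interval, ms.
#' @param U Release probability.
#' @param tau_rec Recovery time constant, ms; 0 gives `x* = 1`.
#' @return Steady-state pre-spike resource fraction.
#' @export
std_steady_state <- function(T, U, tau_rec) {
  if (tau_rec == 0) return(1)
  e <- exp(-T / tau_rec)
  (1 - e) / (1 - (1 - U) * e)
}

# ---- streaming waveform accumulators (reference implementation) ----------
#
# The compiled engine keeps, per postsynaptic neuron, one additive
# accumulator for active square pulses (with scheduled expiries) and one
# exponentially decaying accumulator for IPSPs.  The functions below are the
# engine-independent reference used by the tests: they maintain the same
# state for a single postsynaptic neuron, one step at a time.

#' Initialise empty synaptic accumulators
#'
#' @return A list with `epsp_active` (mV, sum of live square pulses),
#'   `ipsp_active` (mV, decaying inhibitory sum) and `pending` (data frame
#'   of live pulses with their remaining time).
#' @export
synaptic_state <- function() {
  list(epsp_active = 0, ipsp_active = 0,
       pending = data.frame(amplitude = numeric(0), t_left = numeric(0)))
}

#' Advance the synaptic accumulators one engine step
#'
#' Decays the IPSP accumulator by `exp(-dt/tau2)` and expires square pulses
#' whose remaining lifetime has elapsed; overlapping waveforms superpose
#' additively.
#'
#' @param state A list from [synaptic_state()].
#' @param dt Step size, ms (the engine step).
#' @param params List with at least `tau2` (ms).
#' @return Updated state.
#' @export
advance_accumulators <- function(state, dt, params) {
  state$ipsp_active <- state$ipsp_active * exp(-dt / params$tau2)
  if (nrow(state$pending)) {
    state$pending$t_left <- state$pending$t_left - dt
    dead <- state$pending$t_left <= 0
    state$epsp_active <- state$epsp_active - sum(state$pending$amplitude[dead])
    state$pending <- state$pending[!dead, , drop = FALSE]
  }
  state
}

#' Deposit a spike's waveform onto the accumulators
#'
#' @param state A list from [synaptic_state()].
#' @param released Released resource amount `U * x` at the spike.
#' @param type `"E"` (square pulse, amplitude `V0d * released`, width
#'   `t_max`) or `"I"` (jump `V0h * released`, decays under
#'   [advance_accumulators()]).
#' @param params List with `V0d`, `V0h`, `t_max`.
#' @return Updated state.
#' @export
add_waveform <- function(state, released, type = c("E", "I"), params) {
  type <- match.arg(type)
  if (type == "E") {
    amp <- params$V0d * released
    state$epsp_active <- state$epsp_active + amp
    state$pending <- rbind(state$pending,
                           data.frame(amplitude = amp, t_left = params$t_max))
  } else {
    state$ipsp_active <- state$ipsp_active + params$V0h * released
  }
  state
}
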