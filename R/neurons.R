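# Membrane-potential kernels: leaky integrator with asymmetric relaxation,
# saturation gating of the inputs, and a dynamic firing threshold encoding
# absolute and relative refractoriness.
#
# The membrane obeys tau(V) dV/dt = -V + Vin + Vnoise, with tau = tau1 above
# the resting potential (0 mV) and tau2_mem below it.  Inputs are gated by
# (Vsat - V)/Vsat (excitatory, incl. noise) and (Vmin - V)/Vmin
# (inhibitory) so V can never leave [Vmin, Vsat].  After a spike at tf the
# threshold sits at Vsat for the absolute refractory period ta, then decays
# exponentially back to Vth0 at rate kappa.

#' Membrane relaxation time constant
#'
#' `tau1` when the membrane is at or above the resting potential (0 mV),
#' `tau2_mem` below it (ties resolve to `tau1`).
#'
#' @param V Membrane potential(s), mV.
#' @param params List with `tau1`, `tau2_mem` (ms).
#' @return Time constant(s), ms.
#' @export
membrane_tau <- function(V, params)
  ifelse(V >= 0, params$tau1, params$tau2_mem)

#' Saturation-gated synaptic input
#'
#' Excitatory input (synaptic plus external noise) is scaled by
#' `(Vsat - V)/Vsat` and inhibitory input by `(Vmin - V)/Vmin`, so the
#' drive vanishes as V approaches either physiological limit.
#'
#' @param V Membrane potential, mV.
#' @param exc_sum Summed excitatory synaptic input, mV (>= 0).
#' @param inh_sum Summed inhibitory synaptic input, mV (<= 0).
#' @param noise_sum Summed external noise input, mV (>= 0).
#' @param params List with `Vsat`, `Vmin` (mV).
#' @return Gated total input, mV.
#' @export
gated_input <- function(V, exc_sum, inh_sum, noise_sum, params) {
  (params$Vsat - V) / params$Vsat * (exc_sum + noise_sum) +
    (params$Vmin - V) / params$Vmin * inh_sum
}

#' One forward-Euler membrane step
#'
#' Advances `dV = dt * (-V + gated_in) / tau(V)` and clamps the result to
#' `[Vmin, Vsat]`.
#'
#' @param V Membrane potential, mV.
#' @param gated_in Gated total input from [gated_input()], mV.
#' @param dt Step size, ms (must be well below `min(tau1, tau2_mem)`).
#' @param params List with `tau1`, `tau2_mem`, `Vsat`, `Vmin`.
#' @return Updated membrane potential, mV.
#' @export
membrane_step <- function(V, gated_in, dt, params) {
  V2 <- V + dt * (gated_in - V) / membrane_tau(V, params)
  pmin(pmax(V2, params$Vmin), params$Vsat)
}

#' Dynamic firing threshold
#'
#' `Vth0` for a neuron that has never fired; `Vsat` during the absolute
#' refractory period `(tf, tf + ta]`; afterwards
#' `Vth0 + (Vsat - Vth0) * exp(-kappa * (t - tf - ta))` (relative
#' refractoriness).
#'
#' @param t Current time, ms.
#' @param t_last_spike Time of the neuron's last spike, ms, or `-Inf` /
#'   `NA` for "never fired".
#' @param params List with `Vth0`, `Vsat`, `ta` (ms), `kappa` (1/ms).
#' @return Threshold, mV.
#' @export
threshold_at <- function(t, t_last_spike, params) {
  if (is.na(t_last_spike) || !is.finite(t_last_spike)) return(params$Vth0)
  dt_sp <- t - t_last_spike
  if (dt_sp < 0) stop("t must be >= t_last_spike")
  if (dt_sp <= params$ta) return(params$Vsat)
  params$Vth0 + (params$Vsat - params$Vth0) *
    exp(-params$kappa * (dt_sp - params$ta))
}

#' Spike detection against the dynamic threshold
#'
#' A spike is emitted when `V >= Vth(t)` outside the absolute refractory
#' period; within `ta` of the previous spike no spike is possible (the
#' threshold sits at the saturation level the clamp cannot strictly
#' exceed).
#'
#' @param V Membrane potential after the step, mV.
#' @param t Current time, ms.
#' @param t_last_spike Last spike time, ms (`-Inf`/`NA` for never).
#' @param params List with `Vth0`, `Vsat`, `ta`, `kappa`.
#' @return Logical: did the neuron fire this step?
#' @export
detect_spike <- function(V, t, t_last_spike, params) {
  if (is.finite(t_last_spike) && !is.na(t_last_spike) &&
      (t - t_last_spike) <= params$ta)
    return(FALSE)
  V >= threshold_at(t, t_last_spike, params)
}
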