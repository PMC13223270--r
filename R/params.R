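#' Ion-channel parameters for the regular-spiking cortical neuron model
#'
#' Parameters of the fast sodium, delayed-rectifier potassium and slow
#' non-inactivating potassium (M-type) currents. The Na/K kinetics follow the
#' Traub-style formulation for regular-spiking cortical cells, with all rate
#' functions shifted by the threshold parameter `V_T`; the M-current gate `p`
#' relaxes towards a sigmoidal steady state `p_inf(V)` with a bell-shaped
#' voltage-dependent time constant scaled by `tau_max`. The M-current provides
#' spike-frequency adaptation: during prolonged silence `p` decays, lowering
#' the adaptation current and priming the cell for burst discharge.
#'
#' @param g_Na,g_K,g_M maximal conductances (mS/cm^2)
#' @param E_Na,E_K reversal potentials (mV)
#' @param tau_max M-current time-constant scale (ms)
#' @param V_T threshold-shift applied to the Na/K rate functions (mV)
#' @return an object of class `channel_params`
#' @export
channel_params <- function(g_Na = 56, g_K = 6, g_M = 0.09,
                           E_Na = 50, E_K = -90,
                           tau_max = 1000, V_T = -56.2) {
  check_positive(g_Na, "g_Na", strict = FALSE)
  check_positive(g_K, "g_K", strict = FALSE)
  check_positive(g_M, "g_M", strict = FALSE)
  check_positive(tau_max, "tau_max")
  out <- list(g_Na = g_Na, g_K = g_K, g_M = g_M, E_Na = E_Na, E_K = E_K,
              tau_max = tau_max, V_T = V_T)
  class(out) <- "channel_params"
  out
}

#' Model parameters for the conductance-based network
#'
#' Collects every parameter of the membrane equation
#' `C dV/dt = -g_leak (V - E_leak) + I_Na + I_K + I_M + I_ext + I_sup + I_syn`,
#' where all ionic currents are written in driving-force form
#' `g * gate * (E - V)` and the synaptic drive onto neuron i is
#' `sum_j (V_rev(j) - V_i) g_j M_ij`. Each outgoing conductance `g_j` decays
#' exponentially with time constant `tau_s` and jumps by `g_syn` (excitatory
#' cells) or `inh_weight_factor * g_syn` (inhibitory cells) whenever neuron j
#' crosses `spike_threshold` upward.
#'
#' Internally the model uses one coherent unit system: mV, ms, uF/cm^2 and
#' mS/cm^2, with currents as the matching densities (uA/cm^2). User-facing
#' currents (`I_ext`, and the controller amplitude) are given in pA and
#' converted through the single factor `current_scale` (uA/cm^2 per pA);
#' `g_syn` is given in uS/cm^2. The default `current_scale` was fixed once so
#' that the desynchronized-to-burst transition of the standard 1000-neuron
#' random network occurs near `g_syn` of 1.8 uS/cm^2.
#'
#' @param g_syn synaptic coupling strength (uS/cm^2)
#' @param C membrane capacitance (uF/cm^2)
#' @param g_leak leak conductance (mS/cm^2)
#' @param E_leak resting potential (mV)
#' @param I_ext constant external drive, applied to every neuron (pA)
#' @param current_scale conversion from pA to uA/cm^2
#' @param inh_weight_factor multiplier for inhibitory conductance jumps
#' @param tau_s synaptic decay time constant (ms)
#' @param V_rev_exc,V_rev_inh synaptic reversal potentials (mV)
#' @param channel a [channel_params()] object
#' @param spike_threshold spike-detection voltage (mV)
#' @param lockout minimum separation between detected spikes of one neuron (ms)
#' @param guard integration-failure guard on `|V|` (mV)
#' @param init_v_range range of the seeded uniform initial voltages (mV)
#' @return an object of class `model_params`
#' @export
model_params <- function(g_syn = 1.8, C = 1, g_leak = 0.01, E_leak = -85,
                         I_ext = 175, current_scale = 0.008,
                         inh_weight_factor = 4, tau_s = 5.7,
                         V_rev_exc = 0, V_rev_inh = -80,
                         channel = channel_params(),
                         spike_threshold = 0, lockout = 1, guard = 500,
                         init_v_range = c(E_leak, spike_threshold - 20)) {
  check_positive(C, "C")
  check_positive(tau_s, "tau_s")
  check_positive(g_syn, "g_syn", strict = FALSE)
  check_positive(lockout, "lockout", strict = FALSE)
  if (!inherits(channel, "channel_params"))
    stop_param("`channel` must be a channel_params object")
  if (V_rev_inh >= V_rev_exc)
    stop_param("V_rev_inh must be below V_rev_exc")
  if (length(init_v_range) != 2L || init_v_range[1] > init_v_range[2])
    stop_param("`init_v_range` must be an increasing length-2 range")
  out <- list(g_syn = g_syn, C = C, g_leak = g_leak, E_leak = E_leak,
              I_ext = I_ext, current_scale = current_scale,
              inh_weight_factor = inh_weight_factor, tau_s = tau_s,
              V_rev_exc = V_rev_exc, V_rev_inh = V_rev_inh,
              channel = channel, spike_threshold = spike_threshold,
              lockout = lockout, guard = guard, init_v_range = init_v_range)
  class(out) <- "model_params"
  out
}

#' @export
print.model_params <- function(x, ...) {
  cat("Conductance-based network model parameters\n")
  cat(sprintf("  g_syn = %g uS/cm^2 (inhibitory jump x%g), tau_s = %g ms\n",
              x$g_syn, x$inh_weight_factor, x$tau_s))
  cat(sprintf("  C = %g uF/cm^2, g_leak = %g mS/cm^2, E_leak = %g mV\n",
              x$C, x$g_leak, x$E_leak))
  cat(sprintf("  I_ext = %g pA (current_scale %g uA/cm^2 per pA)\n",
              x$I_ext, x$current_scale))
  ch <- x$channel
  cat(sprintf("  channels: g_Na = %g, g_K = %g, g_M = %g mS/cm^2, tau_max = %g ms\n",
              ch$g_Na, ch$g_K, ch$g_M, ch$tau_max))
  invisible(x)
}

# flatten params to the scalar list the C++ core expects
internal_params <- function(params) {
  ch <- params$channel
  list(C = params$C, g_leak = params$g_leak, E_leak = params$E_leak,
       g_Na = ch$g_Na, E_Na = ch$E_Na, g_K = ch$g_K, E_K = ch$E_K,
       g_M = ch$g_M, V_T = ch$V_T, tau_max = ch$tau_max,
       tau_s = params$tau_s,
       V_rev_exc = params$V_rev_exc, V_rev_inh = params$V_rev_inh,
       spike_threshold = params$spike_threshold, lockout = params$lockout,
       guard = params$guard,
       I_ext_internal = params$I_ext * params$current_scale,
       g_jump_exc = params$g_syn * 1e-3,
       g_jump_inh = params$inh_weight_factor * params$g_syn * 1e-3,
       init_v_lo = params$init_v_range[1], init_v_hi = params$init_v_range[2])
}

#' Synaptic conductance after an elapsed decay interval
#'
#' Closed form of the synaptic decay `dg/dt = -g / tau_s`:
#' `g(elapsed) = g0 * exp(-elapsed / tau_s)`.
#'
#' @param g0 conductance at the start of the interval
#' @param elapsed elapsed time (ms, non-negative)
#' @param tau_s decay constant (ms)
#' @return the decayed conductance
#' @export
synaptic_conductance_at <- function(g0, elapsed, tau_s) {
  if (any(elapsed < 0)) stop_param("`elapsed` must be non-negative")
  check_positive(tau_s, "tau_s")
  g0 * exp(-elapsed / tau_s)
}
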