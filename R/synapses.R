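#' Time of peak of the difference-of-exponentials conductance
#'
#' For a synapse with rise constant `tau_rise` and decay constant
#' `tau_decay`, the normalised conductance peaks at
#' `t_peak = (tau_rise tau_decay / (tau_decay - tau_rise)) *
#' log(tau_decay / tau_rise)` after the conductance onset (spike time plus
#' conduction delay).
#'
#' @param spec a [synapse_spec()]
#' @return peak time (ms) measured from conductance onset
#' @export
syn_peak_time <- function(spec) {
  with(spec, tau_rise * tau_decay / (tau_decay - tau_rise) *
         log(tau_decay / tau_rise))
}

# Peak value of exp(-t/tau_decay) - exp(-t/tau_rise); its reciprocal is the
# amplitude normalisation factor that makes the conductance max exactly 1.
syn_norm_factor <- function(tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Normalised synaptic conductance waveform
#'
#' Delayed difference-of-exponentials conductance: zero before
#' `t_spike + t_conduct` (causality), rising with `tau_rise`, decaying with
#' `tau_decay`, normalised so the maximum is exactly 1.
#'
#' @param t evaluation time(s) (ms)
#' @param spec a [synapse_spec()]
#' @param t_spike presynaptic spike time (ms)
#' @return normalised conductance value(s) in `[0, 1]`
#' @examples
#' sp <- synapse_spec(0.5, 2)
#' alpha_conductance(sp$t_conduct + syn_peak_time(sp), sp, 0)  # 1
#' @export
alpha_conductance <- function(t, spec, t_spike = 0) {
  dt <- t - t_spike - spec$t_conduct
  f <- syn_norm_factor(spec$tau_rise, spec$tau_decay)
  s <- f * (exp(-dt / spec$tau_decay) - exp(-dt / spec$tau_rise))
  s[dt < 0] <- 0
  s
}

#' Voltage-dependent magnesium block factor
#'
#' `G(v) = 1 / (1 + exp(-a v) [Mg]_out / b)`, the sigmoidal relief of the
#' NMDA-receptor magnesium block with depolarisation.  Strictly increasing
#' in `v`; equal to 1 at all voltages when `mg_out = 0`.
#'
#' @param v membrane potential (mV)
#' @param p an [mg_block_params()]
#' @return blockade factor in (0, 1]
#' @examples
#' mg_block(0, mg_block_params())  # 1 / (1 + 1.3 / 3.57)
#' @export
mg_block <- function(v, p = mg_block_params()) {
  1 / (1 + exp(-p$a * v) * p$mg_out / p$b)
}

#' Synaptic current
#'
#' `I = A * g_max * s * (v - E_rev)`, multiplied by the magnesium block
#' factor `G` for NMDA synapses.  Sign convention: positive current is
#' outward, so an excitatory synapse below its reversal potential yields a
#' negative (inward) current.  The integrators subtract this current scaled
#' by the membrane resistance, so inward current depolarises.
#'
#' @param v membrane potential (mV)
#' @param spec a [synapse_spec()]
#' @param s normalised conductance (from [alpha_conductance()])
#' @param A short-term depression amplitude factor in (0, 1]
#' @param G optional magnesium block factor (NMDA); default 1
#' @return current (pA)
#' @export
syn_current <- function(v, spec, s, A = 1, G = 1) {
  stopifnot(all(s >= 0), all(A > 0), all(A <= 1))
  A * G * spec$g_max * s * (v - spec$E_rev)
}

#' Conductance trace of a stimulus train on a regular time grid
#'
#' Linear superposition of difference-of-exponentials waveforms, one per
#' presynaptic event, each scaled by the depression amplitude frozen at its
#' event time.  Returned in units of `g_max` (i.e. a single undepressed
#' event peaks at 1).
#'
#' @param times time grid (ms)
#' @param spec a [synapse_spec()]
#' @param event_times presynaptic event times (ms)
#' @param amplitudes per-event depression factors; default all 1
#' @return numeric vector of normalised conductance on `times`
#' @export
conductance_train <- function(times, spec, event_times,
                              amplitudes = rep(1, length(event_times))) {
  stopifnot(length(event_times) == length(amplitudes))
  g <- numeric(length(times))
  for (k in seq_along(event_times)) {
    g <- g + amplitudes[k] * alpha_conductance(times, spec, event_times[k])
  }
  g
}
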