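#' Graded inhibitory synapse description
#'
#' Synaptic conductance `gsyn = gbar_syn * s`, with the activation `s` a
#' logistic function of the presynaptic voltage,
#' `s_inf = 1 / (1 + exp(-(Vpre - Vthresh)/vscale))`. A time constant of 0
#' means instantaneous activation (AB, PY); a positive `tau_syn` gives
#' first-order relaxation `tau_syn * ds/dt = s_inf - s` (PD, 50 ms).
#'
#' @param gbar_syn maximal conductance, uS (>= 0)
#' @param erev reversal potential, mV (-70 for AB/PY, -80 for PD)
#' @param vthresh synaptic threshold, mV
#' @param vscale voltage sensitivity, mV (> 0)
#' @param tau_syn activation time constant, ms (>= 0; 0 = instantaneous)
#' @param target_split named fractions per target compartment, summing to 1
#' @return a `synapse_spec` list
#' @export
synapseSpec <- function(gbar_syn, erev = -70, vthresh = -55, vscale = 5,
                        tau_syn = 0,
                        target_split = c(secondary = 0.4048, tertiary = 0.5952)) {
  if (gbar_syn < 0) stop("gbar_syn must be >= 0")
  if (vscale <= 0) stop("vscale must be positive")
  if (tau_syn < 0) stop("tau_syn must be >= 0")
  if (any(target_split < 0) || any(target_split > 1) ||
      abs(sum(target_split) - 1) > 1e-8)
    stop("target_split fractions must lie in [0,1] and sum to 1")
  structure(list(gbar_syn = gbar_syn, erev = erev, vthresh = vthresh,
                 vscale = vscale, tau_syn = tau_syn,
                 target_split = target_split), class = "synapse_spec")
}

#' Steady-state synaptic activation
#'
#' @param vpre presynaptic voltage, mV
#' @param vthresh threshold, mV
#' @param vscale sensitivity, mV (> 0)
#' @return activation fraction in (0, 1), monotone increasing in `vpre`
#' @export
synapticActivation <- function(vpre, vthresh = -55, vscale = 5) {
  if (vscale <= 0) stop("vscale must be positive")
  1 / (1 + exp(-(vpre - vthresh) / vscale))
}

#' Advance the synaptic activation by one step
#'
#' Exponential-integrator update toward `s_inf(vpre)`; unconditionally keeps
#' `s` in \[0, 1\]. With `tau_syn = 0` the update is instantaneous.
#'
#' @param spec a [synapseSpec()]
#' @param s current activation in \[0, 1\]
#' @param vpre presynaptic voltage, mV
#' @param dt step, ms (> 0)
#' @return updated activation
#' @export
stepSynapse <- function(spec, s, vpre, dt) {
  stopifnot(inherits(spec, "synapse_spec"), dt > 0, s >= 0, s <= 1)
  sinf <- synapticActivation(vpre, spec$vthresh, spec$vscale)
  if (spec$tau_syn == 0) return(sinf)
  sinf + (s - sinf) * exp(-dt / spec$tau_syn)
}

#' Synaptic current onto the postsynaptic compartment
#'
#' `I = gbar_syn * s * (Vpost - Erev)`; positive = outward, i.e.
#' hyperpolarizing when the membrane sits above the reversal potential.
#'
#' @param spec a [synapseSpec()]
#' @param s activation fraction in \[0, 1\]
#' @param v_post postsynaptic voltage, mV
#' @return current in nA
#' @export
synapticCurrent <- function(spec, s, v_post) {
  stopifnot(inherits(spec, "synapse_spec"))
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  spec$gbar_syn * s * (v_post - spec$erev)
}
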