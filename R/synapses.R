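#' Conductance-based synapse specification
#'
#' Chemical synapses are bi-exponential conductances
#' \eqn{g(t) = g_{max} (e^{-t/\tau_d} - e^{-t/\tau_r}) / N} normalized so a
#' single presynaptic spike reaches a peak conductance of exactly `g_max`.
#' Receptor classes follow the model's receptor complement: AMPA and
#' nicotinic (reversal 0 mV) for excitation, fast and slow GABA_A
#' (reversal -75 mV) for perisomatic and dendritic inhibition.
#'
#' @param kind `"AMPA"`, `"nicotinic"`, `"GABA_fast"` or `"GABA_slow"`
#'   (the two GABA classes are both GABA_A receptors with different
#'   kinetics), or a custom kind if all constants are supplied.
#' @param g_max peak conductance, uS.
#' @param tau_rise,tau_decay kinetic time constants, ms
#'   (`0 < tau_rise < tau_decay`); defaults from the class table.
#' @param reversal synaptic reversal potential, mV.
#' @param delay axonal plus synaptic delay, ms.
#' @param target_compartment label of the postsynaptic compartment.
#' @return object of class `synapse_spec`.
#' @export
synapse_spec <- function(kind = "AMPA", g_max = 1e-3, tau_rise = NULL,
                         tau_decay = NULL, reversal = NULL, delay = 1,
                         target_compartment = "soma") {
  defs <- ca1_defaults()$synapses
  if (kind %in% names(defs)) {
    d <- defs[[kind]]
    if (is.null(tau_rise)) tau_rise <- d$tau_rise
    if (is.null(tau_decay)) tau_decay <- d$tau_decay
    if (is.null(reversal)) reversal <- d$reversal
  }
  stopifnot(tau_rise > 0, tau_rise < tau_decay, delay >= 0, g_max >= 0)
  structure(list(kind = kind, g_max = g_max, tau_rise = tau_rise,
                 tau_decay = tau_decay, reversal = reversal, delay = delay,
                 target_compartment = target_compartment),
            class = "synapse_spec")
}

#' Empty synapse state
#' @param spec a `synapse_spec`.
#' @return object of class `synapse_state` holding the pending spike queue.
#' @export
init_synapse_state <- function(spec) {
  structure(list(spec = spec, spike_times = numeric(0)),
            class = "synapse_state")
}

#' Register a presynaptic spike
#'
#' Enqueues a conductance onset at `t + delay`.  Kinetics are linear, so
#' responses to successive spikes superpose.
#'
#' @param state a `synapse_state`.
#' @param t presynaptic spike time, ms.
#' @return updated `synapse_state`.
#' @export
on_presynaptic_spike <- function(state, t) {
  state$spike_times <- c(state$spike_times, t)
  state
}

# normalization constant: value of the double exponential at its peak
biexp_norm <- function(tr, td) {
  tp <- tr * td / (td - tr) * log(td / tr)
  exp(-tp / td) - exp(-tp / tr)
}

#' Time of peak conductance after a single spike
#' @param spec a `synapse_spec`.
#' @return ms after conductance onset (spike time + delay).
#' @export
psc_peak_time <- function(spec) {
  with(spec, tau_rise * tau_decay / (tau_decay - tau_rise) *
         log(tau_decay / tau_rise))
}

#' Synaptic conductance at time t
#' @param state a `synapse_state` (with registered spikes).
#' @param t evaluation time, ms.
#' @return conductance, uS.
#' @export
synaptic_conductance <- function(state, t) {
  sp <- state$spec
  on <- state$spike_times + sp$delay
  on <- on[on <= t]
  if (length(on) == 0) return(0)
  dtv <- t - on
  sp$g_max * sum(exp(-dtv / sp$tau_decay) - exp(-dtv / sp$tau_rise)) /
    biexp_norm(sp$tau_rise, sp$tau_decay)
}

#' Synaptic current
#'
#' Current convention: `I = g(t) * (V_post - reversal)` is the outward
#' membrane current through the receptor, so positive values hyperpolarize
#' the postsynaptic compartment.  This matches the membrane equation used by
#' [membrane_step()], where injected (inward) currents enter with the
#' opposite sign.
#'
#' @param spec a `synapse_spec` (used for documentation symmetry; kinetics
#'   live in `state$spec`).
#' @param state a `synapse_state` advanced to `t`.
#' @param V_post postsynaptic membrane potential, mV.
#' @param t time, ms.
#' @return current, nA (outward positive).
#' @export
synaptic_current <- function(spec, state, V_post, t) {
  g <- synaptic_conductance(state, t)
  g * (V_post - state$spec$reversal)
}

#' Gap junction specification
#'
#' Electrical coupling between cells of the same population (the model uses
#' them within PV basket and within neurogliaform populations).
#'
#' @param cell_pair integer pair of cell indices.
#' @param g_gap coupling conductance, uS (>= 0).
#' @param population population name (`"pvbas"` or `"ngf"`).
#' @param compartments pair of compartment labels.
#' @return object of class `gap_junction_spec`.
#' @export
gap_junction_spec <- function(cell_pair, g_gap, population = "pvbas",
                              compartments = c("soma", "soma")) {
  stopifnot(g_gap >= 0, length(cell_pair) == 2)
  if (!population %in% c("pvbas", "ngf"))
    stop("gap junctions are restricted to pvbas or ngf populations")
  structure(list(cell_pair = cell_pair, g_gap = g_gap,
                 population = population, compartments = compartments),
            class = "gap_junction_spec")
}

#' Gap junction currents
#'
#' Ohmic electrical coupling: `I_i = g_gap * (V_j - V_i)` flows into cell i,
#' and the pair conserves charge exactly (`I_i + I_j = 0`).
#'
#' @param V_i,V_j membrane potentials of the coupled compartments, mV.
#' @param spec a `gap_junction_spec`.
#' @return numeric length-2 vector `c(I_i, I_j)` in nA (inward positive).
#' @export
gap_junction_currents <- function(V_i, V_j, spec) {
  I <- spec$g_gap * (V_j - V_i)
  c(I, -I)
}
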