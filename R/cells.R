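#' Cell model construction
#'
#' Builds the reduced-compartment Hodgkin-Huxley specification for one of the
#' nine CA1 cell types.  Pyramidal cells are five compartments along the
#' somato-dendritic axis (basal, soma, proximal/distal radiatum,
#' lacunosum-moleculare) so that laminar membrane currents are separable for
#' the LFP forward model; interneurons are single-compartment.  Regular
#' spiking types use Traub-type Na/K kinetics with a muscarinic-sensitive
#' K current for adaptation on pyramidal somata; the fast-spiking types
#' (`pvbas`, `aac`) use Wang-Buzsaki kinetics; `olm` carries an H current.
#'
#' @param cell_type one of `"pyr"`, `"pvbas"`, `"olm"`, `"cckbas"`, `"ivy"`,
#'   `"ngf"`, `"bis"`, `"aac"`, `"sca"`.
#' @param overrides named list merged over the cell's entry in the default
#'   parameter table (e.g. `list(spike_threshold = -20)` or nested
#'   compartment/channel values).
#' @param position place coordinate of the cell on the normalized track.
#' @return object of class `cell_spec`.
#' @examples
#' pyr <- build_cell("pyr")
#' sapply(pyr$compartments, `[[`, "label")
#' @export
build_cell <- function(cell_type, overrides = NULL, position = 0.5) {
  cells <- ca1_defaults()$cells
  if (!is.character(cell_type) || length(cell_type) != 1 ||
      !cell_type %in% names(cells)) {
    stop("unknown cell_type '", paste(cell_type, collapse = ","),
         "'; valid types: ", paste(names(cells), collapse = ", "))
  }
  spec <- cells[[cell_type]]
  if (!is.null(overrides)) spec <- merge_params(spec, overrides)
  out <- list(cell_type = cell_type,
              compartments = spec$compartments,
              spike_threshold = spec$spike_threshold,
              position = position)
  class(out) <- "cell_spec"
  validate_cell_spec(out)
  out
}

validate_cell_spec <- function(spec) {
  for (cmp in spec$compartments) {
    if (cmp$length <= 0 || cmp$diameter <= 0)
      stop("compartment geometry must be strictly positive (", cmp$label, ")")
    if (any(unlist(cmp$channels) < 0))
      stop("negative channel density in compartment ", cmp$label)
  }
  if (spec$cell_type == "pyr") {
    d <- setNames(vapply(spec$compartments, `[[`, 0, "depth"),
                  vapply(spec$compartments, `[[`, "", "label"))
    stopifnot(d["lm"] < d["rad-distal"], d["rad-distal"] < d["rad-proximal"],
              d["rad-proximal"] < 0, d["soma"] >= 0, d["basal"] >= d["soma"])
  }
  invisible(spec)
}

#' @export
print.cell_spec <- function(x, ...) {
  cat("<cell_spec>", x$cell_type, "-", length(x$compartments),
      "compartment(s), spike threshold", x$spike_threshold, "mV\n")
  for (cmp in x$compartments) {
    cat(sprintf("  %-13s depth %5g um  L %g d %g  channels: %s\n",
                cmp$label, cmp$depth, cmp$length, cmp$diameter,
                paste(names(cmp$channels), unlist(cmp$channels),
                      sep = "=", collapse = " ")))
  }
  invisible(x)
}

# engine-facing per-compartment arrays; conductances converted from densities
# (mS/cm2 * cm2 * 1e3 -> uS), capacitance to nF
cell_arrays <- function(spec) {
  comps <- spec$compartments
  n <- length(comps)
  area <- vapply(comps, function(c) pi * c$diameter * c$length * 1e-8, 0)
  getd <- function(c, nm) if (is.null(c$channels[[nm]])) 0 else c$channels[[nm]]
  list(
    n = n,
    C_nF = vapply(comps, `[[`, 0, "capacitance") * area * 1e3,
    gL  = vapply(comps, function(c) getd(c, "leak"), 0) * area * 1e3,
    EL  = vapply(comps, function(c) if (is.null(c$e_leak)) -65 else c$e_leak, 0),
    gNa = vapply(comps, function(c) getd(c, "na") + getd(c, "na_fs"), 0) * area * 1e3,
    gKdr = vapply(comps, function(c) getd(c, "kdr"), 0) * area * 1e3,
    gKM = vapply(comps, function(c) getd(c, "km"), 0) * area * 1e3,
    gH  = vapply(comps, function(c) getd(c, "h"), 0) * area * 1e3,
    kin = vapply(comps, function(c) as.integer(getd(c, "na_fs") > 0), 0L),
    # compartment 1 is the root; all others attach to their predecessor except
    # dendritic chains of the pyramidal template, handled by label
    parent = cell_parents(comps),
    g_axial = vapply(comps, function(c)
      if (is.null(c$axial_conductance_to_parent)) 0
      else c$axial_conductance_to_parent, 0),
    depth = vapply(comps, `[[`, 0, "depth"),
    label = vapply(comps, `[[`, "", "label")
  )
}

# soma-rooted tree: basal and rad-proximal attach to soma, rad-distal to
# rad-proximal, lm to rad-distal; single-compartment cells have no parents
cell_parents <- function(comps) {
  labs <- vapply(comps, `[[`, "", "label")
  par <- rep(-1L, length(labs))
  link <- c("basal" = "soma", "rad-proximal" = "soma",
            "rad-distal" = "rad-proximal", "lm" = "rad-distal",
            "axon-initial" = "soma")
  for (i in seq_along(labs)) {
    p <- link[labs[i]]
    if (!is.na(p)) par[i] <- match(p, labs) - 1L
  }
  par
}

soma_index <- function(spec) {
  match("soma", vapply(spec$compartments, `[[`, "", "label"))
}

#' Initial state of a cell at rest
#'
#' @param spec a `cell_spec`.
#' @param v initial voltage (mV) applied to every compartment; gating
#'   variables start at their steady state for `v`.
#' @return object of class `cell_state`.
#' @export
init_cell_state <- function(spec, v = NULL) {
  arr <- cell_arrays(spec)
  if (is.null(v)) v <- arr$EL[soma_index(spec)]
  st <- list(V = rep(v, arr$n), m = NULL, h = NULL, n = NULL,
             mkm = NULL, qh = NULL, xr = NULL, xd = NULL,
             last_spike = -1e18)
  class(st) <- "cell_state"
  # one throwaway zero-length step lets the engine fill steady-state gating
  out <- membrane_step(spec, st, rep(0, arr$n), dt = 1e-3)
  out$state
}

single_cell_net <- function(spec, I_ext, dt, n_steps, state = NULL,
                            record_vm = FALSE, t0 = 0) {
  arr <- cell_arrays(spec)
  stopifnot(length(I_ext) == arr$n)
  syn <- ca1_defaults()$synapses
  st <- NULL
  if (!is.null(state)) {
    st <- state
    if (is.null(st$m)) st <- NULL # voltages only: let engine derive gating
    else {
      need <- arr$n * length(syn)
      if (is.null(st$xr)) { st$xr <- rep(0, need); st$xd <- rep(0, need) }
    }
  }
  list(dt = dt, n_steps = n_steps, t0 = t0,
       C_nF = arr$C_nF, gL = arr$gL, EL = arr$EL, gNa = arr$gNa,
       gKdr = arr$gKdr, gKM = arr$gKM, gH = arr$gH, g_axial = arr$g_axial,
       kin = arr$kin, parent = arr$parent, cell = rep(0L, arr$n),
       comp_start = 0L, comp_end = arr$n - 1L,
       soma_comp = soma_index(spec) - 1L,
       thresh = spec$spike_threshold,
       refrac = ca1_defaults()$spike$refractory,
       syn_tau_rise = vapply(syn, `[[`, 0, "tau_rise"),
       syn_tau_decay = vapply(syn, `[[`, 0, "tau_decay"),
       syn_E = vapply(syn, `[[`, 0, "reversal"),
       conn_ptr = c(0L, 0L), conn_comp = integer(0), conn_slot = integer(0),
       conn_delay = integer(0), conn_w = numeric(0),
       gen_spike_step = integer(0), gen_spike_unit = integer(0),
       gj_i = integer(0), gj_j = integer(0), gj_g = numeric(0),
       I_tonic = I_ext, I_rhythm_amp = rep(0, arr$n),
       I_rhythm_phase = rep(0, arr$n), f_drive = 0,
       vm_comp = if (record_vm) seq_len(arr$n) - 1L else integer(0),
       sample_every = if (record_vm) 1L else 0L,
       cur_src = rep(-1L, arr$n), n_src = 0L,
       record_spikes = TRUE,
       state_in = st,
       V0 = if (is.null(st)) (if (!is.null(state)) state$V else arr$EL)
            else st$V)
}

#' Advance a cell by one time step
#'
#' Integrates all compartment voltages and gating variables of a single cell
#' by `dt` (exponential Euler gating, implicit voltage update) under given
#' per-compartment injected currents.  Positive injected current
#' depolarizes.  A spike is flagged when the soma crosses the spike
#' threshold upward, subject to the refractory latch.
#'
#' @param spec a `cell_spec`.
#' @param state a `cell_state` (from [init_cell_state()] or a previous call).
#' @param external_currents numeric vector, nA, one entry per compartment.
#' @param dt time step, ms.
#' @return list with elements `state` (new `cell_state`) and `spike`
#'   (logical).
#' @export
membrane_step <- function(spec, state, external_currents, dt = 0.1) {
  stopifnot(dt > 0)
  if (any(!is.finite(state$V))) {
    bad <- which(!is.finite(state$V))[1]
    stop("non-finite voltage in compartment ", bad, " (",
         spec$compartments[[bad]]$label, ")")
  }
  net <- single_cell_net(spec, external_currents, dt, 1L, state = state)
  res <- .sim_core(net)
  st <- res$state
  st$last_spike <- st$last_spike[1]
  class(st) <- "cell_state"
  list(state = st, spike = length(res$spike_t) > 0)
}

#' Run a single cell under constant current
#'
#' @param spec a `cell_spec`.
#' @param I_soma constant current injected at the soma, nA.
#' @param duration ms.
#' @param dt ms.
#' @param record_vm record per-compartment voltages at every step.
#' @return list with `spike_times` (ms) and optionally `vm` (matrix).
#' @export
run_cell <- function(spec, I_soma, duration, dt = 0.1, record_vm = FALSE) {
  arr <- cell_arrays(spec)
  I <- rep(0, arr$n); I[soma_index(spec)] <- I_soma
  net <- single_cell_net(spec, I, dt, round(duration / dt),
                         record_vm = record_vm)
  res <- .sim_core(net)
  list(spike_times = res$spike_t, vm = if (record_vm) res$vm else NULL,
       state = res$state)
}

#' Frequency-current curve
#'
#' Steady-state firing rate of a cell model at each level of constant somatic
#' current; the first 100 ms transient is discarded.
#'
#' @param spec a `cell_spec`.
#' @param currents numeric vector of injected currents (nA).
#' @param duration stimulus duration per level, ms (>= 500).
#' @param dt integration step, ms.
#' @return numeric vector of firing rates (Hz), one per current level.
#' @export
fi_curve <- function(spec, currents, duration = 1000, dt = 0.1) {
  if (length(currents) == 0) stop("empty current list")
  stopifnot(duration >= 500)
  vapply(currents, function(I) {
    spk <- run_cell(spec, I, duration, dt)$spike_times
    sum(spk > 100) / ((duration - 100) / 1000)
  }, 0)
}
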