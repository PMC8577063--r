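#' Population sizes
#'
#' Census of the model at a given scale: 9000 pyramidal cells and eight
#' interneuron classes (CCK and PV basket, axo-axonic, bistratified, OLM,
#' neurogliaform, ivy and Schaffer-collateral-associated cells).  Scaled
#' sizes are rounded up so every population survives scaling.
#'
#' @param scale fraction in (0, 1].
#' @param params parameter list.
#' @return named integer vector.
#' @export
population_sizes <- function(scale = 1, params = ca1_defaults()) {
  stopifnot(scale > 0, scale <= 1)
  n <- unlist(params$populations)
  setNames(as.integer(ceiling(n * scale)), names(n))
}

#' Spatial connection-weight profile
#'
#' Distance-dependent weight multiplier on the normalized track.  The
#' `gaussian` profile concentrates weight on nearby targets (used for
#' place-coded CA3/MEC afferents); the `inverted_gaussian` profile spares
#' nearby targets and weights distant ones -- PV basket cells inhibit mainly
#' distant pyramidal cells.
#'
#' @param profile `"none"`, `"gaussian"` or `"inverted_gaussian"`.
#' @param distance track distance(s), finite.
#' @param sigma profile width, track units.
#' @param floor minimum multiplier of the inverted profile at distance 0.
#' @return weight multiplier(s) in (0, 1].
#' @export
spatial_weight <- function(profile = c("none", "gaussian",
                                       "inverted_gaussian"),
                           distance, sigma = 0.1, floor = 0.2) {
  profile <- match.arg(profile)
  stopifnot(all(is.finite(distance)))
  switch(profile,
         none = rep(1, length(distance)),
         gaussian = exp(-distance^2 / (2 * sigma^2)),
         inverted_gaussian = 1 - (1 - floor) * exp(-distance^2 / (2 * sigma^2)))
}

#' Instantiate the cell populations
#'
#' Creates cell templates and place coordinates without wiring: pyramidal
#' cells are spaced evenly along the track with spatially modulated and
#' unmodulated cells interleaved 1:1; interneurons are spaced evenly per
#' population.
#'
#' @param scale fraction in (0, 1].
#' @param params parameter list.
#' @return list with `sizes`, `templates`, `positions`, `pyr_spatial` and
#'   the global cell offset table.
#' @export
build_populations <- function(scale = 1, params = ca1_defaults()) {
  sizes <- population_sizes(scale, params)
  pops <- names(sizes)
  templates <- lapply(pops, function(p) build_cell(p))
  names(templates) <- pops
  positions <- lapply(sizes, function(n) (seq_len(n) - 0.5) / n)
  offsets <- c(0L, cumsum(as.integer(sizes)))[seq_along(sizes)]
  names(offsets) <- pops
  list(sizes = sizes, templates = templates, positions = positions,
       pyr_spatial = seq_len(sizes[["pyr"]]) %% 2L == 1L,
       offsets = offsets, n_cells = sum(sizes))
}

# Bernoulli wiring of one rule, chunked over presynaptic units to bound
# memory at large scale.  Returns 0-based indices.
wire_rule <- function(pre_idx, pre_pos, post_idx, post_pos, rule, rescale) {
  n_pre <- length(pre_idx); n_post <- length(post_idx)
  if (n_pre == 0 || n_post == 0) return(NULL)
  block <- max(1L, as.integer(2e6 / n_post))
  out <- vector("list", ceiling(n_pre / block))
  bi <- 0L
  for (s in seq(1L, n_pre, by = block)) {
    e <- min(s + block - 1L, n_pre)
    nb <- e - s + 1L
    pick <- which(runif(nb * n_post) < rule$p)
    if (length(pick) == 0) next
    i_pre <- (pick - 1L) %/% n_post + s       # local pre within [s, e]
    i_post <- (pick - 1L) %% n_post + 1L
    # no self-synapses (same global unit)
    keep <- pre_idx[i_pre] != post_idx[i_post]
    i_pre <- i_pre[keep]; i_post <- i_post[keep]
    if (length(i_pre) == 0) next
    w <- pmax(rnorm(length(i_pre), rule$w, rule$w_sd), 0)
    prof <- if (is.null(rule$profile)) "none" else rule$profile
    if (prof != "none") {
      d <- abs(pre_pos[i_pre] - post_pos[i_post])
      w <- w * spatial_weight(prof, d, rule$sigma,
                              if (is.null(rule$floor)) 0.2 else rule$floor)
    }
    keep <- w > 0
    bi <- bi + 1L
    out[[bi]] <- data.frame(pre = pre_idx[i_pre[keep]],
                            post = post_idx[i_post[keep]],
                            w = w[keep] * rescale)
  }
  if (bi == 0L) return(NULL)
  do.call(rbind, out[seq_len(bi)])
}

#' Build the CA1 network
#'
#' Instantiates populations, draws the chemical connection lists from the
#' default connection matrix (Bernoulli wiring, truncated-Gaussian weights,
#' spatial profiles), samples gap junctions within the PV basket and
#' neurogliaform populations, and attaches the external input ensemble.
#' At reduced scale the connection weights are multiplied by `1/scale`
#' (capped) so the expected total input per cell is preserved.  The result
#' is fully determined by (`config`, `seed`).
#'
#' @param config run configuration (list or `run_config`), see
#'   [load_run_config()]; fields used here: `state`, `scale`, `duration`,
#'   `params` overrides.
#' @param seed integer.
#' @return object of class `ca1_network`.
#' @export
build_network <- function(config = list(), seed = 1) {
  cfg <- load_run_config(config)
  params <- cfg$params
  pop <- build_populations(cfg$scale, params)
  gens <- build_input_ensemble(state_config(cfg$state), cfg$scale,
                               seed = seed, duration = cfg$duration,
                               params = params)
  if (cfg$out_of_field) {
    # shift all place-field envelopes far beyond the traversal
    gens <- lapply(gens, function(g) {
      if (g$source %in% c("ca3_spatial", "mec")) {
        g$envelope_center <- cfg$duration * 10
        g$envelope_period <- NULL
      }
      g
    })
  }
  gsrc <- vapply(gens, `[[`, "", "source")
  gtarget <- vapply(gens, function(g)
    if (is.null(g$target)) "" else g$target, "")
  gpos <- vapply(gens, function(g)
    if (is.null(g$place_position)) 0.5 else g$place_position, 0)
  rescale <- min(1 / cfg$scale, params$network$weight_rescale_cap)

  pops <- names(pop$sizes)
  unit_of <- function(p, which = NULL) {
    # global presynaptic unit ids: cells first, generators after
    if (p %in% pops) {
      idx <- seq_len(pop$sizes[[p]])
      pop$offsets[[p]] + idx - 1L
    } else {
      sel <- gsrc == p
      pop$n_cells + which(sel) - 1L
    }
  }
  pos_of <- function(p) if (p %in% pops) pop$positions[[p]] else gpos[gsrc == p]

  edges <- with_seed(child_seed(seed, 1), {
    pieces <- list()
    for (rule in params$connections) {
      if (!rule$post %in% pops) stop("connection rule targets unknown population: ",
                                     rule$post)
      if (!(rule$pre %in% pops ||
            rule$pre %in% c("ca3_spatial", "ca3_nonspatial", "mec", "ms_teevra")))
        stop("connection rule from unknown source: ", rule$pre)
      pre_idx <- unit_of(rule$pre)
      pre_pos <- pos_of(rule$pre)
      if (rule$pre == "ms_teevra") {
        sel <- gtarget[gsrc == "ms_teevra"] == rule$post
        pre_idx <- pre_idx[sel]; pre_pos <- pre_pos[sel]
      }
      post_sel <- seq_len(pop$sizes[[rule$post]])
      if (rule$post == "pyr") {
        # spatially coded afferents contact place cells; background afferents
        # contact the unmodulated half
        if (rule$pre %in% c("ca3_spatial", "mec"))
          post_sel <- which(pop$pyr_spatial)
        if (rule$pre == "ca3_nonspatial")
          post_sel <- which(!pop$pyr_spatial)
      }
      post_idx <- pop$offsets[[rule$post]] + post_sel - 1L
      df <- wire_rule(pre_idx, pre_pos, post_idx,
                      pop$positions[[rule$post]][post_sel], rule, rescale)
      if (!is.null(df) && nrow(df) > 0) {
        df$kind <- rule$kind
        df$target <- rule$target
        df$delay <- rule$delay
        df$post_pop <- rule$post
        pieces[[length(pieces) + 1]] <- df
      }
    }
    if (length(pieces)) do.call(rbind, pieces) else
      data.frame(pre = integer(0), post = integer(0), w = numeric(0),
                 kind = character(0), target = character(0),
                 delay = numeric(0), post_pop = character(0))
  })

  gj <- with_seed(child_seed(seed, 2), {
    pieces <- list()
    for (p in names(params$gap_junctions)) {
      gp <- params$gap_junctions[[p]]
      n <- pop$sizes[[p]]
      if (n >= 2) {
        cand <- cbind(seq_len(n - 1), seq_len(n - 1) + 1) # nearest neighbours
        sel <- runif(nrow(cand)) < gp$p
        if (any(sel))
          pieces[[length(pieces) + 1]] <- data.frame(
            pop = p, i = cand[sel, 1], j = cand[sel, 2],
            g = gp$g * rescale)
      }
    }
    if (length(pieces)) do.call(rbind, pieces) else NULL
  })

  structure(list(config = cfg, seed = seed, populations = pop,
                 generators = gens, edges = edges, gap_junctions = gj),
            class = "ca1_network")
}

#' @export
print.ca1_network <- function(x, ...) {
  cat("<ca1_network> state", x$config$state, "scale", x$config$scale,
      "seed", x$seed, "\n  cells:",
      paste(names(x$populations$sizes), x$populations$sizes, sep = "=",
            collapse = " "),
      "\n  generators:", length(x$generators),
      " chemical edges:", nrow(x$edges),
      " gap junctions:", if (is.null(x$gap_junctions)) 0
                         else nrow(x$gap_junctions), "\n")
  invisible(x)
}

# compartment layout of the whole network: concatenated per-population
# template arrays; returns flat engine vectors plus lookup tables
network_compartments <- function(pop) {
  pops <- names(pop$sizes)
  arrs <- lapply(pop$templates, cell_arrays)
  fields <- c("C_nF", "gL", "EL", "gNa", "gKdr", "gKM", "gH", "g_axial")
  flat <- setNames(vector("list", length(fields)), fields)
  kin <- integer(0); parent <- integer(0); cellof <- integer(0)
  depth <- numeric(0); labs <- character(0)
  comp_start <- integer(0); soma <- integer(0); thresh <- numeric(0)
  comp_offset <- 0L; cell_id <- 0L
  for (p in pops) {
    a <- arrs[[p]]
    n <- pop$sizes[[p]]
    for (f in fields) flat[[f]] <- c(flat[[f]], rep(a[[f]], n))
    kin <- c(kin, rep(a$kin, n))
    depth <- c(depth, rep(a$depth, n))
    labs <- c(labs, rep(a$label, n))
    par_rep <- rep(a$parent, n) +
      rep((seq_len(n) - 1L) * a$n, each = a$n) + comp_offset
    par_rep[rep(a$parent, n) < 0] <- -1L
    parent <- c(parent, par_rep)
    comp_start <- c(comp_start, comp_offset + (seq_len(n) - 1L) * a$n)
    soma_loc <- match("soma", a$label) - 1L
    soma <- c(soma, comp_offset + (seq_len(n) - 1L) * a$n + soma_loc)
    thresh <- c(thresh, rep(pop$templates[[p]]$spike_threshold, n))
    cellof <- c(cellof, rep(cell_id + seq_len(n) - 1L, each = a$n))
    comp_offset <- comp_offset + n * a$n
    cell_id <- cell_id + n
  }
  c(flat, list(kin = kin, parent = parent, cell = cellof, depth = depth,
               label = labs, comp_start = comp_start, soma = soma,
               thresh = thresh, n_comp = comp_offset, arrs = arrs))
}

# compartment index (0-based) for (cell, target label); axon-initial falls
# back to the soma when the template has no AIS compartment
target_comp <- function(nc, pop, post_pop, post_cell_global, target) {
  a <- nc$arrs[[post_pop]]
  loc <- match(target, a$label)
  if (is.na(loc) && target == "axon-initial") loc <- match("soma", a$label)
  if (is.na(loc)) loc <- match("soma", a$label)
  nc$comp_start[post_cell_global + 1L] + loc - 1L
}

#' Run a network simulation
#'
#' Integrates all cells, synapses and gap junctions of a network under its
#' sampled external input trains and returns a recording: spike times per
#' population, sampled somatic voltages, pyramidal transmembrane currents
#' binned into laminar sources at the LFP sampling rate, and (by default)
#' the laminar LFP itself.  Identical (`network`, `seed`) give identical
#' output on one platform.
#'
#' @param network a `ca1_network`.
#' @param inputs generator ensemble (defaults to the one attached to the
#'   network).
#' @param duration ms (defaults to the network config).
#' @param dt integration step, ms.
#' @param record list: `vm_per_pop` somatic voltages to keep per population,
#'   `lfp` logical.
#' @param seed integer, controls input spike sampling.
#' @return object of class `ca1_recording`.
#' @export
run_simulation <- function(network, inputs = NULL, duration = NULL,
                           dt = NULL, record = list(), seed = 1) {
  cfg <- network$config
  if (is.null(inputs)) inputs <- network$generators
  if (is.null(duration)) duration <- cfg$duration
  if (is.null(dt)) dt <- cfg$dt
  stopifnot(duration > 0, dt > 0)
  rec <- modifyList(list(vm_per_pop = 2, lfp = TRUE), record)
  params <- cfg$params
  pop <- network$populations
  nc <- network_compartments(pop)
  syn <- params$synapses
  slot_names <- names(syn)

  # --- input spike trains -> engine step events ---------------------------
  n_steps <- round(duration / dt)
  trains <- lapply(seq_along(inputs), function(i)
    sample_spike_train(inputs[[i]], duration, seed = child_seed(seed, 100 + i)))
  gsteps <- lapply(trains, function(tt) as.integer(floor(tt / dt)))
  gunit <- rep(pop$n_cells + seq_along(inputs) - 1L, lengths(gsteps))
  gstep <- unlist(gsteps, use.names = FALSE)
  if (is.null(gstep)) gstep <- integer(0)
  ord <- order(gstep)
  gstep <- gstep[ord]; gunit <- as.integer(gunit[ord])
  keep <- gstep < n_steps
  gstep <- gstep[keep]; gunit <- gunit[keep]

  # --- connections -> CSR over units --------------------------------------
  e <- network$edges
  post_comp <- integer(nrow(e))
  for (p in unique(e$post_pop)) {
    sel <- e$post_pop == p
    a <- nc$arrs[[p]]
    loc <- match(e$target[sel], a$label)
    loc[is.na(loc)] <- match("soma", a$label)
    post_comp[sel] <- nc$comp_start[e$post[sel] + 1L] + loc - 1L
  }
  slot <- match(e$kind, slot_names) - 1L
  if (anyNA(slot)) stop("unknown receptor kind in connection table")
  delay_steps <- pmax(1L, as.integer(round(e$delay / dt)))
  n_units <- pop$n_cells + length(inputs)
  ordu <- order(e$pre)
  pre_sorted <- e$pre[ordu]
  conn_ptr <- c(0L, cumsum(tabulate(pre_sorted + 1L, nbins = n_units)))

  # --- gap junctions -------------------------------------------------------
  gj <- network$gap_junctions
  if (!is.null(gj)) {
    gj_i <- gj_j <- integer(nrow(gj)); gj_g <- gj$g
    for (r in seq_len(nrow(gj))) {
      off <- pop$offsets[[gj$pop[r]]]
      a <- nc$arrs[[gj$pop[r]]]
      soma_loc <- match("soma", a$label) - 1L
      gj_i[r] <- nc$comp_start[off + gj$i[r]] + soma_loc
      gj_j[r] <- nc$comp_start[off + gj$j[r]] + soma_loc
    }
  } else { gj_i <- gj_j <- integer(0); gj_g <- numeric(0) }

  # --- injected drives -----------------------------------------------------
  I0 <- Iamp <- Iph <- numeric(nc$n_comp)
  chol_on <- cfg$state == "theta"
  for (p in names(params$drives)) {
    d <- params$drives[[p]]
    soma_idx <- nc$soma[pop$offsets[[p]] + seq_len(pop$sizes[[p]])] + 1L
    tonic <- if (is.null(d$tonic)) 0 else d$tonic
    amp <- if (is.null(d$rhythm_amp)) 0 else d$rhythm_amp
    if (p %in% c("cckbas", "olm") && !chol_on) { tonic <- 0; amp <- 0 }
    I0[soma_idx] <- I0[soma_idx] + tonic
    if (amp != 0) {
      Iamp[soma_idx] <- amp
      Iph[soma_idx] <- -d$rhythm_phase * pi / 180
    }
  }

  # --- recording layout ----------------------------------------------------
  fs <- params$lfp$sample_rate
  sample_every <- max(1L, as.integer(round(1000 / fs / dt)))
  vm_comp <- integer(0); vm_pop <- character(0); vm_cell <- integer(0)
  for (p in names(pop$sizes)) {
    k <- min(rec$vm_per_pop, pop$sizes[[p]])
    if (k > 0) {
      cells <- pop$offsets[[p]] + seq_len(k)
      vm_comp <- c(vm_comp, nc$soma[cells])
      vm_pop <- c(vm_pop, rep(p, k)); vm_cell <- c(vm_cell, seq_len(k))
    }
  }
  # laminar current sources: pyramidal compartments binned along the track
  nxb <- params$lfp$n_xbins
  cur_src <- rep(-1L, nc$n_comp)
  a_pyr <- nc$arrs[["pyr"]]
  n_pyr <- pop$sizes[["pyr"]]
  xbin <- pmin(nxb - 1L, as.integer(pop$positions$pyr * nxb))
  for (i in seq_len(n_pyr)) {
    idx <- nc$comp_start[pop$offsets[["pyr"]] + i] + seq_len(a_pyr$n)
    cur_src[idx] <- xbin[i] * a_pyr$n + seq_len(a_pyr$n) - 1L
  }
  n_src <- nxb * a_pyr$n
  L <- params$network$track_length_um
  src_pos <- data.frame(
    x_um = rep(((seq_len(nxb) - 0.5) / nxb) * L, each = a_pyr$n),
    depth_um = rep(a_pyr$depth, nxb),
    label = rep(a_pyr$label, nxb))

  net <- list(dt = dt, n_steps = n_steps, t0 = 0,
              C_nF = nc$C_nF, gL = nc$gL, EL = nc$EL, gNa = nc$gNa,
              gKdr = nc$gKdr, gKM = nc$gKM, gH = nc$gH,
              g_axial = nc$g_axial, kin = nc$kin, parent = nc$parent,
              cell = nc$cell,
              comp_start = nc$comp_start,
              comp_end = nc$comp_start - 1L, # unused by the core
              soma_comp = nc$soma, thresh = nc$thresh,
              refrac = params$spike$refractory,
              syn_tau_rise = vapply(syn, `[[`, 0, "tau_rise"),
              syn_tau_decay = vapply(syn, `[[`, 0, "tau_decay"),
              syn_E = vapply(syn, `[[`, 0, "reversal"),
              conn_ptr = as.integer(conn_ptr),
              conn_comp = as.integer(post_comp[ordu]),
              conn_slot = as.integer(slot[ordu]),
              conn_delay = as.integer(delay_steps[ordu]),
              conn_w = e$w[ordu],
              gen_spike_step = gstep, gen_spike_unit = gunit,
              gj_i = as.integer(gj_i), gj_j = as.integer(gj_j), gj_g = gj_g,
              I_tonic = I0, I_rhythm_amp = Iamp, I_rhythm_phase = Iph,
              f_drive = params$network$theta_freq,
              vm_comp = as.integer(vm_comp), sample_every = sample_every,
              cur_src = cur_src, n_src = as.integer(n_src),
              record_spikes = TRUE, state_in = NULL,
              V0 = nc$EL)
  res <- .sim_core(net)

  # --- package the recording ----------------------------------------------
  pop_of_cell <- rep(names(pop$sizes), pop$sizes)
  local_id <- unlist(lapply(pop$sizes, seq_len), use.names = FALSE)
  spikes <- data.frame(pop = pop_of_cell[res$spike_cell],
                       cell = local_id[res$spike_cell],
                       t = res$spike_t)
  time <- seq_len(nrow(res$currents)) * 1000 / fs
  out <- list(spikes = spikes,
              vm = list(mat = res$vm, pop = vm_pop, cell = vm_cell, fs = fs),
              currents = res$currents, current_sources = src_pos,
              time = time, fs = fs, dt = dt, duration = duration,
              state = cfg$state, scale = cfg$scale, seed = seed,
              config = cfg, lfp = NULL, electrodes = NULL)
  class(out) <- "ca1_recording"
  if (isTRUE(rec$lfp)) {
    el <- electrode_spec(
      positions = cbind(x = rep(L / 2, length(params$lfp$electrode_depths)),
                        depth = params$lfp$electrode_depths),
      sigma = params$lfp$sigma)
    out$lfp <- compute_lfp(res$currents,
                           as.matrix(src_pos[, c("x_um", "depth_um")]), el,
                           min_distance = params$lfp$min_distance)
    out$electrodes <- el
  }
  out
}

#' @export
print.ca1_recording <- function(x, ...) {
  cat("<ca1_recording>", x$state, "state,", x$duration, "ms at dt", x$dt,
      "ms\n  spikes:", nrow(x$spikes), "events;",
      "Vm traces:", length(x$vm$pop), ";",
      "LFP:", if (is.null(x$lfp)) "none" else paste(ncol(x$lfp), "electrodes"),
      "\n")
  invisible(x)
}

#' Spike times of one population
#' @param recording a `ca1_recording`.
#' @param pop population name.
#' @return numeric vector, ms.
#' @export
population_spikes <- function(recording, pop) {
  recording$spikes$t[recording$spikes$pop == pop]
}

#' Pyramidal-layer LFP trace
#' @param recording a `ca1_recording` with an LFP.
#' @return numeric vector (mV) at the electrode closest to depth 0.
#' @export
pyramidal_lfp <- function(recording) {
  stopifnot(!is.null(recording$lfp))
  i <- which.min(abs(recording$electrodes$positions[, "depth"]))
  recording$lfp[, i]
}
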