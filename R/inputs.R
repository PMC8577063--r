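#' External input generator specification
#'
#' Inhomogeneous Poisson drives standing in for the afferents of the CA1
#' field: spatially modulated CA3 place-cell input (theta- and slow-gamma
#' modulated, Gaussian place-field envelope), spatially unmodulated CA3
#' background (theta only), MEC grid-like input (slow periodic envelope,
#' theta- and middle-gamma modulated, leading its paired CA3 envelope), and
#' the rhythm-locked GABAergic Teevra projection of the medial septum.
#'
#' The instantaneous rate is a product of the peak rate, the (unit-peak)
#' envelope, and multiplicative cosine modulations:
#' \deqn{r(t) = r_0\,E(t)\,(1+d_\theta\cos(2\pi f_\theta t/1000 - \psi))
#'   (1+d_\gamma\cos(2\pi f_\gamma t/1000))
#'   (1+d_r\cos(2\pi f_r (t-c)/1000))}
#' clipped at zero.  The theta phase offset \eqn{\psi} (degrees) places the
#' rate peak on the shared septo-hippocampal theta clock; ripple modulation
#' is locked to the envelope center \eqn{c}, as ripple episodes are
#' per-event phenomena.
#'
#' @param source `"ca3_spatial"`, `"ca3_nonspatial"`, `"mec"`, `"ms_teevra"`.
#' @param mean_rate peak envelope rate, Hz (rate when all modulations and
#'   the envelope are at 1).
#' @param envelope_center center of the Gaussian envelope, ms (`NULL` for a
#'   flat envelope).
#' @param envelope_width Gaussian sigma, ms (`NULL` = flat).
#' @param envelope_period if set, the envelope repeats with this period (ms)
#'   -- used for the periodic bumps of grid-like MEC drive.
#' @param theta list `(freq, depth, phase)`: Hz, modulation depth in [0,1],
#'   clock phase of the rate peak in degrees.
#' @param gamma,ripple list `(freq, depth)` or `NULL`.
#' @param place_position normalized track coordinate or `NULL`.
#' @param label free-form identifier.
#' @param target for septal drives, the population the generator projects to.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(source, mean_rate,
                           envelope_center = NULL, envelope_width = NULL,
                           envelope_period = NULL,
                           theta = list(freq = 7, depth = 0, phase = 0),
                           gamma = NULL, ripple = NULL,
                           place_position = NULL, label = source,
                           target = NULL) {
  src_ok <- c("ca3_spatial", "ca3_nonspatial", "mec", "ms_teevra")
  if (!source %in% src_ok)
    stop("unknown source '", source, "'; valid: ", paste(src_ok, collapse = ", "))
  stopifnot(mean_rate >= 0, theta$depth >= 0, theta$depth <= 1)
  if (!is.null(gamma)) stopifnot(gamma$depth >= 0, gamma$depth <= 1)
  if (!is.null(ripple)) stopifnot(ripple$depth >= 0, ripple$depth <= 1)
  structure(list(source = source, mean_rate = mean_rate,
                 envelope_center = envelope_center,
                 envelope_width = envelope_width,
                 envelope_period = envelope_period,
                 theta = theta, gamma = gamma, ripple = ripple,
                 place_position = place_position, label = label,
                 target = target),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec>", x$label, sprintf("(%s) peak %g Hz", x$source,
                                           x$mean_rate))
  if (!is.null(x$envelope_width))
    cat(sprintf(", envelope N(%g, %g ms)",
                if (is.null(x$envelope_center)) NA else x$envelope_center,
                x$envelope_width))
  cat(sprintf(", theta %g Hz d=%g psi=%g", x$theta$freq, x$theta$depth,
              x$theta$phase))
  if (!is.null(x$gamma)) cat(sprintf(", gamma %g Hz d=%g", x$gamma$freq,
                                     x$gamma$depth))
  if (!is.null(x$ripple)) cat(sprintf(", ripple %g Hz d=%g", x$ripple$freq,
                                      x$ripple$depth))
  cat("\n")
  invisible(x)
}

generator_envelope <- function(spec, t) {
  if (is.null(spec$envelope_width)) return(rep(1, length(t)))
  cen <- if (is.null(spec$envelope_center)) 0 else spec$envelope_center
  sig <- spec$envelope_width
  if (is.null(spec$envelope_period)) {
    exp(-(t - cen)^2 / (2 * sig^2))
  } else {
    per <- spec$envelope_period
    # wrap the offset into (-per/2, per/2]: periodic bump train
    d <- (t - cen) %% per
    d <- ifelse(d > per / 2, d - per, d)
    exp(-d^2 / (2 * sig^2))
  }
}

#' Instantaneous generator rate
#'
#' @param spec a `generator_spec`.
#' @param t time or vector of times, ms.
#' @return rate(s), Hz; deterministic in (`spec`, `t`).
#' @export
rate_function <- function(spec, t) {
  r <- spec$mean_rate * generator_envelope(spec, t)
  th <- spec$theta
  if (th$depth > 0)
    r <- r * (1 + th$depth * cos(2 * pi * th$freq * t / 1000 -
                                   th$phase * pi / 180))
  if (!is.null(spec$gamma) && spec$gamma$depth > 0)
    r <- r * (1 + spec$gamma$depth * cos(2 * pi * spec$gamma$freq * t / 1000))
  if (!is.null(spec$ripple) && spec$ripple$depth > 0) {
    cen <- if (is.null(spec$envelope_center)) 0 else spec$envelope_center
    r <- r * (1 + spec$ripple$depth *
                cos(2 * pi * spec$ripple$freq * (t - cen) / 1000))
  }
  pmax(r, 0)
}

#' Sample a spike train from a generator
#'
#' Draws one realization of the inhomogeneous Poisson process defined by
#' [rate_function()] using thinning: candidates are sampled from a
#' homogeneous process at the rate upper bound
#' `mean_rate * (1+d_theta)(1+d_gamma)(1+d_ripple)` and accepted with
#' probability `rate(t) / bound`.
#'
#' @param spec a `generator_spec`.
#' @param t_end duration, ms.
#' @param seed integer; the draw is reproducible per (`spec`, `t_end`, `seed`).
#' @return sorted numeric vector of spike times in (0, t_end], ms.
#' @export
sample_spike_train <- function(spec, t_end, seed = 1) {
  stopifnot(t_end > 0)
  bound <- spec$mean_rate *
    (1 + spec$theta$depth) *
    (1 + if (is.null(spec$gamma)) 0 else spec$gamma$depth) *
    (1 + if (is.null(spec$ripple)) 0 else spec$ripple$depth)
  if (bound <= 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- rpois(1, bound * t_end / 1000)
    if (n_cand == 0) numeric(0) else {
      tt <- sort(runif(n_cand, 0, t_end))
      keep <- runif(n_cand) < rate_function(spec, tt) / bound
      unique(tt[keep])
    }
  })
}

#' Network state configuration
#'
#' In the theta (locomotion) state all four source groups are active, the
#' Teevra projection is rhythmic and cholinergic tone is on.  The non-theta
#' state removes the MEC input, the spatially unmodulated CA3 generators and
#' the cholinergic input, and switches the Teevra cells to constant-rate
#' discharge; CA3 place-cell envelopes are compressed into ripple episodes
#' (see [apply_nontheta_transform()]).
#'
#' @param state `"theta"` or `"non_theta"`.
#' @return object of class `state_config`.
#' @export
state_config <- function(state = c("theta", "non_theta")) {
  state <- match.arg(state)
  if (state == "theta") {
    cfg <- list(state = state,
                sources = c("ca3_spatial", "ca3_nonspatial", "mec",
                            "ms_teevra"),
                teevra_mode = "rhythmic", cholinergic = TRUE)
  } else {
    cfg <- list(state = state,
                sources = c("ca3_spatial", "ms_teevra"),
                teevra_mode = "constant", cholinergic = FALSE)
  }
  structure(cfg, class = "state_config")
}

#' Build the external input ensemble
#'
#' Instantiates the generator population for a network state at a given
#' scale: CA3 spatial generators with place fields tiling the track (their
#' envelope centers follow a single constant-speed traversal of duration
#' `duration`), CA3 non-spatial background, MEC grid-like generators whose
#' envelope leads the CA3 envelope at the same track position by the
#' configured lag, and Teevra generators split into target subgroups with
#' distributed theta phase offsets.  In the non-theta state the surviving
#' sources are returned already transformed.
#'
#' @param state a `state_config` (or the state name).
#' @param scale population scale factor in (0, 1].
#' @param seed integer, controls the Teevra phase jitter.
#' @param duration traversal duration, ms (maps track position to envelope
#'   center time).
#' @param params parameter list, see [ca1_defaults()].
#' @return list of `generator_spec`.
#' @export
build_input_ensemble <- function(state = state_config("theta"), scale = 1,
                                 seed = 1, duration = 60000,
                                 params = ca1_defaults()) {
  if (is.character(state)) state <- state_config(state)
  stopifnot(scale > 0, scale <= 1)
  g <- params$generators
  specs <- list()
  add <- function(s) specs[[length(specs) + 1]] <<- s

  if ("ca3_spatial" %in% state$sources) {
    n <- ceiling(g$ca3_spatial$count * scale)
    pos <- (seq_len(n) - 0.5) / n
    for (i in seq_len(n)) {
      add(generator_spec("ca3_spatial", g$ca3_spatial$mean_rate,
                         envelope_center = pos[i] * duration,
                         envelope_width = g$ca3_spatial$envelope_width,
                         theta = g$ca3_spatial$theta,
                         gamma = g$ca3_spatial$gamma,
                         place_position = pos[i],
                         label = paste0("ca3_spatial_", i)))
    }
  }
  if ("ca3_nonspatial" %in% state$sources) {
    n <- ceiling(g$ca3_nonspatial$count * scale)
    for (i in seq_len(n)) {
      add(generator_spec("ca3_nonspatial", g$ca3_nonspatial$mean_rate,
                         theta = g$ca3_nonspatial$theta,
                         label = paste0("ca3_nonspatial_", i)))
    }
  }
  if ("mec" %in% state$sources) {
    n <- ceiling(g$mec$count * scale)
    pos <- (seq_len(n) - 0.5) / n
    for (i in seq_len(n)) {
      add(generator_spec("mec", g$mec$mean_rate,
                         envelope_center = pos[i] * duration - g$mec$mec_lead,
                         envelope_width = g$mec$envelope_width,
                         envelope_period = g$mec$grid_period * duration,
                         theta = g$mec$theta, gamma = g$mec$gamma,
                         place_position = pos[i],
                         label = paste0("mec_", i)))
    }
  }
  if ("ms_teevra" %in% state$sources) {
    n <- ceiling(g$ms_teevra$count * scale)
    tp <- names(g$teevra_phase)
    if (!is.null(g$teevra_share)) {
      cnt <- pmax(1L, round(unlist(g$teevra_share)[tp] * n))
      targets <- rep(tp, cnt)[seq_len(max(n, sum(cnt)))]
      targets <- targets[!is.na(targets)]
      n <- length(targets)
    } else {
      targets <- rep(tp, length.out = n)
    }
    jit <- with_seed(child_seed(seed, 999),
                     runif(n, -g$ms_teevra$phase_jitter,
                           g$ms_teevra$phase_jitter))
    for (i in seq_len(n)) {
      th <- g$ms_teevra$theta
      th$phase <- g$teevra_phase[[targets[i]]] + jit[i]
      add(generator_spec("ms_teevra", g$ms_teevra$mean_rate, theta = th,
                         label = paste0("teevra_", targets[i], "_", i),
                         target = targets[i]))
    }
  }
  if (state$state == "non_theta") {
    specs <- lapply(specs, apply_nontheta_transform,
                    common_center = duration / 2, params = params)
  }
  specs
}

#' Non-theta / ripple transform of a generator
#'
#' CA3 spatial generators: place-field envelopes are compressed 40-fold (the
#' peak rate is scaled up by the same factor so the expected spike count per
#' pass is preserved, up to the configured rate ceiling), theta modulation is
#' removed, slow-gamma modulation retained, ripple modulation (170 Hz)
#' enabled, and envelope centers of an ensemble converge on a common center.
#' Teevra generators lose their theta modulation and discharge at constant
#' rate.
#'
#' @param spec a `generator_spec` with source `ca3_spatial` or `ms_teevra`.
#' @param common_center convergence center, ms (`NULL` keeps the center).
#' @param params parameter list.
#' @return transformed `generator_spec`.
#' @export
apply_nontheta_transform <- function(spec, common_center = NULL,
                                     params = ca1_defaults()) {
  nt <- params$generators$nontheta
  if (spec$source == "ca3_spatial") {
    spec$envelope_width <- spec$envelope_width / nt$compression
    spec$mean_rate <- min(spec$mean_rate * nt$compression, nt$rate_ceiling)
    spec$theta$depth <- 0
    spec$ripple <- nt$ripple
    if (!is.null(common_center)) spec$envelope_center <- common_center
  } else if (spec$source == "ms_teevra") {
    spec$theta$depth <- 0
  } else {
    stop("non-theta transform applies to ca3_spatial or ms_teevra sources, not ",
         spec$source)
  }
  spec
}

#' Pooled binned spike rate of an ensemble
#'
#' @param trains list of spike-time vectors, ms.
#' @param t_end duration, ms.
#' @param bin bin width, ms.
#' @return numeric vector of pooled spike counts per bin.
#' @export
pooled_rate <- function(trains, t_end, bin = 1) {
  edges <- seq(0, t_end, by = bin)
  all_t <- unlist(trains, use.names = FALSE)
  all_t <- all_t[all_t > 0 & all_t <= t_end]
  tabulate(findInterval(all_t, edges, left.open = TRUE),
           nbins = length(edges) - 1)
}

#' Export sampled spike trains as CSV
#'
#' Plain-text export with columns `generator_id, spike_time_ms`.
#'
#' @param trains named list of spike-time vectors.
#' @param path output file.
#' @export
export_spike_trains <- function(trains, path) {
  ids <- names(trains)
  if (is.null(ids)) ids <- as.character(seq_along(trains))
  df <- data.frame(
    generator_id = rep(ids, lengths(trains)),
    spike_time_ms = unlist(trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
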