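#' Electrode specification for the LFP forward model
#'
#' A laminar column of point electrodes spanning stratum oriens to stratum
#' lacunosum-moleculare, in a homogeneous isotropic volume conductor.
#'
#' @param positions matrix with columns `x` and `depth` (um); depths must be
#'   strictly ordered.
#' @param sigma extracellular conductivity, S/m.
#' @return object of class `electrode_spec`.
#' @export
electrode_spec <- function(positions, sigma = 0.3) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "depth")
  stopifnot(sigma > 0, nrow(positions) >= 2,
            all(diff(positions[, "depth"]) > 0) ||
              all(diff(positions[, "depth"]) < 0))
  structure(list(positions = positions, sigma = sigma),
            class = "electrode_spec")
}

#' Linear volume-conductor LFP
#'
#' Computes extracellular potentials from transmembrane currents by the
#' point-source linear approximation,
#' \deqn{\phi(e, t) = \sum_k \frac{I_k(t)}{4 \pi \sigma r_{ek}},}
#' with distances clamped from below so an electrode cannot coincide with a
#' source.  With currents in nA, distances in um and conductivity in S/m the
#' result is in mV.  In the model only pyramidal cells contribute: the field
#' is formed by the summed membrane currents of the aligned pyramidal
#' population.
#'
#' @param currents numeric matrix, time x sources, nA (outward positive).
#' @param source_positions matrix with columns x, depth (um), one row per
#'   source.
#' @param electrodes an `electrode_spec`.
#' @param min_distance distance clamp, um.
#' @param check check that currents sum to zero across sources at each time
#'   (current conservation over the contributing cells); violations warn.
#' @return numeric matrix, time x electrodes, mV.
#' @export
compute_lfp <- function(currents, source_positions, electrodes,
                        min_distance = 10, check = TRUE) {
  currents <- as.matrix(currents)
  sp <- as.matrix(source_positions)
  stopifnot(ncol(currents) == nrow(sp))
  if (check && ncol(currents) > 1) {
    tot <- rowSums(currents)
    ref <- mean(rowSums(abs(currents))) + 1e-12
    if (max(abs(tot)) > 1e-6 * ref)
      warning("source currents do not sum to zero (max residual ",
              signif(max(abs(tot)) / ref, 3), " relative)")
  }
  ep <- electrodes$positions
  K <- matrix(0, nrow(sp), nrow(ep))
  clamped <- FALSE
  for (j in seq_len(nrow(ep))) {
    r <- sqrt((sp[, 1] - ep[j, 1])^2 + (sp[, 2] - ep[j, 2])^2)
    if (any(r < min_distance)) clamped <- TRUE
    r <- pmax(r, min_distance)
    K[, j] <- 1 / (4 * pi * electrodes$sigma * r)
  }
  if (clamped)
    warning("electrode within ", min_distance,
            " um of a source; distance clamped")
  currents %*% K
}

#' Export one LFP trace as CSV
#' @param recording a `ca1_recording` with an LFP.
#' @param electrode electrode index.
#' @param path output file.
#' @export
export_lfp_csv <- function(recording, electrode, path) {
  stopifnot(!is.null(recording$lfp))
  utils::write.csv(data.frame(time_ms = recording$time,
                              lfp_mV = recording$lfp[, electrode]),
                   path, row.names = FALSE)
  invisible(path)
}
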