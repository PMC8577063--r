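#' Frequency band definitions
#'
#' Default analysis bands: theta 4-12 Hz, slow gamma 30-50 Hz, middle gamma
#' 50-90 Hz, fast gamma 90-150 Hz, ripple 110-200 Hz.
#'
#' @param params parameter list.
#' @return named list of `c(low, high)` pairs, Hz.
#' @export
band_defaults <- function(params = ca1_defaults()) {
  lapply(params$bands, function(b) c(low = b[[1]], high = b[[2]]))
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed, half-overlapping segments.
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length, s.
#' @param pad zero-padding factor for a finer frequency grid.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 8, pad = 1) {
  x <- as.numeric(x) - mean(x)
  nseg <- min(length(x), round(seg_s * fs))
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  nfft <- nseg * pad
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    X <- fft(c(seg, numeric(nfft - nseg)))
    acc <- acc + Mod(X[seq_along(acc)])^2
  }
  data.frame(freq = (seq_along(acc) - 1) * fs / nfft,
             power = acc / length(starts) / sum(w^2) / fs)
}

# frequency of the maximum PSD value within [lo, hi] Hz
psd_peak <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  psd$freq[sel][which.max(psd$power[sel])]
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the passband is traversed with zero phase distortion -- phase
#' estimates downstream are unbiased.
#'
#' @param x signal.
#' @param band `c(low, high)` Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order (per pass).
#' @return filtered signal.
#' @export
bandpass <- function(x, band, fs, order = 4) {
  lo <- band[[1]]; hi <- band[[2]]
  stopifnot(lo > 0, lo < hi)
  if (hi >= fs / 2) stop("band (", lo, ", ", hi, ") Hz violates the Nyquist
 frequency ", fs / 2, " Hz")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, as.numeric(x))
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Analytic-signal (Hilbert) phase in degrees with the convention 0 deg at
#' the local maxima (peak) and 180 deg at the minima (trough); the
#' descending flank is (0, 180) and the ascending flank (180, 360).
#'
#' @param x band-limited signal.
#' @return phase series in degrees, `[0, 360)`.
#' @export
instantaneous_phase <- function(x) {
  (Arg(analytic_signal(x)) * 180 / pi) %% 360
}

#' Instantaneous amplitude (envelope)
#' @param x band-limited signal.
#' @return envelope of `x`.
#' @export
instantaneous_amplitude <- function(x) Mod(analytic_signal(x))

# circular helpers (degrees)
circ_mean_deg <- function(deg) {
  (Arg(mean(exp(1i * deg * pi / 180))) * 180 / pi) %% 360
}
circ_r <- function(deg) Mod(mean(exp(1i * deg * pi / 180)))

rayleigh_p <- function(deg) {
  n <- length(deg)
  R <- circ_r(deg)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

# circular-safe phase interpolation: interpolate the unit phasor
phase_at_times <- function(times, phase_deg, time_base) {
  z <- exp(1i * phase_deg * pi / 180)
  re <- approx(time_base, Re(z), times, rule = 2)$y
  im <- approx(time_base, Im(z), times, rule = 2)$y
  (atan2(im, re) * 180 / pi) %% 360
}

#' Spike-phase statistics
#'
#' Circular mean phase, resultant vector length and Rayleigh test of the
#' phases at which spikes occur.
#'
#' @param spike_times ms.
#' @param phase phase series, degrees (e.g. from [instantaneous_phase()]).
#' @param time time base of `phase`, ms.
#' @return list: `n`, `preferred_deg`, `vector_length`, `p_rayleigh`,
#'   `p_reliable` (FALSE when fewer than 10 spikes), `phases`.
#' @export
spike_phase_stats <- function(spike_times, phase, time) {
  ph <- phase_at_times(spike_times, phase, time)
  n <- length(ph)
  list(n = n,
       preferred_deg = if (n > 0) circ_mean_deg(ph) else NA_real_,
       vector_length = if (n > 0) circ_r(ph) else NA_real_,
       p_rayleigh = if (n > 0) rayleigh_p(ph) else NA_real_,
       p_reliable = n >= 10,
       phases = ph)
}

#' Phase-amplitude modulation index
#'
#' Tort-style normalized Kullback-Leibler modulation index: the mean
#' amplitude is binned by phase, normalized to a distribution P, and
#' \eqn{MI = KL(P \| U) / \log(n_{bins})} with the convention
#' \eqn{0 \log 0 = 0}.  MI is 0 for phase-independent amplitude and 1 when
#' all amplitude mass falls in a single bin.
#'
#' @param phase phase series, degrees.
#' @param amplitude amplitude series, same length.
#' @param n_bins number of phase bins.
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude))
  bins <- pmin(n_bins, floor(phase %% 360 / (360 / n_bins)) + 1)
  mean_amp <- vapply(seq_len(n_bins), function(b) {
    v <- amplitude[bins == b]
    if (length(v) == 0) 0 else mean(v)
  }, 0)
  if (sum(mean_amp) <= 0) return(0)
  P <- mean_amp / sum(mean_amp)
  kl <- sum(ifelse(P > 0, P * log(P * n_bins), 0))
  kl / log(n_bins)
}

#' n:m phase-phase coupling test
#'
#' For each acceleration factor m, the theta phase is multiplied by m and
#' compared with the phase of the band centered at `m * f_theta` (width
#' +/- `f_theta / 2`):
#' \eqn{R(m) = |\langle e^{i(m\varphi_\theta - \varphi_m)}\rangle|}.
#' Significance thresholds are the 95th percentile of R over surrogates in
#' which the fast phase is circularly time-shifted by at least
#' `min_shift_s`.  The theta frequency used for band centering is the mean
#' instantaneous frequency of the supplied theta phase.
#'
#' @param theta_phase theta phase series, degrees (from the same signal's
#'   theta band).
#' @param x broadband signal.
#' @param fs Hz.
#' @param m_range integer vector of accelerations.
#' @param n_surrogates surrogate count.
#' @param min_shift_s minimum circular shift, s.
#' @param seed seed for surrogate shifts.
#' @return data.frame: `m`, `R`, `threshold95`, `significant`, `skipped`.
#' @export
nm_coupling <- function(theta_phase, x, fs, m_range = 1:12,
                        n_surrogates = 200, min_shift_s = 1, seed = 1) {
  n <- length(x)
  dphi <- diff(theta_phase) %% 360
  dphi <- ifelse(dphi > 180, dphi - 360, dphi)
  f_theta <- mean(dphi) / 360 * fs
  zt <- exp(1i * theta_phase * pi / 180)
  shift_min <- round(min_shift_s * fs)
  shifts <- with_seed(seed,
                      sample(seq(shift_min, n - shift_min), n_surrogates,
                             replace = TRUE))
  res <- lapply(m_range, function(m) {
    lo <- m * f_theta - f_theta / 2
    hi <- m * f_theta + f_theta / 2
    if (hi >= fs / 2)
      return(data.frame(m = m, R = NA_real_, threshold95 = NA_real_,
                        significant = FALSE, skipped = TRUE))
    phm <- instantaneous_phase(bandpass(x, c(lo, hi), fs))
    zm <- exp(-1i * phm * pi / 180)
    ztm <- zt^m
    R <- Mod(mean(ztm * zm))
    surr <- vapply(shifts, function(s)
      Mod(mean(ztm * zm[c((s + 1):n, 1:s)])), 0)
    thr <- quantile(surr, 0.95, names = FALSE)
    data.frame(m = m, R = R, threshold95 = thr,
               significant = R > thr, skipped = FALSE)
  })
  do.call(rbind, res)
}

# Morlet wavelet amplitude via frequency-domain Gaussian windows
morlet_amplitude <- function(x, fs, freqs, n_cycles = 7) {
  x <- as.numeric(x) - mean(x)
  n <- length(x)
  X <- fft(x)
  fgrid <- (seq_len(n) - 1) * fs / n
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sf <- f / n_cycles
    H <- 2 * exp(-(fgrid - f)^2 / (2 * sf^2)) # analytic: positive freqs only
    H[fgrid > fs / 2] <- 0
    out[i, ] <- Mod(fft(X * H, inverse = TRUE) / n)
  }
  out
}

#' Phase-frequency amplitude map
#'
#' Morlet wavelet amplitude on a frequency grid, averaged within theta-phase
#' bins and normalized so each frequency row sums to one; the map behind
#' amplitude-phase comodulograms.
#'
#' @param x LFP signal.
#' @param fs Hz.
#' @param freqs frequency grid, Hz.
#' @param n_phase_bins theta-phase bins.
#' @param theta_band theta band for the phase reference.
#' @return list: `map` (freq x phase bins, rows sum to 1), `freqs`,
#'   `phase_centers` (deg), `theta_phase`.
#' @export
amplitude_by_theta_phase <- function(x, fs, freqs = seq(20, 200, by = 4),
                                     n_phase_bins = 20,
                                     theta_band = c(4, 12)) {
  th_ph <- instantaneous_phase(bandpass(x, theta_band, fs))
  amp <- morlet_amplitude(x, fs, freqs)
  bins <- pmin(n_phase_bins, floor(th_ph / (360 / n_phase_bins)) + 1)
  map <- t(vapply(seq_len(nrow(amp)), function(i)
    vapply(seq_len(n_phase_bins), function(b) mean(amp[i, bins == b]), 0),
    numeric(n_phase_bins)))
  map <- map / pmax(rowSums(map), 1e-300)
  list(map = map, freqs = freqs,
       phase_centers = (seq_len(n_phase_bins) - 0.5) * 360 / n_phase_bins,
       theta_phase = th_ph)
}

#' Place-cell phase precession fit
#'
#' Circular-linear fit of spike theta phase against position within the
#' place field: the slope maximizing the resultant length of
#' `phase - slope * position` over a slope grid, with the circular mean of
#' the residuals as offset.  Negative slope indicates precession.
#'
#' @param spike_times ms.
#' @param positions position within the field in `[0, 1]`, one per spike.
#' @param phase theta phase series, degrees.
#' @param time time base of `phase`, ms.
#' @param slope_grid candidate slopes, degrees per unit position.
#' @return list: `slope_deg_per_unit`, `offset_deg`, `r` (circular-linear
#'   correlation), `R` (resultant length at the fitted slope), `n`.
#' @export
phase_precession <- function(spike_times, positions, phase, time,
                             slope_grid = seq(-720, 720, by = 1)) {
  if (length(spike_times) < 20)
    stop("phase precession fit refused: fewer than 20 spikes in the field")
  stopifnot(length(positions) == length(spike_times))
  ph <- phase_at_times(spike_times, phase, time)
  Rs <- vapply(slope_grid, function(s) circ_r(ph - s * positions), 0)
  best <- which.max(Rs)
  slope <- slope_grid[best]
  offset <- circ_mean_deg(ph - slope * positions)
  fit <- (slope * positions + offset) * pi / 180
  obs <- ph * pi / 180
  num <- sum(sin(obs - mean_circ(obs)) * sin(fit - mean_circ(fit)))
  den <- sqrt(sum(sin(obs - mean_circ(obs))^2) *
                sum(sin(fit - mean_circ(fit))^2))
  list(slope_deg_per_unit = slope, offset_deg = offset,
       r = if (den > 0) num / den else 0, R = Rs[best],
       n = length(spike_times))
}

mean_circ <- function(rad) Arg(mean(exp(1i * rad)))

#' Detect ripple events
#'
#' Events where the ripple-band envelope exceeds `mean + threshold_sd * SD`;
#' events separated by less than `merge_gap` ms are merged, and only events
#' with duration inside `[min_duration, max_duration]` ms are kept.  The
#' intra-event oscillation frequency is estimated from zero crossings of the
#' band-passed signal within the event.
#'
#' @param x LFP signal.
#' @param fs Hz.
#' @param band ripple band, Hz.
#' @param threshold_sd envelope threshold in baseline SDs.
#' @param min_duration,max_duration ms.
#' @param merge_gap ms.
#' @return data.frame: `start`, `end`, `duration` (ms), `peak_envelope`,
#'   `freq` (Hz); zero rows when nothing crosses threshold.
#' @export
detect_ripples <- function(x, fs, band = c(110, 200), threshold_sd = 3,
                           min_duration = 30, max_duration = 300,
                           merge_gap = 10) {
  if (length(x) < 10 * fs)
    warning("less than 10 s of signal; ripple baseline may be unstable")
  filt <- bandpass(x, band, fs)
  env <- instantaneous_amplitude(filt)
  thr <- mean(env) + threshold_sd * sd(env)
  above <- env > thr
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peak_envelope = numeric(0),
                      freq = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- cbind(starts[r$values], ends[r$values])
  # merge events separated by short gaps
  if (nrow(ev) > 1) {
    keep <- list(ev[1, ])
    for (i in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if ((ev[i, 1] - last[2]) / fs * 1000 < merge_gap)
        keep[[length(keep)]] <- c(last[1], ev[i, 2])
      else keep[[length(keep) + 1]] <- ev[i, ]
    }
    ev <- do.call(rbind, keep)
  }
  out <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- ev[i, 1]; i1 <- ev[i, 2]
    dur <- (i1 - i0 + 1) / fs * 1000
    seg <- filt[i0:i1]
    zc <- sum(diff(sign(seg)) != 0)
    data.frame(start = i0 / fs * 1000, end = i1 / fs * 1000,
               duration = dur, peak_envelope = max(env[i0:i1]),
               freq = zc / 2 / (dur / 1000))
  })
  out <- do.call(rbind, out)
  out <- out[out$duration >= min_duration & out$duration <= max_duration, ,
             drop = FALSE]
  if (nrow(out) == 0) empty else out
}

#' Deterministic synthetic LFP fixture
#'
#' Composite test signal with known ground truth, used to exercise the
#' analysis battery without running the network: a theta carrier plus
#' optional faster components that can be phase-locked to theta (exact n:m
#' locking), gated by a theta-phase window, or confined to explicit burst
#' windows, plus white noise.
#'
#' @param spec list with fields `fs` (Hz), `duration` (ms), `theta`
#'   (`list(freq, amp)`), `noise_sd`, and `components`: each a list with
#'   `freq`, `amp`, and optionally `phase_lock = TRUE`, `gate =
#'   list(center_deg, width_deg)`, or `bursts = list(c(start, end), ...)`
#'   (ms).
#' @param seed integer for the noise draw.
#' @return list: `signal`, `time` (ms), `fs`, `theta_phase_true` (deg),
#'   `annotations` (per component gate/burst windows as logical masks).
#' @export
synth_lfp_fixture <- function(spec, seed = 1) {
  fs <- if (is.null(spec$fs)) 1000 else spec$fs
  dur <- if (is.null(spec$duration)) 20000 else spec$duration
  th <- modifyList(list(freq = 7, amp = 1), if (is.null(spec$theta)) list()
                   else spec$theta)
  n <- round(dur * fs / 1000)
  t_ms <- seq_len(n) / fs * 1000
  theta_arg <- 2 * pi * th$freq * t_ms / 1000
  x <- th$amp * cos(theta_arg)
  ann <- list()
  for (k in seq_along(spec$components)) {
    cp <- spec$components[[k]]
    arg <- if (isTRUE(cp$phase_lock)) (cp$freq / th$freq) * theta_arg
           else 2 * pi * cp$freq * t_ms / 1000
    envk <- rep(1, n)
    if (!is.null(cp$gate)) {
      d <- cos(theta_arg - cp$gate$center_deg * pi / 180)
      kappa <- (360 / cp$gate$width_deg)^2 / 4
      envk <- exp(kappa * (d - 1))
    }
    if (!is.null(cp$bursts)) {
      envk <- rep(0, n)
      for (b in cp$bursts) envk[t_ms >= b[1] & t_ms <= b[2]] <- 1
    }
    x <- x + cp$amp * envk * cos(arg)
    ann[[k]] <- list(freq = cp$freq, active = envk > 0.5)
  }
  if (!is.null(spec$noise_sd) && spec$noise_sd > 0)
    x <- x + with_seed(seed, rnorm(n, 0, spec$noise_sd))
  list(signal = x, time = t_ms, fs = fs,
       theta_phase_true = (theta_arg * 180 / pi) %% 360,
       annotations = ann)
}

#' Theta cycle index per sample
#'
#' Segments a phase series into cycles at the 360 -> 0 wrap (peak to peak).
#'
#' @param phase phase series, degrees.
#' @return integer cycle index per sample, starting at 1.
#' @export
theta_cycles <- function(phase) {
  cumsum(c(TRUE, diff(phase) < -180))
}

#' Rhythm-analysis report for a recording
#'
#' Runs the analysis battery on the pyramidal-layer LFP of a recording:
#' per-population spike-phase statistics against theta, modulation index of
#' each gamma band by theta phase, the n:m phase-phase curve, the
#' phase-frequency amplitude map, and (for non-theta recordings) ripple
#' events.
#'
#' @param recording a `ca1_recording` with an LFP.
#' @param params parameter list (band definitions).
#' @param n_surrogates surrogates for the n:m test.
#' @return list of class `coupling_result`.
#' @export
analyze_recording <- function(recording, params = ca1_defaults(),
                              n_surrogates = 200) {
  lfp <- pyramidal_lfp(recording)
  fs <- recording$fs
  bands <- band_defaults(params)
  th <- bandpass(lfp, bands$theta, fs)
  th_ph <- instantaneous_phase(th)
  pops <- unique(recording$spikes$pop)
  phase_stats <- lapply(setNames(pops, pops), function(p) {
    st <- spike_phase_stats(population_spikes(recording, p), th_ph,
                            recording$time)
    st$phases <- NULL
    st
  })
  mi <- lapply(bands[c("slow_gamma", "middle_gamma", "fast_gamma")],
               function(b) {
                 amp <- instantaneous_amplitude(bandpass(lfp, b, fs))
                 modulation_index(th_ph, amp)
               })
  nm <- nm_coupling(th_ph, lfp, fs, n_surrogates = n_surrogates)
  apf <- amplitude_by_theta_phase(lfp, fs)
  ripples <- if (recording$state == "non_theta")
    detect_ripples(lfp, fs, band = bands$ripple) else NULL
  structure(list(phase_stats = phase_stats, modulation_index = mi,
                 nm = nm, amplitude_map = apf[c("map", "freqs",
                                                "phase_centers")],
                 ripples = ripples, state = recording$state),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result>", x$state, "state\n  preferred theta phases:\n")
  for (p in names(x$phase_stats)) {
    s <- x$phase_stats[[p]]
    cat(sprintf("    %-7s n=%6d  phase %6.1f deg  R=%.2f\n", p, s$n,
                s$preferred_deg, s$vector_length))
  }
  cat("  MI:", paste(names(x$modulation_index),
                     signif(unlist(x$modulation_index), 3),
                     sep = "=", collapse = " "), "\n")
  sig <- x$nm$m[which(x$nm$significant)]
  cat("  significant n:m accelerations:", paste(sig, collapse = ", "), "\n")
  invisible(x)
}
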