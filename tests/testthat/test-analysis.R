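fs <- 1000

test_that("bandpass: passband flat, stopband deep, zero phase", {
  t <- seq(0, 20, by = 1 / fs)[-1]
  x7 <- sin(2 * pi * 7 * t)
  y <- bandpass(x7, c(4, 12), fs)
  mid <- 2000:18000
  expect_lt(abs(sd(y[mid]) / sd(x7[mid]) - 1), 0.05)
  x60 <- sin(2 * pi * 60 * t)
  expect_lt(sd(bandpass(x60, c(4, 12), fs)[mid]), sd(x60) / 20)
  # forward-backward (zero-phase) symmetry; signal::filtfilt handles edges
  # by zero-padding, which leaves a ~3e-4 residual, so the identity is
  # asserted at 0.1% of the unit amplitude
  xr <- rev(x7)
  yr <- rev(bandpass(xr, c(4, 12), fs))
  expect_lt(max(abs((yr - y)[8000:12000])), 1e-3)
  expect_error(bandpass(x7, c(400, 600), fs), "Nyquist")
})

test_that("instantaneous phase anchors 0 at peaks, 180 at troughs", {
  t <- seq(0, 5, by = 1 / fs)[-1]
  x <- cos(2 * pi * 7 * t)
  ph <- instantaneous_phase(x)
  i_pk <- which.max(x[100:4900]) + 99
  i_tr <- which.min(x[100:4900]) + 99
  expect_lt(min(ph[i_pk], 360 - ph[i_pk]), 5)
  expect_lt(abs(ph[i_tr] - 180), 5)
  # descending flank lies in (0, 180)
  i_desc <- i_pk + 18                      # quarter period after a peak
  expect_true(ph[i_desc] > 0 && ph[i_desc] < 180)
  # unwrapped phase advances 7 cycles per second
  d <- diff(ph[1000:2000]) %% 360
  expect_equal(sum(ifelse(d > 180, d - 360, d)), 7 * 360, tolerance = 2)
})

test_that("spike-phase statistics: degenerate, null and von Mises cases", {
  tb <- seq(1, 10000)
  ph <- (7 * 360 * tb / 1000) %% 360
  # all spikes at phase 90
  t90 <- tb[abs(ph - 90) < 1.3][1:20]
  st <- spike_phase_stats(t90, ph, tb)
  expect_equal(st$preferred_deg, 90, tolerance = 2)
  expect_gt(st$vector_length, 0.99)
  # uniform phases
  set.seed(2)
  tu <- runif(1e4, 1, 1e4)
  stu <- spike_phase_stats(tu, ph, tb)
  expect_lt(stu$vector_length, 0.05)
  expect_gt(stu$p_rayleigh, 0.05)
  # von Mises sample recovered against a circular-mean oracle on the sample
  set.seed(3)
  vm <- (180 + 180 / pi * vapply(1:1000, function(i) {
    repeat {
      th <- runif(1, -pi, pi)
      if (runif(1) < exp(cos(th) - 1)) return(th)  # von Mises, kappa = 1
    }
  }, 0)) %% 360
  tvm <- vapply(vm, function(p) tb[which.min(abs(ph - p))], 0)
  stv <- spike_phase_stats(tvm, ph, tb)
  oracle <- (Arg(mean(exp(1i * vm * pi / 180))) * 180 / pi) %% 360
  expect_lt(abs(stv$preferred_deg - 180), 10)
  expect_equal(stv$preferred_deg, oracle, tolerance = 2)
  # few spikes flagged unreliable
  expect_false(spike_phase_stats(t90[1:5], ph, tb)$p_reliable)
})

test_that("modulation index: null, maximum and gated fixture", {
  set.seed(4)
  ph <- runif(1e5, 0, 360)
  expect_lt(modulation_index(ph, rexp(1e5)), 0.01)
  # all amplitude in one bin -> MI = 1
  amp <- as.numeric(ph >= 40 & ph < 60)
  expect_equal(modulation_index(ph, amp), 1)
  # theta-gated 35 Hz bursts beat phase-shuffled surrogates
  fx <- synth_lfp_fixture(list(duration = 30000, theta = list(freq = 7, amp = 1),
                               components = list(list(freq = 35, amp = 0.5,
                                                      gate = list(center_deg = 90,
                                                                  width_deg = 90))),
                               noise_sd = 0.1), seed = 5)
  thp <- instantaneous_phase(bandpass(fx$signal, c(4, 12), fs))
  amp35 <- instantaneous_amplitude(bandpass(fx$signal, c(30, 50), fs))
  mi <- modulation_index(thp, amp35)
  n <- length(thp)
  # the fixture is strictly periodic, so time shifts preserve coupling;
  # phase-shuffled surrogates destroy it
  surr <- vapply(1:200, function(i) modulation_index(sample(thp), amp35), 0)
  expect_gt(mi, quantile(surr, 0.95))
})

test_that("n:m test peaks at the phase-locked accelerations only", {
  fx <- synth_lfp_fixture(list(duration = 30000, theta = list(freq = 7, amp = 1),
                               components = list(
                                 list(freq = 35, amp = 0.4, phase_lock = TRUE),
                                 list(freq = 63, amp = 0.3, phase_lock = TRUE)),
                               noise_sd = 0.05), seed = 6)
  thp <- instantaneous_phase(bandpass(fx$signal, c(4, 12), fs))
  nm <- nm_coupling(thp, fx$signal, fs, n_surrogates = 100)
  sig <- nm$m[which(nm$significant)]
  expect_true(all(c(5, 9) %in% sig))
  expect_true(all(nm$R <= 1 & nm$R >= 0, na.rm = TRUE))
  # amplitude scaling leaves the peak locations unchanged
  nm2 <- nm_coupling(thp, 5 * fx$signal, fs, n_surrogates = 100)
  expect_equal(order(-nm2$R)[1:2], order(-nm$R)[1:2])
  # independent band-limited noise: no significant coupling anywhere
  set.seed(7)
  noise <- bandpass(rnorm(30000), c(4, 12), fs) +
    bandpass(rnorm(30000), c(30, 50), fs)
  thn <- instantaneous_phase(bandpass(noise, c(4, 12), fs))
  indep <- bandpass(rnorm(30000), c(25, 80), fs)
  nmn <- nm_coupling(thn, indep, fs, n_surrogates = 100)
  expect_lt(sum(nmn$significant, na.rm = TRUE), 3)
})

test_that("phase-frequency amplitude map localizes gated bursts", {
  fx <- synth_lfp_fixture(list(duration = 30000, theta = list(freq = 7, amp = 1),
                               components = list(list(freq = 35, amp = 0.6,
                                                      gate = list(center_deg = 90,
                                                                  width_deg = 80))),
                               noise_sd = 0.05), seed = 8)
  m <- amplitude_by_theta_phase(fx$signal, fs, freqs = seq(20, 100, 5))
  expect_equal(rowSums(m$map), rep(1, nrow(m$map)), tolerance = 1e-9)
  row35 <- which.min(abs(m$freqs - 35))
  peak_phase <- m$phase_centers[which.max(m$map[row35, ])]
  expect_true(peak_phase > 0 && peak_phase < 180)   # descending flank
})

test_that("phase precession fit recovers a known slope", {
  tb <- seq(1, 60000)
  ph <- (7 * 360 * tb / 1000) %% 360
  set.seed(9)
  x <- runif(300)
  target <- (360 - 180 * x) %% 360
  tt <- vapply(seq_along(x), function(i) {
    cand <- which(abs(ph - target[i]) < 0.5)
    cand[sample(length(cand), 1)]
  }, 0)
  fit <- phase_precession(tt, x, ph, tb)
  expect_lt(abs(fit$slope_deg_per_unit - (-180)), 10)
  # invariant to adding full turns to all phases (same spikes, shifted base)
  fit2 <- phase_precession(tt, x, (ph + 360) %% 360, tb)
  expect_equal(fit2$slope_deg_per_unit, fit$slope_deg_per_unit)
  # a flat phase-position relation has |slope| < 5
  tflat <- tb[abs(ph - 120) < 0.3][1:50]
  fitf <- phase_precession(tflat, runif(50), ph, tb)
  expect_lt(abs(fitf$slope_deg_per_unit), 5)
  expect_error(phase_precession(tt[1:10], x[1:10], ph, tb), "fewer than 20")
})

test_that("ripple detector finds planted events and nothing else", {
  # pure theta-band signal: no events
  t <- seq(1 / fs, 20, by = 1 / fs)
  expect_equal(nrow(detect_ripples(cos(2 * pi * 7 * t), fs)), 0)

  fx <- synth_lfp_fixture(list(duration = 20000, theta = list(freq = 7, amp = 0.3),
                               components = list(list(freq = 170, amp = 1,
                                                      bursts = list(c(10000, 10100)))),
                               noise_sd = 0.05), seed = 10)
  ev <- detect_ripples(fx$signal, fs)
  expect_equal(nrow(ev), 1)
  expect_true(ev$duration >= 80 && ev$duration <= 120)
  expect_lt(abs(ev$freq - 170), 10)

  fx2 <- synth_lfp_fixture(list(duration = 20000, theta = list(freq = 7, amp = 0.3),
                                components = list(list(freq = 170, amp = 1,
                                                       bursts = list(c(8000, 8100),
                                                                     c(8600, 8700)))),
                                noise_sd = 0.05), seed = 11)
  expect_equal(nrow(detect_ripples(fx2$signal, fs)), 2)
})

test_that("ripple detection is reliable across fixture seeds at SNR >= 3", {
  hits <- vapply(1:50, function(s) {
    fx <- synth_lfp_fixture(list(duration = 15000,
                                 theta = list(freq = 7, amp = 0.3),
                                 components = list(list(freq = 170, amp = 0.9,
                                                        bursts = list(c(7000, 7100)))),
                                 noise_sd = 0.15), seed = s)
    nrow(detect_ripples(fx$signal, fs)) == 1
  }, NA)
  expect_gte(mean(hits), 0.98)
})

test_that("coupling statistics stay bounded under fuzzing", {
  set.seed(12)
  for (k in 1:5) {
    x <- rnorm(8000) + sin(2 * pi * runif(1, 5, 9) * seq_len(8000) / fs)
    thp <- instantaneous_phase(bandpass(x, c(4, 12), fs))
    amp <- instantaneous_amplitude(bandpass(x, c(30, 50), fs))
    expect_true(modulation_index(thp, amp) >= 0 &&
                  modulation_index(thp, amp) <= 1)
    nm <- nm_coupling(thp, x, fs, m_range = c(2, 5), n_surrogates = 20)
    expect_true(all(nm$R >= 0 & nm$R <= 1, na.rm = TRUE))
  }
})

test_that("synthetic fixture is deterministic with faithful annotations", {
  spec <- list(duration = 5000, theta = list(freq = 7, amp = 1),
               components = list(list(freq = 35, amp = 0.5,
                                      gate = list(center_deg = 90,
                                                  width_deg = 60))),
               noise_sd = 0.1)
  f1 <- synth_lfp_fixture(spec, seed = 20)
  f2 <- synth_lfp_fixture(spec, seed = 20)
  expect_identical(f1$signal, f2$signal)
  # theta-only fixture: recovered phase matches the generating ramp
  f3 <- synth_lfp_fixture(list(duration = 10000, theta = list(freq = 7, amp = 1)),
                          seed = 1)
  ph <- instantaneous_phase(f3$signal)
  mid <- 1000:9000
  d <- (ph[mid] - f3$theta_phase_true[mid]) %% 360
  expect_lt(max(pmin(d, 360 - d)), 3)
  # gate annotations mark where the gated component is active
  act <- f1$annotations[[1]]$active
  gate_phase <- f1$theta_phase_true[act]
  dd <- abs(((gate_phase - 90 + 180) %% 360) - 180)
  expect_lt(max(dd), 60)
})
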