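test_that("rate function: unmodulated, spectral content, envelope pairing", {
  flat <- generator_spec("ca3_nonspatial", 10)
  expect_equal(rate_function(flat, seq(0, 1000, 10)), rep(10, 101))

  # CA3 spatial default: Fourier components at exactly 7 and 35 Hz
  spec <- flat_ca3_spec()
  tt <- seq(0, 1e6 - 1, 1)       # 1000 s at 1 ms
  r <- rate_function(spec, tt)
  z <- function(f) Mod(mean((r - mean(r)) * exp(-2i * pi * f * tt / 1000)))
  expect_gt(z(7), 100 * z(11))
  expect_gt(z(35), 100 * z(31))

  # MEC envelope center leads the CA3 center of the same track position by
  # the configured lag (a CA3 place cell at position x peaks at x * duration)
  p <- ca1_defaults()
  ens <- build_input_ensemble(state_config("theta"), scale = 0.01, seed = 1,
                              duration = 20000)
  for (mec in Filter(function(g) g$source == "mec", ens)) {
    expect_equal(mec$place_position * 20000 - mec$envelope_center,
                 p$generators$mec$mec_lead)
  }
})

test_that("thinning sampler is a faithful inhomogeneous Poisson draw", {
  empty <- generator_spec("ca3_nonspatial", 0)
  expect_length(sample_spike_train(empty, 1000, seed = 1), 0)

  flat <- generator_spec("ca3_nonspatial", 10)
  n <- length(sample_spike_train(flat, 1e5, seed = 3))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))

  # window counts match a 1 ms binned Bernoulli oracle simulation
  spec <- flat_ca3_spec()
  counts_thin <- vapply(1:500, function(i) {
    sum(sample_spike_train(spec, 100, seed = i) > 0)
  }, 0)
  counts_oracle <- vapply(1:500, function(i) {
    set.seed(1e6 + i)
    tt <- seq(0.5, 99.5, 1)
    sum(runif(100) < rate_function(spec, tt) / 1000)
  }, 0)
  ks <- suppressWarnings(ks.test(counts_thin, counts_oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("time-rescaled inter-spike intervals are Exp(1)", {
  spec <- flat_ca3_spec()
  rescaled <- unlist(lapply(1:200, function(i) {
    st <- sample_spike_train(spec, 5000, seed = 40 + i)
    if (length(st) < 2) return(numeric(0))
    # integral of the rate between consecutive spikes (1 ms Riemann sum)
    lam <- rate_function(spec, seq(0.5, 4999.5, 1)) / 1000
    L <- c(0, cumsum(lam))
    diff(L[pmin(floor(st) + 1, length(L))])
  }))
  ks <- suppressWarnings(ks.test(rescaled, "pexp"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensembles respect the state configuration and are deterministic", {
  th <- build_input_ensemble(state_config("theta"), scale = 0.02, seed = 5)
  src <- vapply(th, `[[`, "", "source")
  expect_setequal(unique(src), c("ca3_spatial", "ca3_nonspatial", "mec",
                                 "ms_teevra"))
  nt <- build_input_ensemble(state_config("non_theta"), scale = 0.02, seed = 5)
  src_nt <- vapply(nt, `[[`, "", "source")
  expect_false(any(src_nt %in% c("mec", "ca3_nonspatial")))
  th2 <- build_input_ensemble(state_config("theta"), scale = 0.02, seed = 5)
  expect_identical(th, th2)
})

test_that("non-theta transform compresses, adds ripple, flattens Teevra", {
  sp <- generator_spec("ca3_spatial", 5, envelope_center = 4000,
                       envelope_width = 2000,
                       theta = list(freq = 7, depth = 0.6, phase = 0),
                       gamma = list(freq = 35, depth = 0.4))
  tr <- apply_nontheta_transform(sp)
  expect_equal(tr$envelope_width, 50)
  expect_equal(tr$ripple$freq, 170)
  expect_equal(tr$gamma$freq, 35)
  expect_equal(tr$theta$depth, 0)
  # envelope integral (expected count per pass) preserved: width/40, rate*40
  expect_equal(tr$mean_rate * tr$envelope_width, sp$mean_rate * sp$envelope_width)

  tv <- apply_nontheta_transform(generator_spec("ms_teevra", 25,
                                                theta = list(freq = 7,
                                                             depth = 0.9,
                                                             phase = 0)))
  expect_equal(tv$theta$depth, 0)
  expect_error(apply_nontheta_transform(generator_spec("mec", 5)), "mec")
})

test_that("pooled ensemble spectrum recovers theta and gamma within 0.5 Hz", {
  spec <- flat_ca3_spec()
  trains <- lapply(1:100, function(i) sample_spike_train(spec, 60000, seed = i))
  psd <- welch_psd(pooled_rate(trains, 60000), fs = 1000, seg_s = 8)
  sel <- psd$freq > 1 & psd$freq < 20
  expect_lt(abs(psd$freq[sel][which.max(psd$power[sel])] - 7), 0.5)
  sel <- psd$freq >= 20 & psd$freq <= 50
  expect_lt(abs(psd$freq[sel][which.max(psd$power[sel])] - 35), 0.5)
})
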