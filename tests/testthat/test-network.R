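test_that("spatial weight profiles: peak, symmetry, distal inhibition", {
  expect_equal(spatial_weight("gaussian", 0), 1)
  d <- seq(-0.5, 0.5, 0.05)
  expect_equal(spatial_weight("gaussian", d), spatial_weight("gaussian", -d))
  expect_equal(spatial_weight("inverted_gaussian", d),
               spatial_weight("inverted_gaussian", -d))
  # PV baskets inhibit mainly distant pyramidal cells
  expect_lt(spatial_weight("inverted_gaussian", 0, sigma = 0.1),
            spatial_weight("inverted_gaussian", 0.3, sigma = 0.1))
  expect_error(spatial_weight("gaussian", Inf))
})

test_that("full-scale census matches the model composition", {
  n <- population_sizes(1)
  expect_equal(n[["pyr"]], 9000L)
  expect_equal(n[["pvbas"]], 200L)
  expect_equal(n[["cckbas"]], 160L)
  expect_equal(n[["aac"]], 60L)
  expect_equal(n[["bis"]], 70L)
  expect_equal(n[["olm"]], 80L)
  expect_equal(n[["ngf"]], 130L)
  expect_equal(n[["ivy"]], 260L)
  expect_equal(n[["sca"]], 40L)
  # spatially modulated and unmodulated pyramidal cells interleave 1:1
  pop <- build_populations(1)
  expect_equal(sum(pop$pyr_spatial), 4500L)
})

test_that("network build is deterministic in (config, seed)", {
  n1 <- build_network(tiny_config(), seed = 11)
  n2 <- build_network(tiny_config(), seed = 11)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$gap_junctions, n2$gap_junctions)
  n3 <- build_network(tiny_config(), seed = 12)
  expect_false(identical(n1$edges, n3$edges))
})

test_that("realized edge counts follow the Bernoulli wiring law", {
  # pvbas -> pyr at scale 0.05: N_pre x N_post pairs, probability p
  p <- ca1_defaults()
  rule <- Filter(function(r) r$pre == "pvbas" && r$post == "pyr",
                 p$connections)[[1]]
  n_pair <- 10 * 450
  counts <- vapply(1:20, function(s) {
    net <- build_network(list(scale = 0.05, duration = 1000), seed = 100 + s)
    sum(net$edges$post_pop == "pyr" &
          net$edges$pre >= net$populations$offsets[["pvbas"]] &
          net$edges$pre < net$populations$offsets[["pvbas"]] + 10)
  }, 0)
  expect_lt(abs(mean(counts) - rule$p * n_pair),
            3 * sqrt(rule$p * (1 - rule$p) * n_pair) / sqrt(20))
})

test_that("a disconnected, undriven network stays silent", {
  p <- ca1_defaults()
  p$connections <- lapply(p$connections, function(r) { r$w <- 0; r$w_sd <- 0; r })
  p$drives <- list()
  net <- build_network(list(scale = 0.01, duration = 1000,
                            params = list(connections = p$connections,
                                          drives = list())), seed = 1)
  net$config$params$drives <- list()
  rec <- suppressWarnings(run_simulation(net, seed = 1))
  expect_equal(nrow(rec$spikes), 0)
})

test_that("simulation is reproducible and dt-convergent", {
  net <- build_network(tiny_config(duration = 1500), seed = 3)
  r1 <- suppressWarnings(run_simulation(net, seed = 3))
  r2 <- suppressWarnings(run_simulation(net, seed = 3))
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$lfp, r2$lfp)

  # dt convergence while trajectories still shadow (chaotic divergence
  # accumulates later in any network integrator): every early spike of the
  # coarse run has a fine-run partner within 0.5 ms
  r3 <- suppressWarnings(run_simulation(net, dt = 0.05, seed = 3))
  s1 <- sort(r1$spikes$t[r1$spikes$pop == "pyr" & r1$spikes$t < 200])
  s3 <- sort(r3$spikes$t[r3$spikes$pop == "pyr" & r3$spikes$t < 250])
  expect_gt(length(s1), 0)
  nearest <- vapply(s1, function(t) min(abs(s3 - t)), 0)
  expect_lte(max(nearest), 0.5)
})

test_that("reduced-scale weights are rescaled with a cap", {
  p <- ca1_defaults()
  cap <- p$network$weight_rescale_cap
  rule <- Filter(function(r) r$pre == "cckbas" && r$post == "pyr",
                 p$connections)[[1]]
  net <- build_network(list(scale = 0.02, duration = 1000), seed = 2)
  w <- net$edges$w[net$edges$post_pop == "pyr" &
                     net$edges$pre >= net$populations$offsets[["cckbas"]] &
                     net$edges$pre < net$populations$offsets[["cckbas"]] +
                       net$populations$sizes[["cckbas"]]]
  # 1/scale = 50 exceeds the cap, so the multiplier is the cap itself
  expect_lt(abs(mean(w) / (rule$w * cap) - 1), 0.25)
})
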