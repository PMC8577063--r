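test_that("pyramidal template spans the laminar axis at the declared depths", {
  pyr <- build_cell("pyr")
  labs <- vapply(pyr$compartments, `[[`, "", "label")
  depths <- vapply(pyr$compartments, `[[`, 0, "depth")
  expect_setequal(labs, c("soma", "basal", "rad-proximal", "rad-distal", "lm"))
  expect_equal(depths[match(c("soma", "basal", "rad-proximal", "rad-distal",
                              "lm"), labs)],
               c(0, 100, -100, -250, -400))
})

test_that("fast-spiking basket template is perisomatic only", {
  pv <- build_cell("pvbas")
  labs <- vapply(pv$compartments, `[[`, "", "label")
  expect_false("lm" %in% labs)
  expect_true(length(pv$compartments) <= 2)
})

test_that("unknown cell types are rejected with the valid list", {
  expect_error(build_cell("unicorn"), "unicorn")
  expect_error(build_cell("unicorn"), "pyr")
})

test_that("a passive compartment at its leak reversal is a fixed point", {
  cell <- passive_cell(-65)
  st <- init_cell_state(cell, v = -65)
  out <- membrane_step(cell, st, 0, dt = 0.1)
  expect_equal(out$state$V, -65, tolerance = 1e-12)
  expect_false(out$spike)
})

test_that("axial current vanishes between identical equipotential compartments", {
  cell <- two_comp_cell()
  st <- init_cell_state(cell, v = -60)
  out <- membrane_step(cell, st, c(0, 0), dt = 0.1)
  # both compartments relax identically: any axial flow would break symmetry
  expect_equal(out$state$V[1], out$state$V[2], tolerance = 1e-12)
})

test_that("non-finite state is rejected naming the compartment", {
  cell <- passive_cell()
  st <- init_cell_state(cell)
  st$V[1] <- NaN
  expect_error(membrane_step(cell, st, 0), "compartment 1")
})

test_that("spike counts match a fine-step reference integration", {
  cck <- build_cell("cckbas")   # single-compartment soma
  n_coarse <- length(run_cell(cck, 0.028, 500, dt = 0.1)$spike_times)
  n_fine <- length(run_cell(cck, 0.028, 500, dt = 0.001)$spike_times)
  expect_lte(abs(n_coarse - n_fine), 1)
})

test_that("halving dt shifts spike times by less than 0.5 ms per spike", {
  pyr <- build_cell("pyr")
  s1 <- run_cell(pyr, 0.15, 2000, dt = 0.1)$spike_times
  s2 <- run_cell(pyr, 0.15, 2000, dt = 0.05)$spike_times
  n <- min(length(s1), length(s2))
  expect_gt(n, 5)
  expect_lt(abs(s1[1] - s2[1]), 0.5)
  # per-spike comparison: successive inter-spike intervals agree
  expect_lt(mean(abs(diff(s1[1:n]) - diff(s2[1:n]))), 0.5)
})

test_that("gating variables stay in [0, 1] under random drive", {
  cell <- build_cell("pyr")
  arr_n <- length(cell$compartments)
  st <- init_cell_state(cell)
  set.seed(42)
  for (k in 1:200) {
    I <- rnorm(arr_n, 0, 0.03)
    net <- ca1rhythms:::single_cell_net(cell, I, 0.1, 5000L, state = st)
    res <- ca1rhythms:::.sim_core(net)
    st <- res$state
    gates <- c(st$m, st$h, st$n, st$mkm, st$qh)
    expect_true(all(gates >= 0 & gates <= 1))
    st$last_spike <- st$last_spike
  }
})

test_that("rest is drift-free after settling", {
  pyr <- build_cell("pyr")
  settle <- run_cell(pyr, 0, 5000)$state
  cell_net <- ca1rhythms:::single_cell_net(pyr, rep(0, 5), 0.1, 100000L,
                                           state = settle, record_vm = TRUE)
  vm <- ca1rhythms:::.sim_core(cell_net)$vm
  expect_lt(max(abs(vm[nrow(vm), ] - vm[1, ])), 0.01)
})

test_that("f-I curves behave: zero at rest, nondecreasing, fast-spiking max", {
  pyr <- build_cell("pyr")
  pv <- build_cell("pvbas")
  expect_error(fi_curve(pyr, numeric(0)), "empty")
  expect_equal(fi_curve(pyr, 0, duration = 500), 0)
  rates <- fi_curve(pyr, c(0, 0.1, 0.2, 0.3, 0.5), duration = 600)
  expect_true(all(diff(rates) >= 0))
  # at matched strong drive the fast-spiking cell outruns the adapting cell
  expect_gt(fi_curve(pv, 0.1, duration = 600), fi_curve(pyr, 0.1, duration = 600))
})
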