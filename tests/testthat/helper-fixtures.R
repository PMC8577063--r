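# shared fixtures, built in code

# single passive compartment (leak only) for fixed-point tests
passive_cell <- function(e_leak = -65) {
  build_cell("cckbas", overrides = list(compartments = list(
    list(label = "soma", depth = 0, length = 20, diameter = 20,
         capacitance = 1.0, channels = list(leak = 0.1), e_leak = e_leak,
         axial_conductance_to_parent = 0))))
}

# two identical passive compartments coupled axially
two_comp_cell <- function() {
  build_cell("cckbas", overrides = list(compartments = list(
    list(label = "soma", depth = 0, length = 20, diameter = 20,
         capacitance = 1.0, channels = list(leak = 0.1), e_leak = -65,
         axial_conductance_to_parent = 0),
    list(label = "basal", depth = 50, length = 20, diameter = 20,
         capacitance = 1.0, channels = list(leak = 0.1), e_leak = -65,
         axial_conductance_to_parent = 0.05))))
}

# default CA3-spatial generator with a flat envelope
flat_ca3_spec <- function() {
  g <- ca1_defaults()$generators$ca3_spatial
  generator_spec("ca3_spatial", g$mean_rate, theta = g$theta, gamma = g$gamma)
}

# tiny network configuration for fast simulation tests
tiny_config <- function(duration = 2000, ...) {
  list(scale = 0.01, duration = duration, ...)
}
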