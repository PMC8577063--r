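Package: ca1rhythms
Title: Conductance-Based Model of Hippocampal CA1 Field Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates local field potential rhythms of the hippocampal CA1
    field with a reduced-compartment Hodgkin-Huxley network of pyramidal cells
    and eight interneuron classes, driven by structured spike-train generators
    emulating CA3, medial entorhinal cortex and medial septum inputs. Includes
    a linear volume-conductor LFP forward model, theta/gamma/ripple state
    configurations, and an analysis battery for spike-phase statistics,
    phase-amplitude modulation index, n:m phase-phase coupling, place-cell
    phase precession and ripple event detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
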