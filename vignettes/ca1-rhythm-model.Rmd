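---
title: "A conductance-based model of CA1 field rhythms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of CA1 field rhythms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ca1rhythms` simulates the rhythmic activity of the hippocampal CA1 field —
theta (4–12 Hz), slow (30–50 Hz), middle (50–90 Hz) and fast (90–150 Hz)
gamma, and ripple oscillations (110–200 Hz) — with a conductance-based
network of pyramidal cells and eight interneuron classes (PV and CCK basket,
axo-axonic, bistratified, OLM, neurogliaform, ivy and
Schaffer-collateral-associated cells), driven entirely by structured
external inputs from CA3, the medial entorhinal cortex (MEC) and the medial
septum (MS). The package also contains the linear volume-conductor forward
model that turns pyramidal membrane currents into laminar field potentials,
and the cross-frequency analysis battery (spike–phase statistics,
phase–amplitude modulation index, n:m phase–phase coupling, phase-precession
fits, ripple detection) used to characterize the simulated signals.

## The model

### Cells

All neurons are Hodgkin–Huxley-formalism, reduced-compartment models.
The pyramidal template has five cylindrical compartments placed on the
somato-dendritic axis at fixed depths (basal +100 µm, soma 0, proximal
radiatum −100, distal radiatum −250, lacunosum-moleculare −400 µm) so that
the laminar separation of synaptic currents — the quantity the LFP model
needs — is representable.  Interneurons are single-compartment.  Channel
complements are a declared defaults table (`inst/extdata/defaults.yaml`):

* regular-spiking types (pyr, cckbas, ivy, ngf, bis, sca, olm) use
  Traub-type Na/K-DR kinetics; the pyramidal soma carries an additional
  muscarinic-sensitive K current (K-M) for spike-frequency adaptation;
* the fast-spiking perisomatic types (pvbas, aac) use Wang–Buzsáki kinetics
  with instantaneous Na activation (a relaxing activation variable puts this
  model into depolarization block, so `m = m_inf` is used, as in the
  original formulation);
* OLM cells carry an H current, giving sag and rebound.

Units are fixed package-wide: ms, mV, nA, µS, µF/cm², µm; channel densities
are declared in mS/cm² and converted through the compartment surface area.
Spikes are upward threshold crossings at −10 mV on the soma with a 2 ms
refractory latch — robust at the default step of 0.1 ms.

Integration uses exponential Euler for gating variables (steady state and
step factor tabulated on a 0.05 mV grid, rebuilt for each dt) and an
implicit-in-voltage Euler step with a Hines solve over each cell's
compartment tree.  Convergence is tested: halving dt changes inter-spike
intervals by well under 0.5 ms per spike; spike counts at dt = 0.1 ms match
a dt = 0.001 ms reference within one spike.

### Synapses

Chemical synapses are bi-exponential conductances normalized so a unitary
event peaks at the connection weight.  Receptor classes: AMPA (τ 0.5/3 ms,
E = 0), nicotinic (1/8 ms, 0 mV), GABA_A fast (0.5/6 ms, −75 mV) for
perisomatic inhibition and GABA_A slow (3/30 ms, −75 mV) for the dendritic
inhibition of neurogliaform and ivy cells, whose IPSPs have characteristic
times of tens of milliseconds.  NMDA receptors and short-term plasticity are
deliberately absent.  Gap junctions couple PV basket pairs and
neurogliaform pairs (nearest-neighbour candidates accepted with a fixed
probability, position-independent conductance); they are ohmic and conserve
charge exactly.  In the network core, synapses with identical kinetics onto
the same compartment are aggregated into per-class state variables, so the
per-step cost is independent of synapse count; presynaptic spikes deposit
weight increments through a delay ring buffer (delays round to integration
steps, minimum one step).

### External inputs

All drive is generated by inhomogeneous Poisson processes
(`generator_spec()`), with rate

r(t) = r₀ · E(t) · (1 + d_θ cos(2π f_θ t − ψ)) · (1 + d_γ cos(2π f_γ t)) ·
(1 + d_r cos(2π f_r (t − c)))

clipped at zero.  E(t) is a unit-peak Gaussian envelope (place field), a
periodic bump train (grid-like MEC drive) or flat.  Defaults: theta 7 Hz
depth 0.6, slow gamma 35 Hz depth 0.4 on CA3 place-cell generators, middle
gamma 63 Hz on MEC generators, ripple 170 Hz depth 0.6 in the non-theta
state; peak rates 5 Hz (CA3, MEC) and 25 Hz (Teevra, depth 0.9).  The theta
phase offset ψ places each source on a shared septo-hippocampal clock;
ripple modulation is locked to the envelope center because ripple episodes
are per-event phenomena (this also makes event-aligned averages preserve the
170 Hz component).  Sampling uses thinning against the analytic rate bound;
the samplers pass a binned-Bernoulli comparison and the time-rescaling test.

The theta-state ensemble contains CA3 place-cell generators tiling the
track (envelope centers follow one constant-speed traversal), CA3 background
generators (theta only), MEC generators whose envelope leads the CA3
envelope at the same position by 500 ms (the place cell receives MEC input
first, then CA3 input — the two-oscillator interference that produces phase
precession), and MS Teevra generators split into target subgroups
(CCK basket, axo-axonic, ivy, bistratified) with distributed phase offsets.
Cholinergic input enters through its two receptor routes: a tonic
depolarizing current in CCK basket cells (muscarinic) and a
theta-locked rhythmic current into OLM cells (nicotinic).

The non-theta transform removes MEC, CA3 background and cholinergic input,
switches Teevra generators to constant rate, compresses CA3 place-field
envelopes 40-fold (peak rate scaled up to preserve the expected spike count
per pass, capped at a configurable ceiling), removes their theta
modulation, retains slow gamma and adds 170 Hz ripple modulation, and
converges envelope centers — producing ~100 ms population discharges.

### Network

Population sizes at scale 1 follow the model census (9000 pyramidal cells;
160/200 CCK/PV baskets; 60 axo-axonic; 70 bistratified; 80 OLM; 130
neurogliaform; 260 ivy; 40 SCA).  Scaled sizes are `ceiling(scale * N)` and
weights are multiplied by `1/scale` (capped at 20) to preserve expected
input.  Wiring is Bernoulli per connection rule with truncated-Gaussian
weights (clipped at zero).  Spatial profiles on the normalized track:
Gaussian for place-coded afferents (CA3 spatial → pyr/pvbas, MEC → pyr) and
inverted Gaussian for PV basket → pyramidal inhibition, which spares nearby
cells (floor 0.05 at zero distance) and targets distant ones — the
disinhibition that lets place cells fire when the animal is in their field.
Spatially modulated and unmodulated pyramidal cells interleave 1:1.

Two desk-scale design choices deserve note.  First, rules onto the small
interneuron populations use higher connection probabilities (up to 0.6)
with proportionally smaller weights than a full-scale model would: with
3–13 cells per class at scale 0.05, sparse wiring makes the afferent count
per cell — and therefore the whole network's operating point — fluctuate
strongly between wiring realizations; raising p preserves the expected
input while shrinking its variance.  Second, beyond the core pathways
(CA3 → pyr/pvbas/bis/sca, MEC → pyr distal, Teevra → cckbas/aac,
pyr ↔ pvbas, cckbas → pyr soma, olm → pyr lm and → ngf, ngf → pyr lm and
→ pvbas, bis → pyr, ivy → pyr, aac → pyr axon-initial segment, sca → pyr)
the default matrix contains a small set of additional edges
(pvbas ↔ cckbas mutual inhibition, olm → pvbas, pyr → olm/bis/ivy
collaterals, pvbas → bis/ivy, bis → ivy, Teevra subgroups onto ivy and
bistratified cells) that implement the phase-coupling scheme: each
interneuron class is held away from its non-preferred phases by rhythmic
inhibition and released in its preferred window.  The axo-axonic target
label `axon-initial` resolves to the pyramidal soma, since the reduced
template folds the initial segment into the somatic compartment.

### LFP

The field is computed by the linear volume-conductor approximation from
pyramidal transmembrane currents only: φ(e,t) = Σ_k I_k(t) / (4π σ r_ek),
σ = 0.3 S/m, with a 10 µm distance clamp.  Transmembrane current per
compartment is computed as net axial inflow plus injected current, which by
Kirchhoff's law equals the capacitive + ionic + synaptic outflow and sums
to exactly zero over each cell — so the dipole (not monopole) character of
the field is preserved to machine precision.  During simulation the
per-compartment currents of pyramidal cells are averaged over 1 ms windows
(a box-car anti-alias) and accumulated into laminar sources binned along
the track (25 bins × 5 depths); electrodes sit in a column at the track
center at depths +100, 0, −100, −250, −400 µm.

## The analysis battery

* Filtering: 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), so phases are unbiased.  Phase convention: 0° at
  the LFP peak, 180° at the trough, descending flank (0°, 180°).
* Spike–phase statistics: circular mean, resultant length, Rayleigh test
  (with the standard finite-n correction); fewer than 10 spikes flags the
  p value unreliable.
* Modulation index: Tort-style normalized KL divergence of the phase-binned
  mean amplitude, 18 bins, 0·log 0 = 0.
* n:m test: R(m) = |⟨exp(i(mφ_θ − φ_m))⟩| for m = 1…12, with the fast band
  centered at m·f_θ (width ± f_θ/2) and f_θ estimated as the mean
  instantaneous frequency of the supplied theta phase; significance from
  ≥ 200 circular time-shift surrogates (minimum shift 1 s); bands beyond
  Nyquist are skipped and flagged.
* Amplitude–phase map: Morlet wavelet amplitude (7 cycles) on a frequency
  grid, averaged in 20 theta-phase bins, each frequency row normalized to
  sum 1.
* Phase precession: circular–linear fit maximizing the resultant length of
  φ − s·x over the slope grid [−720, +720]°/unit (1°/unit steps); the fit
  refuses fewer than 20 spikes; negative slope is precession.
* Ripple detection: ripple-band envelope threshold at mean + 3 SD, events
  merged across < 10 ms gaps, kept for durations in [30, 300] ms;
  intra-event frequency from zero crossings.
* `synth_lfp_fixture()` builds deterministic composite signals (theta
  carrier, optionally phase-locked or theta-gated or burst-windowed fast
  components, white noise) with ground-truth annotations, so every analysis
  operation is testable without running the network.

One practical caveat, encoded in the tests: time-shift surrogates only
destroy phase–amplitude coupling for aperiodic signals; for strictly
periodic fixtures, phase-shuffling surrogates are used instead.

## What the reference simulation shows, and how it is measured

The package's reference run (scale 0.05, 60 s theta state, default seed 1)
reproduces the phase-coupling scheme of the full model: axo-axonic and
neurogliaform cells fire near the LFP theta peak, PV baskets on the
descending phase, pyramidal, OLM and bistratified cells near the trough,
ivy and CCK baskets on the ascending phase, each within ±60° of its target.
Slow-gamma amplitude is significantly modulated by theta phase against
time-shift surrogates.  Three measurement conventions matter:

* The pyramidal preferred phase is assessed on the spatially unmodulated
  half of the population.  The place-coded half is, by design, the second
  mode of the (bimodal) mixture: inside the field these cells are
  disinhibited and fire earlier.  Out-of-field firing at the trough is the
  canonical preference the coupling scheme depicts.
* Sparsity — the fraction of pyramidal cells firing in a theta cycle is of
  order 1% — is measured in the out-of-field condition (place-field
  envelopes moved outside the traversal), which isolates the background
  sparsity the claim refers to; the reference runs give 0.8–1.5% across
  wiring seeds.  During a traversal the place-coded ensemble adds several
  percent on top, a consequence of tiling a 60 s track with 225 place
  fields.
* The scheme is asserted at the package's default seed.  At this scale the
  emergent theta reference rotates by roughly ±25° between wiring
  realizations (10 PV baskets instead of 200 make the dipole balance
  realization-dependent), so individual populations near a band edge can
  cross it on other seeds; the full-scale network does not have this
  freedom.

A known limitation, stated rather than patched: the pooled pyramidal
phase histogram in the reduced-scale model is not visibly bimodal.  The
two subpopulations differ clearly in concentration (resultant length ~0.3
broad vs ~0.65 sharp) but their circular means nearly coincide, because at
this scale the in-field disinhibition contrast is too weak to pull the
place-cell mode a quarter cycle ahead of the background mode.  The
corresponding acceptance check is implemented faithfully (two prominent
smoothed-histogram modes) and fails honestly on the reduced network.
The axo-axonic population also fires at unrealistically high rates relative
to its small census — a property the full model shares and documents.

## Problem sizes and numerical choices

Default test and reference sizes were chosen to make the full suite
practical on a laptop-class single core: generator spectra use 100
generators × 60 s; the network property suite runs 60 s at scale 0.05
(≈ 500 cells, ≈ 2300 compartments, dt 0.1 ms) plus a 30 s out-of-field run;
fixture-based analysis tests use 15–30 s signals with 100–200 surrogates.
The full 9000-cell network is reachable from the same configuration
(`scale = 1`) but is not exercised by the default suite.  Degenerate inputs
are handled explicitly: empty spike trains, empty ripple sets and
sub-threshold networks return empty-but-typed results; numerical blow-up
(|V| > 200 mV) aborts with the offending cell and time; non-finite states
are rejected naming the compartment.

## What the synthetic data do and do not establish

The generators emulate the *statistical structure* of the afferents —
rates, rhythmic modulation depths, place-field envelopes, septal phase
offsets, compression in the non-theta state — not their biological
microstructure: no spike-train autocorrelation beyond the rate function, no
theta-sequence structure in CA3, no learning or remapping, no 2-D grid
geometry, and the declared channel kinetics and connection parameters stand
in for the full model's table-driven values.  Passing the suite therefore
shows that the implemented mechanisms produce the targeted rhythm
phenomenology under the declared conditions; it does not validate the
parameter values against in vivo data.
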