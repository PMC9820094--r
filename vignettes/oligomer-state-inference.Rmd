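---
title: "Inferring the oligomeric state of a four-MPM transporter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the oligomeric state of a four-MPM transporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostate)
```

# The question and the strategy

The yeast K⁺ transporter Trk1 carries four MPM motifs (A–D) around a
central pore, each homologous to a 2-TM K-channel α-subunit, so one
monomer is structurally a complete channel. Related SKT transporters
crystallise as dimers, and tetramers with MPM D buried centrally have
been proposed. `oligostate` implements three complementary computational
routes to the oligomeric state:

* a coarse-grained geometry that predicts, for each hypothetical
  arrangement, whether a given split-fluorophore (BiFC) fusion experiment
  *could* produce complementation;
* a constraint-elimination engine that intersects those predictions with
  observed BiFC outcomes;
* stepwise-photobleaching analysis that counts emitters per
  diffraction-limited spot directly, and a semi-quantitative spectral
  readout that follows the monomer/dimer balance through culture growth.

Every pipeline is exercised on data from the package's own synthetic-data
generator, which carries ground truth for recovery testing.

# The coarse-grained geometry

## Model

All geometry lives in the membrane plane: the fusion-tag anchors
(N-terminus, C-terminus, intracellular loop 3) are all cytosolic, so the
distances that discriminate arrangements are lateral. The model unit is
the nominal MPM diameter. A monomer is four unit-diameter disks at the
corners of a unit square, counter-clockwise A, B, C, D as seen from the
extracellular side, centroid at the pore. Arrangements are rigid poses of
this layout: a C2 dimer abuts a named MPM–MPM edge of each monomer
(interfaces AB/BA, BC/CB, CD/DC, DA/AD); a C4 tetramer places the four
copies of a named central MPM nearest the global centroid, adjacent
copies touching. Asymmetric assemblies, trimers and mixed interfaces are
out of scope.

Each anchor has a *home* (N-terminus at MPM A, C-terminus at MPM D,
loop 3 at the C–D edge midpoint), a 2-D *offset* from that home
(representing where the flexible tail actually dangles) and a *linker
reach* (the maximum lateral tether length of linker plus fragment). A
fragment pair can complement when

* the anchor–anchor distance is at most
  `reach(anchor₁) + reach(anchor₂) + fp_diameter`, and
* the reconstituted-fluorophore disk (diameter `fp_diameter`) admits a
  placement on the inner half of the anchor–anchor segment (fractions
  0.25–0.75) that does not interpenetrate any MPM disk beyond 5 % of
  `fp_diameter`.

The placement is sampled along the segment rather than pinned to the
midpoint because tethers are flexible: a fluorophore that must sit
exactly halfway would be spuriously blocked whenever the straight line
between two reachable anchors crosses the protein body, which is not a
physical constraint.

Two *declarative steric-block rules* complete the predictor
(`default_block_rules()`): the DA/AD dimer with both fragments at the
N-termini (a clash between the loops connecting MPMs C and D prevents
complementation that the distance criterion alone would allow), and
tetramer A for VN at an N-terminus with VC at a C-terminus (a clash
between reconstituted fluorophores in the tetramer). Blocked cells count
as "signal not expected" in the inference below. The second rule encodes
a genuine limit of distance-based reasoning: the experiment with the two
fragments swapped between the same two anchors has identical distances,
yet atomic-scale models distinguish them — only a clash-type rule can
represent that.

## Calibration of the defaults

The distance thresholds intentionally avoid any literal nanometre figure:
reported proximity thresholds for BiFC vary by an order of magnitude
between sources and the printed value for this system is implausibly
large, so units are treated as unreliable and everything is expressed in
model units. The default anchor offsets (N `(-0.54, 0.09)`,
C `(0.66, -1.25)`, loop 3 `(-1.38, 0.29)`), reaches (1.34, 1.74, 0.91)
and `fp_diameter` (0.15) were calibrated once, by a grid-and-refinement
search, so that the computed 9 × 5 feasibility table reproduces — on all
45 cells — the verdicts established by atomic-scale structural modelling
of the transporter (`reported_feasibility_table()`). The calibrated
defaults sit with separation margins of 0.20–0.55 model units between the
largest feasible and smallest infeasible distance of every experiment, so
the agreement is not knife-edge. The offsets are large for the N-terminal
and loop-3 anchors, which is the geometric echo of long flexible tails:
roughly one MPM diameter of lateral excursion.

Three structural facts about the calibration are worth recording. First,
the C-terminal anchor must sit at `x > -0.5` (in the monomer frame) or
the C–C verdicts of the BC/CB and DA/AD dimers tie exactly; second, the
N-terminal anchor must sit at `x < -0.5` or the N–N distances of
tetramers C and D swap order; third, the loop-3 and C-terminal offsets
must satisfy `x_loop3 + x_C < -0.5` for the loop-3 experiment to prefer
the BC/CB over the DA/AD dimer. These mirror-symmetry tie lines of the
square are why the defaults are asymmetric.

## Properties

The predictor is monotone in reach (growing reaches never turn feasible
into infeasible), invariant under permuting monomer indices, and
equivariant under cyclic relabelling of the MPMs: `relabel_layout()`
permutes labels and anchor homes while keeping every coordinate fixed,
and the CD-interface distances of the `shift = -1` relabelling equal the
DA-interface distances of the original exactly. All three are enforced by
tests.

# Constraint elimination

Observed outcomes are combined with a feasibility table in two stages
with deliberately different semantics:

* **Stage 1 — false-positive rejection.** An arrangement predicted
  `feasible` for an experiment in which BiFC was never observed is
  eliminated: it promised a signal that did not appear. `blocked` does
  not eliminate (the prediction itself expects no signal), and positive
  observations are ignored.
* **Stage 2 — positive explanation.** Among survivors, only arrangements
  predicted `feasible` for every positive *discriminator* observation are
  kept. The discriminator set defaults to the loop-3 experiment alone.

The asymmetry is intentional: monomers and multimers coexist in the
membrane, so a multimer cannot be rejected merely because it fails to
predict a terminal-fusion positive — a coexisting species may produce
that signal. The loop-3 insertion, by contrast, was designed so that its
positive discriminates among the surviving multimers. For the same
reason the monomer is exempt from stage 2 and reported as a coexisting
species.

On the bundled inputs, stage 1 leaves three multimer candidates (CD/DC,
DA/AD, tetramer D) and stage 2 leaves only the CD/DC dimer. A
property-based test checks the staged engine against a definitional
set-filter on random tri-state tables and observation sets, along with
anti-monotonicity in evidence and order-invariance within a stage.

# The synthetic-data generator

## Photobleaching traces

`simulate_trace()` draws, per emitter: an amplitude from a normal
truncated at zero (defaults 234.7 ± 47 cnts/pix, the single-molecule
signal intensity of the modelled acquisition), an on-time in frames until
irreversible bleaching, and an optional two-state telegraph blinking
sequence. The trace is background (default 200 ± 30 cnts/pix Gaussian,
or a Poisson–gamma EMCCD model with excess noise factor 2 and default
gain 30) plus the summed amplitudes of live, fluorescent emitters over
1000 frames of 10 ms.

The default on-time law is geometric with mean 223 frames — memoryless
photobleaching, the maximum-entropy choice given only a mean. Its SD
(≈ mean) exceeds the observed spread of the experiments this emulates;
an optional truncated-normal mode (mean 223, SD 52) matches that spread
when the distribution shape matters. Truncation of the geometric at the
1000-frame acquisition gives an expected *observed* on-time of 220.5
frames, a 1 % bias acknowledged in the recovery tests. Blinking defaults
(off-rate 0.005/frame, mean dark time 5 frames) make blinks visibly
shorter than bleaches; they are a modelling choice, not a measured
quantity.

What the generator deliberately does not emulate: spatial structure
(spot detection and localisation are upstream of this package), focal
drift, spectral cross-talk, cellular autofluorescence gradients, and
dark or immature fluorophores. Consequently, passing recovery tests
demonstrates that the counting algorithm is correct for well-formed
traces with the stated statistics — not that real cellular fractions are
free of maturation bias (fractions are reported uncorrected, as in the
practice this package models).

## Spectra and growth scenarios

Emission spectra live on the fixed 16-point grid 510–540 nm in 2 nm
steps. A reporter spectrum is a background profile plus a Gaussian peak
(default centre 530 nm — Venus-like, inside the 528–534 nm window — and
SD 8 nm) plus noise; a control spectrum omits the peak.

A `growth_scenario()` encodes a culture: logistic OD600 growth from an
inoculum of 0.1 (≈ 1.1 × 10⁶ cells/mL) to a plateau of 2.5 at rate
0.35 h⁻¹ (late-exponential OD ≈ 2.5 around 14 h); a logistic expression
amplitude (midpoint 15 h, scale 5 h); and a dimer fraction that is flat
at 0.12 for 0.1 mM KCl but rises logistically from 0.12 to 0.75
(midpoint 40 h, scale 8 h) into the stationary phase for ≥ 1 mM. At
0.1 mM the fluorescence additionally decays after a late-exponential
peak (default peak 24 h, decay time 60 h). The strain couplings are:
intramolecular reporter ∝ monomer fraction + 0.1 × dimer fraction (the
leak term represents N-to-C contacts between separate monomers, which
make the monomer estimate a slight overestimate), intermolecular pair
∝ dimer fraction, full fluorophore ∝ 1, control ∝ 0. The dynamics are a
phenomenological reconstruction of the reported qualitative pattern —
the sources report the pattern, not a kinetic model — and all parameters
are exposed.

# Step detection and counting

## Exact penalized segmentation

`detect_steps()` minimises, over all segmentations into constant-mean
segments, the within-segment sum of squares plus a penalty per change
point. The optimum is found *exactly* by pruned dynamic programming
(PELT, implemented in C++), with ties broken towards fewer change
points. Exactness is the reason this algorithm was chosen over greedy
binary segmentation: the package's own acceptance property demands
equality with the exhaustive-search optimum on random short traces, and
binary segmentation cannot guarantee that. The test oracle is an
independent O(n²) dynamic program in plain R, itself cross-checked
against literal enumeration of all change-point placements at tiny n.

The default penalty is BIC-style, `2 σ̂² log n`, with σ̂ estimated as
`mad(diff(x)) / √2` — first differences remove the piecewise-constant
signal, and the MAD resists the outliers the steps themselves create.
For exactly constant (noiseless) traces σ̂ is zero; the penalty then
falls back to a tiny positive value so that the exact piecewise-constant
segmentation with the fewest change points is recovered rather than one
change point per frame. At the default SNR (step ≈ 235, noise SD 30) a
one-frame event already clears the penalty, so even short blinks are
segmented.

## From steps to emitters

`count_emitters()` treats every downward level change as a candidate
bleach and pairs each upward change with the nearest preceding unpaired
downward change of comparable magnitude (within 35 %) and dark gap
(≤ 50 frames) as a blink; the emitter count is the number of unpaired
downward steps. Unpairable rises flag the spot (`unpaired_rise`), counts
above 4 flag aggregates, and an initial level inconsistent with
`n × unit amplitude` above the final baseline (beyond 1.5 units) flags a
level mismatch. The unit amplitude is the median unpaired downward step.
These rules are declared design choices: the analysis software they
stand in for is not public, so recovery against generator ground truth —
not agreement with an external implementation — is the validation.

`summarize_population()` aggregates counts into fractions over spots
with ≥ 1 detected emitter and attaches percentile bootstrap confidence
intervals (default 2000 resamples, seeded). At 10⁴ spots with default
trace statistics, the pipeline recovers mixture monomer fractions of
0.65 and 0.80 within ± 5 percentage points and the mean bleach-step
amplitude within 5 %; residual 3–4-emitter counts (≈ 1 %) come from
rare blink/bleach coincidences, matching the rare higher counts such
experiments report.

# Semi-quantitative BiFC

`background_correct()` subtracts the matched control spectrum pointwise
(negatives retained — clipping would bias the band mean);
`peak_fluorescence()` averages the three grid points in the inclusive
530–534 nm band (534 is the stated band edge, so a half-open band was
rejected); `ratio_timecourse()` divides inter- by intramolecular peak
series joined on time (nearest neighbour within 0.5 h), flagging — not
dropping or imputing — times where the denominator is non-positive;
`phase_averages()` averages ratios in the exponential (5–25 h) and
stationary (50–150 h) windows, with across-replicate SD (n − 1) when
replicates are supplied. Correction and peak metric are linear, and
ratios are invariant under common rescaling of both series; both are
tested.

`fit_phenomenological()` is a raw-polynomial least-squares fit (default
degree 4) used purely for smooth display, with prediction refused
outside the data range. A quartic can localise the single interior
maximum of the 0.1 mM fluorescence course to within 2 h when fitted over
the rise and early decline (2–40 h); over the full 160 h course it
cannot — a documented limit of a degree-4 polynomial on an asymmetric
peak, and the reason the fitted window in the corresponding test is
2–40 h.

At zero spectral noise the full chain — generator → correction → peak →
ratio — returns exactly the generator's coupling ratio
`d / ((1 − d) + 0.1 d)`; the end-to-end test allows 10 %.

# Construct arithmetic

Coordinates are 1-based inclusive throughout, matching residue
numbering. The default fragments are VN = Venus 1–155 (155 residues),
VC = Venus 156–238 (83), GC = yEGFP 155–238 (84). `delete_segment()`
and `insert_fragment()` do pure coordinate bookkeeping — every edit
changes the length by exactly the stated amount, shifts downstream
features, truncates overlapping ones and records the edit as a feature —
and the two operations commute with coordinate remapping (tested).
No real Trk1/Venus/yEGFP sequences are bundled (they are not printed in
the sources this package models); dummy sequences of user-declared
length drive all tests, and users supply FASTA for real constructs.
FASTA I/O uses Biostrings; a minimal GenBank flat-file writer/reader is
provided in-package because no pre-installed package emits GenBank with
features, and round-trip identity is tested for both formats.

# Problem sizes, determinism, limitations

The test suite runs the counting pipeline at 1 200–2 000 spots and the
acceptance checks at the study scale of 10⁴ spots (about two minutes
total on one CPU); spectra and time courses are seconds. Every
stochastic function takes a seed, seeds all its randomness from it, and
restores the caller's RNG stream, so identical calls are bit-identical —
a property asserted across all three pipelines.

Known limitations: the geometry is 2-D and coarse-grained — it
reproduces the published feasibility pattern by calibration and cannot
make de-novo structural predictions; blocked verdicts encode structural
knowledge the distance model cannot derive; emitter counting is
uncorrected for dark fluorophores; growth-scenario dynamics are
phenomenological; and the inference is purely logical — it weighs no
evidence probabilistically and models no mixtures of multimer species
beyond carrying the monomer alongside.
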