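# oligostate

Tools for inferring the oligomeric state of polytopic membrane transporters
from fluorescence data, modelled on the yeast K⁺ transporter Trk1.

Trk1 contains four MPM motifs (Membrane-helix–Pore-helix–Membrane-helix,
labelled A–D) arranged around a central pore, each homologous to a
two-transmembrane K-channel α-subunit, so a single monomer could in
principle form a complete channel — yet related SKT-family transporters
crystallise as dimers and tetrameric models have been proposed. This
package implements the three computational analyses by which that question
can be settled from bench-scale fluorescence experiments:

1. **Geometric BiFC feasibility** (`oligomer_geometry` functions).
   A coarse-grained 2-D membrane-plane model of the monomer and its
   symmetric arrangements — the monomer, four C2 dimers named by their
   MPM–MPM interface (AB/BA, BC/CB, CD/DC, DA/AD) and four C4 tetramers
   named by their central MPM. For each arrangement × fusion experiment
   (split-fluorophore fragments VN/VC/GC tethered at the N-terminus,
   C-terminus or intracellular loop 3), bimolecular fluorescence
   complementation (BiFC) is predicted *feasible* when some admissible
   fragment pair is within the combined tether reach plus fluorophore
   diameter and the reconstituted fluorophore has a clash-free placement,
   *blocked* when a declarative steric rule overrides, *infeasible*
   otherwise.

2. **Constraint-elimination inference** (`bifc_inference`). Stage 1
   removes every arrangement predicted feasible for an experiment in
   which BiFC was never observed (false-positive rejection); stage 2 keeps
   only arrangements that can explain the positive discriminator
   (the loop-3 insertion experiment). Monomers, which coexist with
   multimers in the membrane, are carried alongside rather than
   eliminated.

3. **Stepwise-photobleaching emitter counting** (`step_counting`), with a
   first-class synthetic-data generator (`synthetic_data`). Traces of
   diffraction-limited spots are segmented by exact penalized
   least-squares change-point detection (PELT, in C++); downward steps are
   bleaches, down–up pairs of matching amplitude are blinks, and per-spot
   emitter counts aggregate into monomer/dimer fractions with bootstrap
   confidence intervals.

4. **Semi-quantitative BiFC** (`bifc_quant`). Background-corrected
   emission spectra (510–540 nm, 2 nm steps), the mean 530–534 nm "peak
   fluorescence" readout, inter/intra-molecular ratio time courses over
   culture growth, exponential- vs stationary-phase averages, and
   4th-degree phenomenological fits.

A `constructs` module provides the supporting sequence arithmetic
(fragment splitting, loop deletion, internal insertion, FASTA/GenBank
emission).

## Worked example

The staged elimination over the bundled feasibility table and the
published BiFC outcomes:

```r
library(oligostate)
run_inference()
#> <consistency_result>
#>   candidates: dimer_CD
#>   coexisting: monomer
#>   eliminated:
#>     dimer_AB     stage 1 (nn)
#>     dimer_BC     stage 1 (nn)
#>     tetramer_A   stage 1 (nn)
#>     tetramer_B   stage 1 (nn)
#>     tetramer_C   stage 1 (nn)
#>     dimer_DA     stage 2 (loop3)
#>     tetramer_D   stage 2 (loop3)
```

The absent N–N terminal signal removes five arrangements that would have
produced it; the observed loop-3 complementation then excludes the DA/AD
dimer and the D-centred tetramer, leaving the CD/DC dimer as the only
multimeric arrangement consistent with all observations — monomers
coexist.

Counting emitters in a synthetic population whose ground truth is 65 %
single-emitter spots:

```r
pop <- simulate_population(mixture_spec(c(0.65, 0.35, 0), 2000),
                           trace_params(seed = 42))
res <- count_population(pop, summary_cfg = summary_config(seed = 1))
res$summary
#> <population_summary> 2000 spots (1987 used)
#>   n_emitters fraction lower upper
#> 1          1    0.650 0.628 0.671
#> 2          2    0.335 0.314 0.356
#> 3          3    0.014 0.009 0.019
#> 4          4    0.002 0.000 0.004
```

The recovered single-emitter fraction (0.650, 95 % CI 0.628–0.671) matches
the generative mixture; the small 3–4-emitter tail comes from occasional
blink/bleach misclassification.

K⁺-dependent dimerisation in the synthetic 1 mM KCl growth scenario — the
inter/intra BiFC ratio is far below 1 while cells grow exponentially and
rises well above 1 in the stationary phase:

```r
tc <- simulate_bifc_timecourse(growth_scenario(1),
                               c("intra", "inter", "control"), seed = 7)
rs <- ratio_timecourse(peak_series(tc, "inter"), peak_series(tc, "intra"))
phase_averages(rs)
#>         phase      mean        sd n
#> 1 exponential 0.1395053 0.1258737 5
#> 2  stationary 2.1988505 0.2313386 5
```

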