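---
title: "Inferring helix frequencies and helix-helix correlations from compensatory rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring helix frequencies and helix-helix correlations from compensatory rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lm2r)
```

## The problem

Regulatory RNAs such as riboswitches do not sit in a single secondary
structure: they populate an ensemble of structures, and gene-regulatory
function depends on *which helices co-occur*.  For the adenine riboswitch in
the *V. vulnificus* `add` mRNA, the central mechanistic question is whether
helices characteristic of the ligand-bound aptamer (P1, P2) are
anticorrelated with the helices that sequester the ribosome binding site
(P4A, P4B, P4C) even in the absence of ligand — the signature of a
Monod-Wyman-Changeux (MWC, conformational-selection) mechanism — or whether
the two groups form independently, as a competing non-MWC model proposes.

`lm2r` implements the analysis chain that answers this question from
chemical-mapping data:

1. **Mutant design** (`design_compensatory_quartet()`,
   `design_double_pair_lock()`): for each candidate base pair, the quartet
   of constructs probed — wild type, each single mutant, and the
   compensatory double mutant — and, for each helix, double-base-pair
   "lock" variants that stabilize it.
2. **Profile conditioning** (`read_rdat()`, `normalize_profile()`,
   `correct_attenuation()`, `subtract_background()`).
3. **The rescue factor** (`rescue_factor()`): a quantitative,
   inspection-free summary of how completely the double mutant restores
   the wild-type reactivity profile.
4. **Simulation calibration** (`build_calibration()`): in-silico
   mutate-map-rescue over many sequences links observed rescue factors to
   underlying helix frequencies.
5. **Bayesian inference** (`posterior_frequency()`,
   `posterior_correlation()`, `combine_posteriors()`): sample-based
   posteriors over helix frequencies `F` and correlation values `g`.

## The rescue factor

For two profiles $d_A, d_B$ over the $N$ compared nucleotides,

$$\mathrm{RMSD}(A,B) = \sqrt{\tfrac1N \sum_{i=1}^N \left(d_A(i)-d_B(i)\right)^2},$$

and for a quartet (WT, single mutants A and B, double mutant AB)

$$\text{rescue factor} = 1 - \frac{\mathrm{RMSD}(\mathrm{WT},\mathrm{AB})}
 {\max\!\big(\mathrm{RMSD}(\mathrm{WT},\mathrm{A}),\,
             \mathrm{RMSD}(\mathrm{WT},\mathrm{B})\big)}.$$

A factor of 1 means the compensatory mutant restores the wild-type profile
exactly; 0 means it is as disrupted as the worse single mutant; negative
values (retained, not clipped) flag double mutants that disrupt the profile
further.  Per-pair factors are averaged across all tested base pairs of a
helix (`helix_rescue()`), which our simulations confirm is substantially
more informative than any single pair.

Two conventions matter and are configurable:

* **Compared positions** default to the construct's probed region including
  the mutated positions themselves; a flag (`exclude_mutated` on
  `quartet()`) drops a ±1 window around the substitutions.  The flanking
  reference hairpins are excluded by construction — they are normalization
  anchors, not signal.
* **Category thresholds** for no/partial/full rescue default to 0.2 / 0.7
  (`classify_rescue()`); they only label output tables and never enter the
  inference.

## Profile conditioning

Profiles are normalized so the mean reactivity over the flanking GAGUA
reference loops is 1; modifier chemistries that react with only part of the
loop can restrict the anchor with a position mask.  Signal attenuation
towards the 3' end is corrected by a per-position geometric factor anchored
at the two loops: the ratio of the 5' to the 3' loop mean sets the total
correction, interpolated exponentially along the profile.  This closed-form
anchor model deliberately replaces the full capillary-electrophoresis
likelihood machinery, which operates upstream of the data this package
consumes.  Background (no-modification) profiles are subtracted
elementwise and floored at zero, since negative reactivities are unphysical
and the RMSD is sensitive to spurious negative excursions.

## Simulation calibration

The rescue factor has no closed-form relation to helix frequency, so the
package calibrates it by simulation, mirroring the experimental pipeline on
sequences folded in silico:

* fold the sequence with a partition-function backend and keep candidate
  helices of ≥ 3 stacked pairs whose base-pair probabilities all reach the
  screening cutoff (default 1%; the published analysis reports that
  lowering it to 0.1% leaves conclusions unchanged, and the acceptance
  suite re-checks a reduced-scale version of that claim);
* for every pair of every candidate helix, design the compensatory quartet,
  fold all four variants, convert each base-pair probability matrix to an
  idealized reactivity profile, and compute the rescue factor;
* record one calibration sample per helix: base-pair count, mean rescue
  factor, and mean base-pair probability (the simulated helix frequency).

The **simulated reactivity** of a position is its probability of being
unpaired, $1-\sum_j p(i,j)$.  This is the one place where the package fixes
a modeling convention the experimental literature leaves open: SHAPE
reactivity tracks nucleotide flexibility, for which probability-unpaired is
the simplest deterministic, monotone proxy.  Simulated profiles are
noise-free by default; Gaussian noise can be added through the synthetic
module for sensitivity analyses.

### The bundled fold backend

The default backend is a McCaskill-style inside/outside dynamic program
over a deliberately simple energy model: per-pair energies (G-C −3.0,
A-U −2.0, G-U −1.0 kcal/mol), a minimum hairpin loop of 3 nt, no stacking
or loop terms, Boltzmann statistics at a configurable temperature (default
37 °C).  Its value is not thermodynamic accuracy but *exactness and
self-containment*: the test suite verifies that its probabilities equal
brute-force enumeration of all nested structures to < 1e-9 for every
fixture sequence up to 18 nt, so every downstream stage rests on a backend
that is provably correct for its model.  ViennaRNA's `RNAfold -p` (Turner
energies) is wired in as an alternative production backend
(`fold_backend("vienna")`), and calibration tables carry a backend tag so
tables from different backends are never silently mixed.  Numerically, the
dynamic program rescales all quantities by a per-nucleotide factor chosen
adaptively, keeping partition functions within double range for sequences
of a few hundred nucleotides.

## Bayesian inference

Given an observed helix-level rescue factor, `posterior_frequency()`
collects every calibration sample with the same base-pair count and a
simulated rescue factor in the same bin (binwidth 0.05, chosen for
sufficient per-bin sampling); the simulated frequencies of those samples
*are* the posterior sample, summarized by the median and visualized through
a kernel density estimate.  Design choices:

* **Bin starvation**: if the exact (n_bp, bin) cell has fewer than 20
  samples, the match is relaxed stepwise — ±1 bin, then ±1 base pair, then
  ±2 bins — with each relaxation logged; an empty match after relaxation is
  an error naming the starved bin.  Observed factors outside the populated
  range clamp to the nearest populated bin with a warning.
* **KDE**: Gaussian kernel, Silverman bandwidth, boundary-reflected at 0
  and 1 for frequencies and at 0 for correlation values, since both live on
  bounded or half-bounded supports.

`posterior_correlation()` turns two frequency posteriors — the probed helix
in the wild-type background and in a background locking the partner helix —
into samples of the correlation value $g = F(\text{probed} \mid
\text{locked}) / F(\text{probed})$ by forming pairwise ratios
(locked / wild-type), with the cross-product capped at 10⁶ seeded draws.
Zero denominators are excluded with a log line; an all-zero denominator set
is an error.  `combine_posteriors()` merges a lock experiment with its
flipped counterpart by multiplying the two kernel density estimates on a
shared 2048-point grid spanning `[0, max(4, 99.5th percentile)]` under a
flat prior on `g`, renormalizing by the trapezoid rule, and redrawing
samples by inverse-CDF sampling.  `posterior_support(post, 1)` integrates
the posterior mass above `g = 1` — the quantity that discriminates
independence from mutual exclusion.

Two robustness properties are enforced by the acceptance suite rather than
assumed: halving or doubling the KDE bandwidth moves no reported posterior
support by as much as a factor of 2, and switching the screening cutoff
between 1% and 0.1% moves posterior medians by at most 0.05 over the
informative rescue-factor range (0.2–0.8).  The lowest rescue-factor bin is
the exception and a known limitation: its posterior tracks exactly the
tiny-frequency helices that the looser cutoff admits, so low-factor
inferences are stable only in the qualitative sense that they stay low
(< 0.2) under both cutoffs.

## Two-state validation of lock mutants

Lock mutants are validated by `two_state_fit()`: a candidate profile is
decomposed as $f \cdot d_A + (1-f) \cdot d_B$ against two locked-state
endpoint profiles, with the closed-form least-squares fraction clamped to
[0, 1] and the residual RMSD reported.  Multi-modifier data are fit by
concatenating per-modifier profiles (each normalized within its modifier)
under a single shared fraction, matching the experimental practice of
fitting one two-state picture across several probe chemistries.  Per-profile
scale freedom is deliberately not fitted: prior normalization fixes the
scales, and freeing them would let the fit absorb genuine disagreement.

## The synthetic-fixture generator

Because the full experimental chain needs data that no desk environment can
download, the synthetic module generates ground-truth ensembles the whole
pipeline can be tested against: a construct populating a small set of
discrete dot-bracket structures with stated weights, idealized reactivity
equal to the weighted unpaired fraction plus Gaussian noise (sd 0.1
reactivity units, a typical normalized SHAPE error), clipped at zero.
Quartet fixtures respond to mutation through an explicit model:

* single mutants reassign the weight of pair-containing structures to the
  next-highest-weight alternative (or uniformly, configurable);
* the compensatory double mutant restores the pair-containing weight while
  half of the remaining weight rearranges to an open chain — the
  `rearranged_fraction = 0.5` default is what makes rescue *partial* at
  intermediate frequencies, mimicking ensemble members that fail to return
  to the wild-type fold.

`make_calibration_fixture()` spans true frequencies 0.05–0.95 on bistable
two-helix constructs (two mutually exclusive helices sharing a central
strand) with helix lengths cycling over 3–6 bp; `lock_ensemble()` emulates
an imperfect lock mutant by conditioning the ensemble on a helix with a 5%
leak.  All fixtures are seed-deterministic, bit-reproducible, and
independent of the caller's RNG stream.

What the fixtures do **not** emulate: correlated noise along the read-out,
saturation and dilution artifacts of capillary electrophoresis, sequence
context effects on probe chemistry, and tertiary-structure protections.
Passing fixture tests therefore demonstrates the correctness of the
algorithms and the internal consistency of the calibration—inference loop,
not the field accuracy of the simple energy model on any particular RNA.

## Problem sizes and numerical conventions

The packaged validation runs use problem sizes chosen to exercise the
statistics meaningfully on a desk machine: brute-force backend equivalence
on sequences ≤ 18 nt; the rescue-factor/frequency trend on ~30 random
sequences of 50–80 nt (several hundred screened helices); parameter
recovery against a 200-helix fixture calibration; and cutoff robustness on
36 sequences folded under both cutoffs.  Tie-breaks and degenerate inputs
follow one rule: physically impossible requests (empty comparison sets,
zero reference-loop means, identical two-state endpoints, all-zero
denominators) are errors, while legitimately uninformative data (a quartet
whose single mutants do not move the profile) carry a classed condition
(`lm2r_uninformative`) that aggregation layers skip with a logged warning.

## Known limitations

* The simple pair-energy backend overpopulates isolated pairs and shifted
  helix registers relative to nearest-neighbour models; screened helix
  lists at the 1% cutoff therefore include faint registers that Turner-rule
  backends would suppress.  Production analyses should prefer the
  ViennaRNA backend.
* Rescue factors from compensatory swaps are exactly energy-neutral for
  the probed pair under the bundled model, so the simulated signal comes
  entirely from the mutated bases' interactions with the rest of the
  sequence; shared-strand competing helices can push simulated rescue
  factors below zero at intermediate frequencies.
* Posteriors inherit the calibration ensemble: a calibration built from
  sequences unlike the construct under study biases frequency estimates in
  ways the package cannot detect.  Calibration tables therefore carry
  their provenance (backend, cutoffs, seed, config hash).
* Pseudoknots and non-Watson-Crick pairings are outside the structural
  model everywhere.
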