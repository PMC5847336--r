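# lm2r — lock-mutate-map-rescue analysis of RNA structural ensembles

Regulatory RNAs populate ensembles of secondary structures, and their
function hinges on which helices co-occur.  `lm2r` implements quantitative
compensatory-mutagenesis analysis for chemical-mapping data — the
mutate-map-rescue (M²R) and lock-mutate-map-rescue (LM²R) strategy — to
infer, for any helix of interest, how often it forms in the ensemble and
whether it is correlated or anticorrelated with other helices.  The
motivating application is the adenine riboswitch of the *V. vulnificus*
`add` mRNA, where the anticorrelation of aptamer helices (P1, P2) with the
ribosome-binding-site-sequestering helices (P4A, P4B) distinguishes
Monod-Wyman-Changeux conformational selection from competing models.

## The method in brief

For a candidate base pair, four constructs are probed: wild type, a single
mutant on each side of the pair, and the compensatory double mutant.  The
**rescue factor**

```
rescue factor = 1 − RMSD(WT, AB) / max(RMSD(WT, A), RMSD(WT, B))
```

with `RMSD(A, B) = sqrt(mean((d_A(i) − d_B(i))²))` over the probed
nucleotides, quantifies how completely the double mutant restores the
wild-type reactivity profile: 1 is full rescue, 0 none, intermediate values
partial rescue.  Simulated M²R experiments over many folded sequences
calibrate the relation between the rescue factor (averaged over a helix's
pairs) and the helix frequency `F`; matching an observed factor against
calibration samples of the same helix length and factor bin yields a
sample-based posterior over `F`.  Repeating the measurement in a background
that "locks" a second helix (two consecutive base pairs switched to
alternative Watson-Crick pairs) gives the conditional frequency, and the
correlation value

```
g(h1, h2) = F(h1 | h2) / F(h1)
```

is estimated by pairwise ratios of posterior samples; `g ≪ 1` means mutual
exclusion (the MWC signature), `g ≈ 1` independence.  Posteriors from an
experiment and its flipped counterpart (lock h1, probe h2) are combined by
multiplying kernel density estimates under a flat prior, and the integrated
mass above `g = 1` summarizes the evidence against mutual exclusion.

## Worked example

Design the published lock and quartet mutants for the bundled
adenine-riboswitch construct, then run the full synthetic chain — quartets,
rescue factors, frequency posteriors, correlation — on a ground-truth
bistable ensemble:

```r
library(lm2r)

con <- add_construct()
con
#> <rna_construct> add: 198 nt, positions -13..184 (offset -14)
#>   probed region: 13..140
#>   reference loops: 5' -2-2 | 3' 150-154

design_double_pair_lock(con, add_helices()$P1)
#> <mutant_spec> A19U-U20A-A76U-U77A

sapply(design_compensatory_quartet(con, base_pair(19, 77, con)), mutant_label)
#>        mutA        mutB       mutAB
#>      "A19U"      "U77A" "A19U-U77A"

# ground truth: two mutually exclusive 4-bp helices at 50/50
cal <- make_calibration_fixture(200, seed = 101)
bis <- lm2r:::.bistable_construct(4L, 950L)
ens <- toy_ensemble(bis$construct, c(bis$dbA, bis$dbB), c(0.5, 0.5),
                    seed = 1450)

wt <- probe_ensemble_helix(ens, bis$helixA, cal)
attr(wt, "rescue")
#> <helix_rescue> helix: mean rescue factor 0.345 over 4 pair(s)
wt
#> <freq_posterior> rescue factor 0.345 (4 bp): median F = 46.6%, 17 samples, 95% CI [37.9%, 59.8%]

locked <- probe_ensemble_helix(lock_ensemble(ens, bis$helixB), bis$helixA, cal)
locked
#> <freq_posterior> rescue factor -1.078 (4 bp): median F = 14.5%, 3 samples, 95% CI [9.3%, 14.9%]

posterior_correlation(wt, locked, pair_ref = "A-B")
#> <corr_posterior> A-B: median g = 0.286, P(g > 1) = 0, 95% upper bound 0.381
```

Reading the output: partial rescue (factor 0.345) in the wild-type
background maps to a frequency posterior centred near the true 50%; in the
background locking the competing helix, rescue vanishes and the inferred
frequency collapses, so the correlation posterior concentrates well below
1 — the two helices exclude each other, as constructed.

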