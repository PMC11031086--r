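# coreceptR

Evolutionary and proximal-signaling analysis of T-cell coreceptor motifs.

## What this package is for

The CD4 coreceptor binds peptide:MHC-II on the outside of the T cell and,
through intracellular motifs, shapes how the TCR-CD3 complex converts antigen
recognition into signaling (CD3ζ ITAM phosphorylation, ZAP70/PLCγ1 activation,
IL-2 production). Studies of such motifs combine two very different kinds of
computation:

1. **Molecular evolution on ortholog alignments** — which residues are
   conserved, which pairs covary, which codon sites evolved under purifying
   selection, and what ancestral sequences looked like; and
2. **Bespoke assay statistics** — paired-stimulation flow-cytometry histogram
   differencing, sucrose-gradient FFLISA normalization with raft (DRM) vs
   soluble (DSM) membrane AUC, IL-2 dose-response summaries, and
   percent-of-control summary tables comparing mutant cell lines with paired
   controls.

`coreceptR` implements both halves as a tested, reusable pipeline, plus a
seeded synthetic-data module that generates every input with known ground
truth so each estimator can be validated by parameter recovery.

## The statistics at the core

* **Conservation**: per-column Shannon entropy H(p) of the non-gap amino-acid
  distribution, z-scored across columns (population SD) so scores have mean 0
  and SD 1; lower = more conserved.
* **Covariation**: plug-in mutual information
  MI(i,j) = Σ p(a,b) log₂ p(a,b)/(p(a)p(b)) over jointly non-gap rows, with
  the average-product correction MIp = MI − (MĪᵢ·MĪⱼ)/MĪ. A pair is called
  covarying when MI > 4 and both conservation scores are < −0.5, or MI > 8
  and both are < −0.3, capped at the top 0.5% of all pairs by MI.
* **Per-site selection (FEL-style)**: MG94 codon model over the 61 sense
  codons (equal frequencies, transition/transversion ratio κ), site-wise
  synonymous rate α and nonsynonymous rate β fitted by maximum likelihood via
  Felsenstein pruning; LRT of β = α against χ²(1); purifying flag when β < α
  and p < 0.1; ω = β/α.
* **Ancestral reconstruction**: marginal posteriors at any internal node by
  two-pass pruning under JTT (or Poisson) with gaps as missing data.
* **Flow signaling**: agonist-minus-null bin-by-bin histogram subtraction
  (null rescaled to the agonist total), percent responders
  = 100·Σ max(diff, 0)/N_agonist, positive-mass-weighted mean intensity and
  SEM, 500-nearest-neighbour display smoothing.
* **Gradient FFLISA**: fraction-1 background subtraction, CD4
  percent-of-total, per-fraction channel/CD4 normalization, and trapezoid AUC
  over fractions 1–6 (DRM) and 6–10 (DSM), which sum exactly to the total.
* **Functional assays**: trapezoid IL-2 AUC on the log₁₀ dose axis for a
  30 µM, 1:3 titration, sensitivity at the measured ~41 nM point,
  engagement-induced endocytosis deltas, and integer percent-of-control
  tables (half-away-from-zero rounding).

## Worked example

```r
library(coreceptR)

# paired-stimulation flow histograms with a planted 30% responder fraction
pair <- gen_flow_pair(n_events = 10000, responder_fraction = 0.3,
                      shift = 1.0, seed = 7)
d <- subtract_background(pair$agonist, pair$null)
response_stats(d)
#> <response_stats> %responders=30.10 mean=2.497 sem=0.002701 pos.mass=3010

# sucrose-gradient FFLISA: LCK normalized to CD4, DRM/DSM AUC
prof <- subtract_fraction1(gen_gradient_profile(seed = 7))
auc_drm_dsm(normalize_channel_to_cd4(prof, "LCK"))
#> <auc_result> DRM (f1-6) 33.52 | DSM (f6-10) 9.439 | total 42.96

# IL-2 dose response (30 uM top, 1:3 titration)
s <- gen_dose_series(seed = 7)
dose_response_auc(s)      # 3410.5  (pg/mL x log10 nM)
sensitivity_at(s, 41)     # 43.5 pg/mL at the 41.15 nM titration point

# covariation calling rule on the deterministic 401-position fixture
fx <- make_covariation_fixture()
calls <- call_covariation(fx$pairs, fx$sites)
sum(calls$covary_call)                 # 401 of 80,200 pairs
attr(calls, "called_fraction")         # 0.005  (0.5%)
```

The percent responders (30.10) recovers the planted 30% fraction; the LCK
trace carries most of its area in the DRM half of the gradient (33.5 of 43.0)
because the generator places the LCK peak at the DRM center; and the calling
rule selects exactly 0.5% of all possible pairs on the fixture.

A full end-to-end run (simulation → per-line assay analysis → evolution stage
→ percent-of-control summary table, with a reproducibility manifest):

```r
run_pipeline(system.file("extdata", "demo_config.json",
                         package = "coreceptR"),
             out_dir = "demo_out")
```

There is also a command-line entry point (`inst/scripts/coreceptr`) with
`simulate`, `flow`, `gradient`, `dose` and `report` subcommands.

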