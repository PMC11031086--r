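---
title: "Models and methods in coreceptR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coreceptR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coreceptR` couples per-residue evolutionary analysis of coreceptor ortholog
alignments with the statistics of the cell-biology assays used to test motif
function. This vignette is the package's account of those methods: the models
and their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## 1. Evolutionary analyses

### Alignment handling

Alignments are anchored to a reference sequence (by convention a mouse
coreceptor sequence): columns that are insertions relative to the reference
are removed (`strip_nonreference_columns()`), and the remaining columns are
numbered consecutively from `ref_offset` (default 48, the first consistently
aligned residue when ortholog sets differ in start-codon usage). The codon
layer, when present, is trimmed in register and must translate to the protein
layer — this is validated at construction.

### Conservation

ConSurf-style Bayesian rate estimation is out of scope; what this package
reproduces exactly is the *normalization convention*: scores are z-scores of a
per-column variability measure, so the average over residues is 0 with SD 1,
and lower scores mean more conserved. The variability proxy is the Shannon
entropy (bits) of the non-gap column distribution. Population SD (divisor
*n*) is used so the SD-1 property holds exactly on any input. Invariant
columns (entropy 0) automatically receive the most negative score. Because
the proxy differs from a rate-based score, the calling thresholds (−0.5,
−0.3) are honored on the proxy scale; on real data the set of pairs that fire
may shift relative to a rate-based score. All-gap columns are unscored, and
an alignment whose columns all have identical entropy raises a diagnostic
error rather than returning 0/0.

### Covariation

`mutual_information()` uses the plug-in (maximum-likelihood) MI estimator
over rows that are non-gap in both columns, with no pseudocounts. Pairs with
joint coverage below 50% of rows (configurable; never fewer than 2 rows) are
unscored. The average-product correction,
`MIp(i,j) = MI(i,j) − mean_i × mean_j / mean_all`, is computed over scored
pairs. The calling rule is deliberately strict-inequality:
`MI > 4` with both conservations `< −0.5`, or `MI > 8` with both `< −0.3`.

The 0.5% selection is implemented as a *cap* applied after the thresholds
(`call_covariation(..., cap = TRUE)`, the default), ranking passing pairs by
MI with lexicographic tie-breaks. Whether that fraction was an outcome or a
cap in the original procedure is ambiguous; both behaviors are available
(`cap = FALSE` reports the uncapped fraction), and the cap is the default
because it makes the selected fraction a guaranteed property of the output.
The raw MI drives the rule by default (`mi_column = "mi_raw"`); MIp is
reported alongside.

### Codon model and per-site selection

The codon machinery uses an MG94-style model on the 61 sense codons with
*equal* codon frequencies. Single-nucleotide changes occur at rate α
(synonymous) or β (nonsynonymous), times κ for transitions; multi-nucleotide
changes have rate 0. Equal frequencies make the generator symmetric, so
transition probabilities come from a real symmetric eigendecomposition —
fast and numerically stable — and keep the simulator and estimator
self-consistent at desk scale. This deviates from HyPhy-style empirical
frequencies; on real data fitted ω values will differ somewhat from an
empirical-frequency fit.

Rates are normalized so that the expected substitution rate is 1 at
α = β = 1 for the fitted κ: branch lengths are expected neutral
substitutions per codon, and a global scale parameter absorbs any
inconsistency between the input tree's units and that convention.

`fit_global_kappa_and_scale()` fits κ and the scale (optionally plus one
shared ω) by Nelder–Mead on log-parameters from the deterministic start
(κ=2, scale=1, ω=1) — reruns are bit-identical. `fel_site_test()` then fits
per-site (α, β) by bounded quasi-Newton on log rates (bounds e⁻⁹–e⁴), a
one-dimensional golden-section fit for the null β = α, and refers
2·(lnL_alt − lnL_null) to χ²(1); the purifying flag requires β < α *and*
p < 0.1. No mixture correction is applied to the test distribution, and no
per-branch re-optimization is done per site. Invariant sites return NA
estimates with p = 1. Likelihoods use Felsenstein pruning with per-node
column rescaling; a 3-taxon exhaustive-summation oracle pins the
implementation to 1e-8 in the tests.

### Ancestral reconstruction

`marginal_ancestral_reconstruction()` computes per-site marginal posteriors
at any node by a two-pass (inside/outside) pruning algorithm: upward
conditional likelihoods, a downward complementary message with the
equilibrium frequencies at the root, posterior ∝ up × down, normalized per
site. Gaps are missing data (all-ones tip message). The JTT model (the
standard empirical choice for protein ortholog work; exchangeabilities and
frequencies obtained from phangorn) is the default; the symmetric Poisson
model exists for hand-checkable examples. MAP ties are broken alphabetically
and flagged — on a two-tip symmetric example the A/V posterior is exactly
0.5/0.5 and the flag fires.

Tree estimation is out of scope: trees are inputs (Newick with branch
lengths, parsed strictly — a parser warning is treated as a malformed tree).

## 2. Flow-histogram signaling analysis

`subtract_background()` subtracts the null-stimulation histogram from the
agonist histogram bin by bin after rescaling the null counts to the agonist
total (equal-size samples are the design target; real exports may differ
slightly). Percent responders is the positive difference mass over the
agonist total. Mean intensity and SEM are computed on the *positive part
only*: the procedure defines responders as positive bins but is silent on
how negative bins enter the mean, so they are excluded, with the positive
mass recorded and used as the effective *n* for the SEM (the effective-*n*
convention is likewise not specified by the source procedure; this choice is
flagged in the output). "500 nearest neighbors" smoothing is a centered,
edge-truncated moving average of 500 bins, applied strictly as a display
layer — statistics are always computed pre-smoothing.

## 3. Gradient FFLISA analysis

Fraction 1 of the 10-fraction gradient is assay background: its raw gMFI is
subtracted per channel, with negative results floored at 0 (negative gMFI is
nonphysical). CD4 percent-of-total, channel/CD4 normalization
(`channel[f]/CD4[f] × CD4%[f]`, with 0/0 → 0 since no CD4-bound signal can
be attributed to a CD4-free fraction), and trapezoid AUC on the unit-spaced
fraction index with zero baseline over fractions 1–6 (DRM) and 6–10 (DSM).
The shared fraction-6 endpoint makes DRM + DSM = total an exact identity.
Peak-detection or thresholded AUC variants of commercial software are not
emulated.

## 4. Functional assays

IL-2 dose-response AUC is the trapezoid integral of the mean reading against
log₁₀ concentration (titrations are plotted on log axes); zero-peptide wells
are excluded from the log axis and recorded separately. A dilution-index
axis is available behind `x_axis = "index"`. Sensitivity is the mean reading
at the *measured* titration point nearest the target (default 41 nM — the
7th point of a 30 µM, 1:3 series is 30000/3⁶ ≈ 41.15 nM), not a fitted-curve
interpolation. Endocytosis deltas subtract each 10 µM replicate from the
0 µM average (positive = internalization; negative values preserved).
Percent-of-control values are rounded half away from zero to integers with
sign preserved; summary tables fix control rows at 100 and mark missing
assays `ND`.

## 5. Synthetic data: the stated world

Each generator is a pure function of its parameters including the seed; every
operation draws from its own named RNG stream derived from the seed, so
extending one stream never shifts another and reruns are byte-identical.

* **Flow pairs**: 10⁴ events per stimulation (the per-sample couple count of
  the assay family), log₁₀-normal background (mean 1.5, SD 0.15), responders
  shifted by 1.0 log₁₀ unit (a strong phospho-shift, >6σ), binned on 64
  shared bins over [0, 5].

  The binning default deserves its own paragraph. Positive-part counting
  noise under the null is ≈ √(n_occupied/N) of total mass; at a 1024-bin
  resolution with any realistic population width this is 5–10% of events —
  incompatible with the ≤2-point null-recovery floor that the
  percent-responder estimator is required to meet at N = 10⁴. The 64-bin
  default matches the histogram resolution to the sample size (measured null
  noise: 1.65% mean over 30 seeds, recovery error within ±1.4 points for a
  planted 30% fraction). Resolution remains configurable; at high
  resolutions the percent-responder noise floor rises accordingly.
* **Gradient profiles**: background offset (50 gMFI) plus Gaussian peaks
  (SD 1 fraction) at the DRM (3) and DSM (8) centers, additive noise
  (SD 5), clipped at 0; fraction 1 receives background and noise only, so
  fraction-1 subtraction recovers the peaks. Default amplitudes place CD4 in
  both compartments, LCK mostly in the DRM, and CTxB (the raft marker)
  almost entirely in the DRM.
* **Dose series**: 12 points from 30 µM with 1:3 dilution; 4PL mean
  (bottom 0, top 2000 pg/mL, EC50 500 nM, Hill 1.5 — a mid-titration EC50 so
  the 41 nM point sits on the rising flank) times multiplicative lognormal
  noise with CV 0.1 (mean exactly 1), 3 replicates.
* **Protein MSAs**: conserved sites are invariant (rate 0); neutral sites
  evolve under the symmetric 20-state Poisson model; each covarying pair is
  one joint neutral character relabelled through a random permutation —
  perfect coupling, chosen over an energetic coupling model because it gives
  unambiguous high-MI ground truth.
* **Codon alignments**: MG94 with per-site ω and global κ on the given tree,
  equal frequencies, uniform root.

What the generators do **not** emulate: cytometer compensation/spillover and
FCS structure, gating, sucrose-density physics, ELISA standard curves,
alignment errors and indels (the pipeline removes reference-relative indels
anyway), among-site rate heterogeneity beyond the planted classes, and
phylogenetic correlation of MI background (real alignments share a tree; the
APC exists precisely because of this, but the generator's neutral background
is already independent across sites). A green parameter-recovery test
therefore establishes estimator correctness under the stated model, not
robustness to every artifact of real data.

## 6. Acceptance-scale choices

The acceptance suite runs the neutral-recovery target at its stated scale
(16 taxa, 300 codons; the global fit recovers ω within ±0.15 of 1). The
per-site FEL distributional check (ω = 0.1 vs neutral; ≥40% vs ≤15% flagged)
is run in the unit tests at 90 sites per regime to keep the suite inside its
time budget; at the full 300-site design the measured rates are 50.3% and
6.3%. Multi-seed recovery bounds (percent responders ±2 points and ≤2%
under the null; percent-of-control AUC 60 ± 10 for a 0.6× response) are
asserted on estimates aggregated over 24 seeds, mirroring how averaged
percent-responder values are reported in practice.

## 7. Known limitations

* The conservation proxy is entropy-based; thresholds tuned for rate-based
  scores may select different residues on real alignments.
* Equal codon frequencies bias ω estimates on compositionally skewed real
  data relative to empirical-frequency MG94 fits.
* χ²(1) asymptotics for the FEL LRT are anticonservative at low divergence;
  no mixture correction is applied.
* Branch-subset (foreground-only) selection testing is not implemented; the
  whole tree contributes to each site fit.
* The pipeline emits tables only; no plotting layer.
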