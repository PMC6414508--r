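---
title: "Methods: paired depot comparison of TMT adipose-tissue proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired depot comparison of TMT adipose-tissue proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotproteo)
```

## The analysis model

The package analyzes a paired two-depot proteome design: each subject
contributes one abdominal and one femoral subcutaneous adipose-tissue
sample, multiplexed with TMT isobaric labels. Protein-level signals are
summed reporter-ion S/N values, and an identical pooled control (a mixture
of all study samples) is carried in every LC-MS run as the inter-run bridge.

The processing chain, in fixed order:

1. **Score filter.** Proteins with identification score < 5 are removed
   (score exactly 5 is kept). The threshold is the conventional Sequest HT
   cut-off for low-confidence identifications.
2. **Intra-run loading normalization.** Within each run, every sample is
   scaled so its total signal (over present values) equals the highest total
   in the run. This removes per-channel loading differences under the
   assumption of equal protein input per channel.
3. **Inter-run normalization (IRS).** Per protein, the reference is the
   geometric mean of the control-channel values across the runs where the
   control is present; all samples in run *k* are multiplied by
   reference / control value in run *k*. After the step the control values
   of every such protein are exactly equal across runs, which is the defining
   property of a bridge-channel correction. A `global` mode (one scalar per
   run from control totals) is available for comparison.
4. **Blood correction.** Given a user-supplied exclusion list of
   blood-specific proteins, each retained value is multiplied by
   `T_i / (T_i − B_i)` (total over blood-listed signal per sample), the
   abundance the protein would have in a blood-free sample. The correction
   conserves per-sample totals and within-sample ratios exactly; blood
   proteins are removed and per-sample blood fractions reported.
5. **Imputation and transform.** Missing values are replaced by half of the
   smallest positive signal in the entire dataset (one global constant),
   then everything is log2-transformed.
6. **Univariate statistics.** Per protein: two-sided paired Student's *t*
   across subjects, Benjamini–Hochberg q-values over all proteins, and the
   geometric-mean fold change `2^mean(log2 abd − log2 fem)`. Proteins with
   p < 0.05 (strict) are flagged.
7. **Multivariate test.** Sample profiles are reduced by classical
   (Torgerson) metric MDS on pairwise Euclidean distances — equivalent to
   principal-coordinate/PCA scores — to `n_pairs − 1` components (7 for 8
   pairs, the maximal degrees of freedom of the paired design), and the
   per-subject score differences enter the one-sample Hotelling *T²* test:
   `T² = n d̄ᵀ S⁻¹ d̄`, `F = (n−p)/(p(n−1)) T² ~ F(p, n−p)`. With p = 1 this
   reduces exactly to the squared paired *t*.
8. **Morphology.** Paired *t* on per-subject fat cell sizes, and Spearman
   correlations between flagged proteins and fat cell size per depot
   (exact permutation null for n ≤ 9 without ties, *t*-approximation
   otherwise).
9. **Clustering report.** Flagged proteins are standardized per row
   (mean 0, sd 1) and clustered with Euclidean distances under the ward.D
   linkage convention — Ward's criterion applied to *unsquared* distances
   via the Lance–Williams recurrence. Merge heights therefore differ from
   ward.D2-style implementations that square distances first.

### Assumptions

* Equal protein amounts were labeled per channel (step 2 would otherwise
  remove genuine global differences).
* The pooled control is the identical mixture in every run; IRS is exact
  only under that assumption.
* The blood list is correct and complete; the correction removes listed
  signal but cannot detect unlisted contamination.
* Paired *t* assumes approximately normal within-pair log2 differences;
  with n = 8 pairs this is a working approximation, which is one reason the
  pipeline also reports the global multivariate test.

## The synthetic-data generator

`simulate_experiment()` emulates the study conditions so that every stage
has a test bed with known ground truth. Signal model per tissue protein *x*
and sample *i* (subject *s*, depot *d*, run *k*):

```
signal = baseline_x * 2^(u_xs ± Δ_x/2 + link_xsd) * batch_xk * loading_i * ε_xi
```

* `baseline_x`: log-normal across proteins, log2 mean 10, log2 sd 2 —
  reporter-signal totals spanning roughly four orders of magnitude, as in
  summed-S/N protein tables.
* `u_xs`: per-subject, per-protein biological effect (log2 sd 0.25),
  shared by the subject's two depots and therefore cancelling in the paired
  contrast.
* `Δ_x`: planted log2 depot effect, split symmetrically (+Δ/2 abdominal,
  −Δ/2 femoral) so the per-protein grand mean stays at baseline. The default
  map is the 22-protein reference effect set (fold changes 0.80–1.25).
* `batch_xk`: per-protein, per-run factor (log2 sd 0.20) — the quantity IRS
  must remove.
* `loading_i`: per-sample channel loading (log2 sd 0.25) — the quantity
  intra-run normalization must remove.
* `ε`: multiplicative measurement error with CV 0.10 by default
  (mean-one log-normal).

Blood proteins share one composition profile across samples and are scaled
per sample so the blood share of total signal equals a fraction drawn
uniformly from [0.18, 0.38]; the share is pinned exactly on the final
observed matrix (contamination is a property of the sample, not of the
measurement), so the generator's planted fraction is recoverable to
machine precision before censoring. The control channel is the pooled mean
of all study samples' pre-batch, pre-loading signals — identical in both
runs by construction, giving inter-run normalization a true invariant to
restore.

Fat cell sizes are bivariate normal per subject (abdominal mean 58.0 μm,
femoral 65.9 μm; sds 3.3·√8 ≈ 9.3 and 2.3·√8 ≈ 6.5 μm, converting the
reference standard errors at n = 8 to sds so the printed SEMs are
reproduced in expectation; within-subject correlation 0.6). Size-linked
proteins receive a subject-level component tied to the fat-cell-size latent
through a Gaussian copula (strength 0.8, amplitude 0.5 log2 — chosen so
that rank correlations around 0.6–0.7 emerge, the regime where n = 8
Spearman tests sit near p ≈ 0.03). A protein linked in *both* depots uses
one shared subject latent (overall adipocyte size), so the link cancels in
the paired contrast; a depot-specific link uses that depot's latent and
therefore adds genuine within-pair variance — a planted femoral-only
association necessarily makes that protein's depot effect noisier.

### Missingness

Two controls exist: left-censoring below a quantile of the observed signal
distribution (`detection_limit_quantile`, default 0.005) and uniform random
missingness (`missing_rate`, default 0). The default is censoring-only:
TMT reporter quantification is essentially complete per run for identified
proteins, so isolated missing-at-random cells are rare in this data type,
whereas low-signal dropout is real. The distinction matters because of the
paper-style *global* half-minimum imputation: a censored cell is genuinely
low, so the global half-minimum is close to its true value, while a
randomly missing mid-abundance cell would be imputed orders of magnitude
too low and act as a large artificial outlier in the paired differences.
Setting `missing_rate > 0` exercises exactly that behaviour on purpose.

All draws come from one seeded generator in fixed order; identical configs
give identical outputs.

### What the generator does not emulate

Peptide/spectrum-level structure, TMT isotope-impurity cross-talk and ratio
compression, structured (run-level) identification dropout, and any
non-log-normal abundance shape. Passing recovery tests therefore shows the
pipeline's algebra and calibration are right under the stated model, not
that real acquisitions satisfy that model.

## Numerical and design choices

* **"FDR q-value" = Benjamini–Hochberg** adjusted p-values, not Storey's
  π₀-estimated q-values; with several hundred tests and all q above the
  threshold the distinction is immaterial, and BH is the reproducible
  default. Flagging stays on unadjusted p < 0.05 (strict), mirroring the
  analysis the pipeline reproduces.
* **MDS flavor:** classical metric MDS on Euclidean distances (equal to PCA
  scores up to sign). Component signs are fixed by making each component's
  largest-magnitude score positive, for deterministic output. Variance
  explained is the retained eigenvalue sum over the sum of positive
  eigenvalues.
* **Hotelling implementation:** one-sample T² on paired difference vectors
  of the MDS scores — mathematically the two-dependent-samples test. A
  singular difference covariance (p too large, or degenerate data) is a
  hard error suggesting fewer components rather than a silently
  regularized statistic.
* **Degenerate statistics report missing, not significant.** Zero-variance
  paired differences with nonzero mean return a missing p-value with a
  warning (t = 0, p = 1 when the mean is also zero); zero rank variance
  makes Spearman's rho missing.
* **Totals over present values.** Normalization and blood-correction sums
  use non-missing entries only; imputation happens afterwards, matching the
  stage order of the original workflow.
* **Inter-run reference = geometric mean** of control values, preserving
  log-scale symmetry between runs; a protein absent from a run's control
  leaves that run untouched and is flagged in the report. A control value
  of exactly 0 is treated as missing with a warning.
* **Exactness caveat (compositional closure):** equalizing total signal is
  exact only when the samples have identical composition. With planted
  nonzero depot effects, the depot totals differ slightly, and total-based
  normalization introduces a common bias of order the signal-weighted mean
  planted effect (≈0.002 log2 under the default map) into every protein's
  fold change. The noise-free exactness tests therefore use a null effect
  map and a fixed blood fraction, where recovery is exact to machine
  precision; this closure bias is inherent to total-signal normalization,
  not to the implementation.
* **ward.D, not ward.D2**, to match the stated convention; dendrograms are
  also exported as Newick for interoperability.
* **Column clustering** of the heatmap is optional and off by default; only
  the protein axis is clustered.

## Problem sizes used by the test suite

Unit tests run on small constructed fixtures (2–8 subjects, 2–60 proteins)
plus default-size simulations (651 proteins × 18 samples). Calibration
checks use 2000 null proteins for the flag-rate/uniformity tests and 2000
replicate draws for the Hotelling null; recovery checks use n = 200
subjects for fold changes and n = 10000 for morphology means. These sizes
make the whole suite run in well under a minute while leaving Monte-Carlo
error far below the asserted tolerances.

## Known limitations

* The blood exclusion list is always user input; the package ships only a
  synthetic example list from its generator and does not curate a real one.
* With 8 pairs the FDR-adjusted results are expected to be null; the
  package reports q-values but the design is underpowered for
  protein-level discovery, which is precisely what the simulation shows.
* The pipeline starts at protein-level quantification; raw spectra,
  database search and PSM aggregation are out of scope.
* A p < 0.05 flag on 610 tests implies ≈30 expected false positives under
  the global null; the flagged count is a descriptive screen, not an
  error-controlled discovery set.
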