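# depotproteo

Paired-design analysis of isobaric-label (TMT) adipose-tissue proteomes:
abdominal versus femoral subcutaneous depots, from raw reporter-signal tables
to differential and multivariate statistics — together with a calibrated
synthetic-data generator so the whole pipeline can be exercised and validated
with no external data.

## The problem and who this is for

Upper- and lower-body subcutaneous adipose tissue differ in metabolic risk,
and paired biopsies from the two depots can be compared at the protein level
with multiplexed TMT quantification. Two practical obstacles dominate such
analyses, and this package implements the corresponding corrections as
reusable, tested components:

1. **Multi-run structure.** A 10-plex TMT experiment on 8 subjects × 2 depots
   needs two LC-MS runs; each carries the study samples plus one pooled
   control channel (an identical mixture of all samples). Within a run,
   channel loading differences are removed by equalizing each sample's total
   signal to the highest in the run. Between runs, per-protein batch effects
   are removed by *internal reference scaling* (IRS): for protein *x* with
   control values *c_xk* in run *k*, every sample in run *k* is multiplied by
   `geomean_k(c_xk) / c_xk`, which makes the identical control samples agree
   exactly across runs.

2. **Blood contamination.** Adipose biopsies carry residual blood; its
   proteins can account for a fifth to a third of the total signal. Given an
   exclusion list of blood-specific proteins, every retained protein value is
   rescaled to its abundance in a blood-free sample:

   ```
   final[x, i] = normalized[x, i] * Σ_x normalized[x, i] /
                 (Σ_x normalized[x, i] − Σ_blood normalized[x, i])
   ```

   The correction conserves each sample's total signal and all within-sample
   ratios; blood-listed proteins are removed, and the per-sample blood
   fraction is reported.

On the corrected table the package then applies the statistical chain of a
paired depot comparison: global half-minimum imputation of missing values,
log2 transform, per-protein two-sided paired Student's *t* with
Benjamini–Hochberg FDR q-values and geometric-mean fold changes
(`FC = 2^mean(log2 abd − log2 fem)`), Spearman correlation of protein levels
with adipocyte size (exact permutation p for n ≤ 9), classical
multidimensional scaling of the sample profiles to `n_pairs − 1` principal
coordinates followed by the paired Hotelling *T²* global test
(`T² = n d̄ᵀ S⁻¹ d̄`, `F = (n−p)/(p(n−1)) · T² ~ F(p, n−p)` on the
per-subject difference vectors), and Euclidean/ward.D hierarchical clustering
of the flagged proteins for heatmap reporting.

The synthetic generator (`simulate_experiment()`) emulates the full design —
two runs of 9 channels, 610 tissue + 41 blood proteins, planted log2 depot
effects, per-sample blood fractions in 18–38%, per-protein run batch effects,
channel loading, measurement noise, detection-limit censoring, and paired
fat-cell-size morphology (58.0 vs 65.9 μm) with size-linked proteins — and
returns the ground truth for every planted quantity, so parameter recovery
and statistical calibration are directly testable.

## Worked example

```r
library(depotproteo)

sim <- simulate_experiment(sim_config(seed = 1))
fit <- depot_fit(sim$proteins, sim$design,
                 blood = sim$blood, morphology = sim$morphology)
summary(fit, n_top = 5)
```

```
Paired depot proteome comparison
  proteins: 651 quantified, 651 after score filter, 610 analyzed after blood removal
  blood contamination: 18-35% of total signal (41 proteins removed)
  differential (paired t, alpha = 0.05): 42 flagged of 610
Paired Hotelling T2: T2 = 31.42, F(7, 1) = 0.6413, p = 0.7481
  7 components explaining 87.5% of total variation, n = 8 pairs
  fat cell size: abdominal 59.2 +/- 2.8 vs femoral 66.7 +/- 2.6 um (paired p = 0.0201)
  top differential proteins:
 accession  gene    FC        p     q
    P07355 ANXA2 1.194 0.000185 0.113
    P00338  LDHA 0.866 0.003300 0.546
    P13489  RNH1 0.854 0.003970 0.546
     T0298 T0298 0.877 0.004330 0.546
     T0587 T0587 1.109 0.004820 0.546
```

Reading this: 651 simulated proteins survive the identification-score filter
(score ≥ 5); removing the 41 blood-listed proteins leaves 610 for analysis,
with 18–35% of each sample's signal attributed to blood. 42 proteins have
paired-t p < 0.05 (the 22 planted effects plus the expected ≈5% of the 588
null proteins), none pass the FDR threshold at this sample size (all
q > 0.05), and the global multivariate depot difference is not significant
for this draw — all consistent with an 8-pair design. `coef(fit)` returns
the per-protein log2 fold changes, `plot(fit, "heatmap")` the clustered
standardized heatmap, and `run_pipeline(out_dir, sim = sim_config(seed = 1))`
writes every intermediate table plus `summary.json`.

A thin CLI with `simulate`, `normalize`, `bloodcorrect`, `stats`, `run` and
`reproduce` subcommands is installed at `exec/depotproteo`.

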