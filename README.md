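# scarvalid

Genomic-scar HRD classification and the analytical validation of a
scar-based assay, as a reproducible R package.

## The problem

Homologous recombination deficiency (HRD) sensitizes tumors to PARP
inhibitors and platinum chemotherapy. HRD leaves persistent copy-number
"scars": excess breakpoints per chromosome arm, short segments, oscillating
copy-number runs, and genome-wide loss of heterozygosity (gLOH). A
scar-based classifier scores these patterns with a gradient-boosted tree
ensemble and calls a sample HRD-positive above a prespecified cutoff of
0.7 — independent of whether an HRR gene mutation is found.

Before such an assay can be used clinically it needs analytical
validation: limit of blank (LoB), limit of detection (LoD) against tumor
purity, concordance against a surrogate truth marker, factorial-design
precision (reproducibility and repeatability), and robustness to
interfering substances. The underlying specimens in such studies are
proprietary, so `scarvalid` pairs every estimator with a synthetic
copy-number/VAF data generator: each statistic can be exercised end to end
on data whose ground truth is known, and each count-derived published
statistic can be recomputed exactly from its printed counts.

The package provides, as tidyverse-style functions over tibbles:

- **`genome_sim`**: a deterministic toy genome (22 × 100 Mb, centromere at
  40%), seeded simulation of scarred vs. quiet allele-specific copy-number
  profiles and SNP VAF tables, matched-normal dilution
  (`effective purity = dilution × purity`), Bernoulli QC failures, and
  interferent perturbation hooks (`build_genome()`, `simulate_specimen()`,
  `dilute_replicate()`, `apply_perturbations()`,
  `generate_study_cohort()`).
- **`scar_features`**: breakpoints per arm, segment-size spectrum,
  oscillation chains, and gLOH — genome-wide and within telomeric /
  centromeric arm portions — assembled into a fixed 121-feature schema
  (`assemble_features()`, `scar_feature_matrix()`).
- **`hrd_caller`**: stratified 7:3 split, XGBoost training, cutoff
  calibration to 90% sensitivity, and three-state calls
  (positive / negative / unknown, with unknowns for QC failure or
  effective tumor purity below 10%) — `train_hrd_caller()`,
  `select_cutoff()`, `make_call()`.
- **`validation_stats`**: Wilson score intervals, validity-weighted LoB
  FPR, VAF-derived dilution factor and adjusted tumor purity, hit-rate LoD
  determination, PPA/NPA, majority-call references, reproducibility,
  repeatability, and interference percent agreement.
- **`study_runner`**: `run_study()` orchestrates
  simulate → features → score → statistics for each study design with
  deterministic seeds and stable TSV/CSV/JSON outputs;
  `verify_printed_tables()` recomputes every count-derived statistic from
  a transcribed table fixture.

## Key quantities

For counts `x/n`, every interval is a two-sided Wilson score interval
(normal quantile, no continuity correction). Concordance uses
`PPA = a/(a+c)`, `NPA = d/(b+d)` with unknown-status samples excluded by
default. LoB FPR is `Σ X·V / Σ V` over replicates (V = valid, X =
positive). The LoD is the median, across specimens, of the mean adjusted
tumor purity (undiluted computational purity × VAF-derived dilution
factor) at the lowest dilution level reaching a 95% hit rate.

## Worked example

```r
library(scarvalid)

genome  <- build_genome()                       # 22 x 100 Mb toy genome
trained <- train_hrd_caller(genome = genome, seed = 1)
trained$holdout_auc
#> [1] 1

lod <- run_study("lod", model = trained$model, genome = genome,
                 seed = 201, quiet = TRUE)
lod
#> <study_result: lod> 282 replicates
#>   lod_tp_pct: 20.44
#>   n_replicates: 282
```

A classifier trained on 400 synthetic specimens (200 scarred, 200 quiet,
purities 0.2–0.9) separates the planted contrast perfectly on the 120
held-out samples (AUC 1). The dilution study then titrates three
HRD-positive specimens to five target purity levels (282 replicates); the
lowest level passing a 95% hit rate per specimen gives per-specimen
adjusted tumor purities whose median — here 20.44% tumor purity — is the
assay's limit of detection. Published count-derived statistics are checked
exactly:

```r
v <- verify_printed_tables()
all(v$pass, na.rm = TRUE)
#> [1] TRUE
subset(v, statistic == "ppa", c(computed_pct, computed_lower, computed_upper))
#>   computed_pct computed_lower computed_upper
#> 1           90          82.56          94.48
```

`plot_score_distribution()`, `plot_dilution_series()` and
`autoplot()`/`tidy()`/`glance()` on the fitted model cover the usual
inspection plots and summaries.

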