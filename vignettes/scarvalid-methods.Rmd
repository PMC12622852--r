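---
title: "Methods: scar-based HRD classification and its analytical validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scar-based HRD classification and its analytical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scarvalid` implements two things that are usually entangled in a
diagnostic-assay validation: the scar-based HRD classifier itself, and the
statistical machinery used to validate such an assay. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic data can and cannot show.

## 1. The synthetic genome and scar process

All coordinates live on a configurable toy genome, by default 22
chromosomes of 100 Mb with the centromere at 40% of each chromosome
(`build_genome()`), 0-based half-open internally and 1-based inclusive in
exported files. A real genome's coordinates can be supplied instead; the
default keeps everything self-contained with no reference downloads, and
at 2.2 Gb it is close enough to a human autosomal complement that rates
per 100 Mb carry over.

Profiles are generated arm by arm (`simulate_profile()`):

- **Breakpoints** are Poisson with rate `breakpoint_rate_pos = 8` /
  `breakpoint_rate_neg = 1.5` per 100 Mb per arm. The positive rate gives
  roughly 170 breakpoints per scarred genome and ~30 per quiet genome —
  the order of magnitude seen when highly rearranged tumor genomes are
  compared with diploid-dominated ones.
- **Short-segment excess**: each breakpoint spawns a companion breakpoint
  0.5–8 Mb away with probability `short_segment_bias_pos = 0.4`
  (`0.05` for negatives), shifting segment-size mass below 10 Mb for
  scarred genomes.
- **Oscillation bursts**: `oscillation_burst_rate_pos = 6` bursts per
  scarred genome (0.3 per quiet genome), each an alternating
  `(t, t+1)` run of 4–10 segments of 0.3–3 Mb. The generator's burst
  definition deliberately matches the feature detector's chain definition
  so that recovery tests are interpretable.
- **Copy-number states** are drawn from weights favoring 2 (strongly so
  for negatives); LOH (minor copy 0) is planted per segment at
  `loh_fraction_pos = 0.35` vs. `loh_fraction_neg = 0.05`.

Segments are merged to maximal segmentation, so every profile satisfies
the container invariants: sorted, non-overlapping, tiling every arm, no
identical adjacent same-arm states, and `minor <= total - minor`.

**SNP VAFs.** Heterozygous SNPs are placed at `snp_density = 1` per Mb
(a realistic order for a hybrid-capture panel's usable germline hets, and
enough — ~2,200 per genome — for stable dilution factors); 5% of
positions are homozygous-reference sentinels. For a het SNP in a segment
`(t, m)` at purity `rho`, with the alternate allele on a random
haplotype,

```
E[VAF] = (rho * c_alt + (1 - rho)) / (rho * t + 2 * (1 - rho)),
```

read depth is Poisson with mean `depth = 500` scaled by the local
copy-number mass, and the observed VAF is binomial. At `rho = 0` every
het SNP reverts to 0.5; in a pure tumor a (2, 0) segment's lost allele
reads 0.

## 2. Purity degradation: the observed profile

Real copy-number callers lose low-contrast events as tumor purity falls.
The paper-facing pipeline treats segmentation as given, so `scarvalid`
models the loss at the boundary level (`observe_profile()`): a boundary
between states is detected with probability
`pnorm((contrast - 2 * noise_sd) / noise_sd)`, where contrast is the
log-ratio difference of the two segments at the effective purity, or — for
copy-neutral LOH boundaries — the allelic-imbalance difference against a
0.04 VAF threshold. Missed boundaries merge segments, which inherit the
longest member's state. With `noise_sd = 0.05` (a typical log-ratio noise
scale for high-depth panels), a 2-vs-3 transition stays detectable down to
roughly 15% purity, so scar signal degrades in the purity range where the
assay's limit of detection should sit. This mechanism is this package's
own device: it makes scores purity-dependent without simulating reads,
and it is the single knob (`noise_sd`) behind the LoD behavior.

## 3. Features

`assemble_features()` produces a fixed, documented 121-feature schema
(`feature_schema()`): the three scar families × three regions
(genome-wide, telomeric, centromeric) plus per-chromosome summaries and
gLOH. The production feature list of the assay this emulates is
proprietary and longer (>100 features); this schema spans exactly the
described families without pretending to replicate undisclosed features.

Decisions the underlying description leaves open, fixed here:

- **Breakpoint basis**: a breakpoint is any change in the
  `(total, minor)` pair — copy-neutral LOH boundaries are scars. A
  `total`-only basis is available (`feature_config()`).
- **Arm portions**: telomeric and centromeric windows are each 20% of arm
  length (`f_tel = f_cen = 0.2`), anchored at the telomere and centromere
  respectively; no extent is published, and 20% keeps windows
  non-overlapping on every arm while being large enough to catch the
  clustered events the regional features exist for.
- **Oscillation**: a chain is a maximal run of ≥3 same-arm segments whose
  totals alternate between exactly two states; alternation is judged on
  total copy number only.
- **gLOH**: fraction of the genome in LOH (minor 0, total ≥ 1), excluding
  contiguous LOH runs covering ≥90% of an arm (the conventional
  whole-arm exclusion); homozygous deletions do not count.

## 4. The classifier

An XGBoost binary classifier (logistic objective, `max_depth = 3`,
`eta = 0.1`, 150 rounds, single-threaded) is trained on a labeled
synthetic cohort after a stratified 7:3 split. Desk-scale hyperparameters
are deliberate: a few hundred samples and 121 features need shallow
trees; the production model's hyperparameters are unpublished.

The positivity cutoff is calibrated as the **largest** threshold
retaining the target sensitivity (90%) on held-out scores, ties resolved
upward (`select_cutoff()`). The model ships with its calibrated cutoff,
but `run_study()` overrides it to the prespecified 0.7 by default for
report parity — on well-separated synthetic scores the calibrated value
is much higher than 0.7 and either choice calls the same samples; 0.7 is
what the emulated assay prespecifies. Calls are three-state
(`make_call()`): QC failure → unknown (`qc_fail`, no score); effective
tumor purity < 10% → unknown (`low_purity`); otherwise positive iff
`score >= cutoff`, with the tie at the cutoff counted positive (the
textual rule "above the cutoff" is ambiguous; ≥ is chosen and
configurable). Blank specimens with no tumor compartment carry `NA`
purity and skip the purity gate.

## 5. Validation estimators

All intervals are two-sided Wilson score intervals with the exact normal
quantile (1.959964 at 95%) and **no continuity correction** — this exact
variant reproduces, digit for digit, every published interval in the
transcribed tables (checked by `verify_printed_tables()` and the test
suite). Report percentages are rounded half-up to two decimals.

- **LoB FPR**: `sum(X * V) / sum(V)`; invalid replicates leave both sums.
- **Dilution factor**: over het SNPs imbalanced in the undiluted sample
  (|VAF − 0.5| > 0.02), the coverage-weighted deviation ratio
  `sum(|v_d − .5| * depth_d) / sum(|v_u − .5| * depth_u)`. The plain
  deviation ratio is biased for copy numbers other than 2 because the
  deviation's denominator `rho * t + 2(1 − rho)` is purity-dependent;
  coverage is proportional to that same denominator, so the weighted
  ratio is linear in purity for every copy-number class. Adjusted tumor
  purity is the undiluted computational purity times this factor.
- **LoD**: per specimen, the smallest dilution level with empirical hit
  rate ≥ 95%; its mean adjusted purity is the specimen's value; the
  overall LoD is the median across specimens. Raising the threshold can
  never select a lower level (monotonicity is tested).
- **Concordance**: `PPA = a/(a+c)`, `NPA = d/(b+d)`, unknown-status
  samples excluded by default; optionally unknowns count against NPA.
- **Precision**: reference status per specimen by majority call with the
  ≥50% tie going to positive (verbatim rule); reproducibility is
  agreement of valid known-status replicates with the reference, pooled
  separately over positive- and negative-reference specimens;
  repeatability counts within-run pairs whose two valid replicates agree,
  dropping pairs with an invalid or unknown member from both sums.
- **Interference**: percent agreement per (specimen, substance) against a
  control-condition majority reference; specimens without controls (the
  necrosis series) use their own majority and are excluded from the
  overall aggregate but reported at sample level.

One published value is deliberately not reproduced: the lower interval
bound of 96.88% for 112/112 interference agreement. Wilson gives 96.68%
and Clopper–Pearson 96.76%; the origin of 96.88% is unidentifiable, so
the package reports the Wilson bound and the acceptance suite documents
the discrepancy instead of imitating it.

## 6. Study designs

`generate_study_cohort()` defaults to the emulated study shapes: LoB
5 normal specimens × 12 replicates (no QC failures); LoD 3 positive
specimens × 5 target-purity levels with (19, 19, 19, 19, 18) replicates
per level = 282, HC failure rate 5%; precision 22 specimens (11+11) × 36
replicates over 3 sites with the two factor-group designs (3 lots × 2
sequencers, or 2 lots × 3 runs) = 792, LC/HC failure rates 0.5%/1%;
concordance 101 surrogate-positive + 130 surrogate-negative specimens
with purities uniform on 0.08–0.92; interference 11 spiked samples (nine
substances plus controls) and a 6-sample necrosis series. The LoD
"dilution levels" are *target effective purities*; the mass fraction
mixed with matched normal is `level / purity`, so a specimen must be at
least as pure as its highest level (LoD specimen purities default to
0.58–0.66). Generation is cheap, so the defaults are the full study
sizes rather than reduced ones; tests that only probe report shapes use
smaller custom designs.

Interferent effects default to null — matching the emulated finding of
full agreement in spiked samples — with depth/noise hooks available for
robustness experiments. QC failures are two independent Bernoulli gates
(LC and HC) because only failure counts, not mechanisms, are described.

## 7. Determinism and numerical choices

Every generator takes an integer seed; sub-seeds are derived
arithmetically, so identical (design, params, seed) give byte-identical
manifests, and `run_study()` reruns are byte-identical including written
files (floating-point columns are serialized at fixed six-decimal
precision to keep write → read → write stable). XGBoost runs
single-threaded with a fixed seed, making serialized model artifacts
reproducible. Degenerate inputs fail loudly with typed conditions:
empty manifests, overlapping segments (reported with line numbers),
single-class training sets, zero valid replicates.

## 8. What the simulation does and does not show

The generator plants exactly the contrasts the features measure, so
recovery tests demonstrate that the pipeline's plumbing — features,
training, calibration, calls, statistics — is correct, not that the
classifier would reach any particular accuracy on real tumors. Real FFPE
data differ in ways deliberately out of scope: segmentation error beyond
the boundary-detection model, wave/GC artifacts, subclonality, FFPE
chemistry, and reversion-mutation truth labels (truth here is a
simulation input). The LoD mechanism, likewise, is only as realistic as
the boundary-detection model; its value on synthetic data (~20% tumor
purity at default noise) characterizes the pipeline, not any assay.
Problem sizes in the tests (500 random profiles for oracle equivalence,
a 400-specimen training cohort, 20 label shuffles, 282-replicate
dilution series) were chosen as the smallest sizes at which the checked
properties are stable.
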