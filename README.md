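# exposcreen

Two-step GC-MS/MS biomonitoring of environmental pollutant mixtures in
human plasma: screening triage of a wide chemical panel, QC-gated targeted
quantitation, and cohort statistics on left-censored concentrations — with
a synthetic-data generator that makes the whole pipeline testable without
instrument data.

## The problem

Exposure studies that target many pollutants at once face a structural
trade-off: most chemicals in a wide panel are present near or below
detection limits, so a single targeted method wastes effort on analytes
that can never support statistics. A two-step design fixes this. A
semi-quantitative **screening** step runs the full panel and removes
chemicals that fail analytical quality control or are detected in fewer
than 20% of study samples; the **targeted** step then quantifies the
survivors under full QC and a reporting layer computes cohort statistics
on the censored results. `exposcreen` is aimed at analytical-exposure and
exposome researchers who want that flow as auditable, composable R
functions rather than spreadsheet conventions.

## What is implemented

* **Detection** — the four-criterion detect call per peak: retention time
  within ±0.1 min of the calibration standard (inclusive), quantifier area
  strictly above the most recent instrument blank, peak-shape similarity
  `exp(-(Δw² + Δa²)/2) ≥ 0.6`, and qualifier/quantifier ratio within ±20%
  of the calibration standards when a qualifier transition exists.
* **Calibration** — matrix-matched weighted least squares over detected
  levels (unweighted or 1/x, chosen by minimum summed squared relative
  back-calculation error), acceptance at ≥ 3 detected levels and R² > 0.8,
  inverse prediction, duplicate averaging, and the method-blank
  subtraction rule (blank mean > 10 × lowest calibration level and blank
  RSD < 50%).
* **Screening triage** — gate order analytical → recovery (< 50% excludes)
  → detection rate (< 20% excludes, strict), an append-only gate ledger,
  and panel assembly with flagged additions that bypass screening.
* **Targeted QC** — matrix-spike RSD gate (> 60% excludes), inter-batch
  Kruskal–Wallis gate (p < 0.01; chi-square default, Monte-Carlo
  permutation option), SRM percent-error gate (|PE| > 50% in more than one
  batch excludes, unusable batches ignored), LOD = 3 × SD of low-level
  spikes, and censoring with LOD/√2 substitution.
* **Cohort statistics** — detection-rate-conditional summaries (median
  only above 50% detects; maxima over uncensored values), Wilcoxon
  rank-sum comparisons with exact enumeration for groups of ≤ 8 and a
  Bonferroni cut-off of `0.05 / n_eligible` (≥ 30% detects), parent–child
  Spearman correlation matrices paired by family, and reference-median
  ratios at one-decimal half-up rounding.
* **Synthetic study generator** — a family-structured cohort (72 probands,
  29 controls, 76 parents; 37/33/32 mother-father/father-proband/
  mother-proband pairs), per-chemical log-normal exposures with age slopes
  and a shared family effect sized analytically to a target Spearman
  correlation, and a linear instrument model with batch effects, injection
  CV, additive baseline noise and the full per-batch QC complement.

See `vignettes/two-step-biomonitoring.Rmd` for the models, the boundary
conventions, and the reasoning behind every open design choice.

## Worked example

The `analysis/` scripts run the full study end to end
(`Rscript analysis/01_simulate.R`, then `02_screening.R`,
`03_targeted_quantitation.R`, `04_cohort_statistics.R`), writing stage
tables under `results/`. The same flow programmatically:

```r
library(exposcreen)

sim <- simulate_study(synthetic_config(seed = 1))
run <- run_pipeline(sim)
run
#> two-step biomonitoring run
#>   screened: 20 chemicals
#>   excluded (analytical): 2, excluded (rate): 3, advanced: 15
#>   targeted panel: 15 (incl. 0 additions)
#>   excluded by targeted QC: 8, reported: 7
#>   7 chemicals eligible for tests, adjusted alpha 0.007143 (0.007)
```

Reading the report: of 20 screened chemicals, the two zero-response
chemicals fail the analytical gate and the three trace-level chemicals
fall below the 20% detection-rate gate; 15 advance. Targeted QC (spike
RSD, inter-batch Kruskal–Wallis, SRM accuracy, estimable LOD) reports 7,
and the Bonferroni-adjusted cut-off for the 7 test-eligible chemicals is
0.05/7 = 0.007. `run$summary_table` holds the per-group detection rates,
medians and maxima (`"<LOD"` where reporting rules suppress them),
`run$comparisons` the adults-vs-children, proband-vs-control and
mother-vs-father rank-sum results — with the defaults' positive age slopes,
the persistent pollutants come out significantly higher in adults —
and `run$correlations` the mother- and father-child Spearman matrices.

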