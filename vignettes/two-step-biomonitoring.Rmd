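---
title: "A two-step GC-MS/MS biomonitoring pipeline: models, gates, and design choices"
author: "exposcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-step GC-MS/MS biomonitoring pipeline}
  %\VignetteEncoding{UTF-8}
---

## The problem

Wide-panel biomonitoring of environmental pollutants in human plasma faces a
structural difficulty: most chemicals in a large targeted panel will not be
detected often enough in a given cohort to support statistics. A two-step
design addresses this: a semi-quantitative **screening** run over the full
panel rules out chemicals that are analytically unworkable or rarely
detected, and a **targeted** run then quantifies the surviving subset under
full quality control — matrix-matched calibration, method blanks, matrix
spikes, certified reference serum — before a reporting layer computes
cohort statistics on the left-censored concentrations.

`exposcreen` implements that whole flow as composable, tested R functions,
plus a synthetic-data generator that emulates the statistical structure of a
family-based cohort study so every stage is testable without instrument
data. The `analysis/` scripts run the four stages over one simulated study;
`run_pipeline()` chains them programmatically.

## The synthetic study

The generator is not a toy fixture: it is the package's definition of the
study conditions, and its defaults are fixed at the emulated design.

**Cohort.** 72 probands (affected children), 29 unrelated neurotypical
controls, and 76 parents, with 37 mother/father, 33 father/proband and 32
mother/proband pairs realized *by construction*: the smallest feasible
number of full mother/father/proband triads is solved from the pair counts
and the parent total (32 triads with the defaults), remaining pairs and
singles fill the rest, and controls carry no family id. Sex is drawn per
role (83% male probands, 62% male controls; parents' sex is fixed by role)
and ages are uniform on per-role ranges chosen so the role means match the
emulated cohort (probands 3–14 y, mean 8.5; controls 7.4–17 y, mean 12.2;
parents 32–50.6 y, mean 41.3).

**Exposures.** Per chemical, log concentration is Gaussian:
`log C = log(GM) + beta_age * age + b_family + e`, with total SD `log(GSD)`.
The family effect `b_family` is shared by family members; its variance
fraction is set from the target Spearman correlation `rho_S` via the exact
bivariate-normal relation `rho_P = 2 sin(pi rho_S / 6)` — no numerical
solving is needed because, conditional on age, family members' log
concentrations are bivariate normal with Pearson correlation equal to the
shared-variance fraction. Subjects without a family id receive an
independent effect of the same size so that every subject has the same
marginal distribution. The default target correlation is 0.6, the level
reported for the most strongly shared household exposures.

**Instrument response.** Integrated peak areas follow
`area = slope * conc * B * (1 + eps) + intercept + eta`, with per-injection
multiplicative noise `eps ~ N(0, cv)` (default cv = 5%), a per-chemical,
per-batch sensitivity factor `B = exp(N(0, sd_batch))` (default 10%), and an
additive baseline term `eta ~ N(0, slope * noise_floor)`. The additive term
is what makes detection non-trivial: without it, any chemical with nonzero
response would be "detected" in every sample. The per-chemical
`noise_floor` defaults to `lod_true / 3`, so that the 3-SD detection-limit
estimate recovers the design LOD, and the instrument-blank reference area is
`intercept + 3 * slope * noise_floor` — an upper envelope of the integrated
baseline, giving a realistic sigmoid detection curve centred near the LOD.
Every stated noiseless-limit property holds when `response_cv`,
`noise_floor` (and, where relevant, the retention-time and shape jitters)
are zero; the batch factor may stay on because per-batch matrix-matched
calibration cancels it exactly.

**Batch layout.** Five batches; study samples are assigned to batches as
evenly as possible (with 177 subjects, exact equal batches are impossible;
sizes differ by at most one). Each batch carries six calibration levels
(0.005–10 ng/mL, four orders of magnitude), instrument blanks (the first
acquisition of every batch, so each sample has a "most recent" blank),
five method blanks, six matrix spikes, three SRM aliquots and two low-level
spikes; donor serum pairs (2 unspiked + 6 spiked) run in batch 1.
Calibration standards are prepared fresh, so the optional volatile-loss
scenario (`batch_loss`) zeroes only stored sample types in the final batch
— exercising the rule that a chemical's unmeasurable batches are dropped
from gates and statistics. An optional interferent injector shifts study
retention times beyond the window for negative tests, and an optional
contamination term exercises the blank-subtraction gate.

**What the generator does not emulate.** Chromatographic raw signal (it
starts at integrated areas), extraction chemistry beyond a multiplicative
recovery factor, nonlinear response, heavy-tailed or correlated-across-
chemical exposures, and assay drift within a batch. Passing tests therefore
demonstrate the *logic* of the gates and statistics under the assumed
response and exposure models, not robustness to every real-data pathology.

## Detection and screening

A peak is a detect when all applicable criteria pass: retention time within
±0.1 min of the calibration standard's (inclusive); quantifier area strictly
above the most recent instrument blank's; peak shape similar to the
calibration standard's; and qualifier/quantifier ratio within ±20%
(relative, inclusive) of the calibration standards' when a qualifier
transition exists. Boundary conventions are centralized and deliberate:
"within ±" is read inclusive, "above" strict. Peak-shape similarity has no
published formula, so it is operationalized as a Gaussian kernel on the
relative deviations of width-at-half-height and asymmetry,
`exp(-(dw^2 + da^2)/2)`, pass at 0.6 (configurable); it is 1 at identity and
decreases monotonically in either deviation. Detection is called per
injection; a sample counts as detected if either duplicate passes (the
per-injection calls are retained in the output).

Screening gates run in a fixed order so exclusion reasons are unambiguous:
**analytical** (calibration acceptable: at least 3 detected levels and
R² > 0.8 — here, acceptable in a majority of batches, since the synthetic
study is batched while a single screening run would have one curve), then
**recovery** (donor-serum recovery is advisory above 50% and an exclusion
below), then the **detection-rate** gate (strictly below 20% of study
samples excludes; exactly 20% advances). Chemicals of special interest may
be added to the targeted panel afterwards, flagged as bypassing screening.

## Calibration and quantitation

Curves are weighted least squares of mean duplicate response on nominal
concentration over the *detected* levels only, either unweighted or with
1/concentration weights. The weighting mode is chosen per chemical and
batch by the smaller sum of squared relative back-calculation errors of
the levels, with ties (e.g. noiseless data) broken to unweighted. A point
worth stating honestly: under this relative-error criterion the
1/concentration mode wins for most realistic noise structures — including
homoscedastic noise — whenever the levels span orders of magnitude, because
the lowest level dominates the relative error. That is exactly why 1/x
weighting is the de-facto default in quantitative chromatography, and the
criterion is kept because it is the one a validation protocol can state
precisely.

Quantitation is inverse prediction `(response - intercept)/slope` on
acceptable curves only (never extrapolated from unacceptable ones), with
negative back-calculations floored at zero and flagged. Non-detected
injections are non-detects; duplicates average arithmetically, a single
quantified injection is used alone and flagged (discarding it would halve
the sample size), and two missing injections yield a missing record.
Method-blank subtraction applies per chemical and batch only when the blank
mean exceeds 10× the lowest detected calibration level *and* blank RSD is
below 50%; it operates on the concentration scale (the response scale would
be equivalent for a linear curve up to the intercept, and concentrations
are what the rest of the pipeline sees).

## Targeted QC gates

Per panel chemical: matrix-spike **RSD** pooled over batches must not
exceed 60% (strict: exactly 60% passes); the **Kruskal–Wallis** test on
spikes across batches must not reject at p < 0.01; and the **SRM** percent
error `100 (measured - certified)/certified` must not exceed 50% in
absolute value in more than one batch, with unusable batches (e.g.
coelution) excluded from the count. Gates with insufficient data are
skipped with a warning and retain the chemical — except that a chemical
with no estimable LOD cannot be reported at all. Batches where all matrix
spikes are non-detect are treated as unmeasurable for that chemical and
dropped from gates and statistics (the volatile-loss signature).

The Kruskal–Wallis p-value defaults to the tie-corrected chi-square
approximation on k−1 degrees of freedom. At the design's group sizes (5
batches × 6 spikes) that approximation is *conservative* in the far tail:
simulation places the realized type-I error at the 0.01 cut near 0.3%. A
Monte-Carlo permutation p (`method = "permutation"`) is therefore provided
and restores nominal calibration — about 1% null exclusions at the 0.01 cut
— and is what the calibration checks in the test suite and acceptance
script exercise; the chi-square default matches standard practice and errs
on the side of retaining chemicals.

**LOD** is 3 × SD of the measured concentrations of ~10 low-level spikes
(the multiplier is a field convention; validation protocols often name the
estimator without stating the formula). The screening-era **IDL** uses the
one-sided 99% Student-t multiplier, `t(0.99, n-1) × SD` of back-calculated
replicate injections. Values strictly below the LOD are censored and
replaced by LOD/√2 for statistics — a substitution with acceptably low bias
below ~50% censoring. The divisor is a single configuration constant
because the literature contains both LOD/√2 and LOD/2 conventions; the
default is √2.

## Reporting layer

Summaries are detection-rate-conditional: medians (over substituted values)
are reported only above 50% detects — read strictly, so exactly 50% reports
"<LOD"; the rule is stated both as "> 50%" and as "not < 50%" in common
usage and the conservative reading was chosen — and maxima are taken over
uncensored values only. Group
comparisons use the two-sided Wilcoxon rank-sum test on substituted values
(substitution creates honest ties at LOD/√2), with eligibility at ≥ 30%
pooled detects and significance at the Bonferroni-adjusted cut-off
`0.05 / n_eligible` (23 eligible chemicals gives the published 0.002). The
rank-sum p is computed by exact enumeration of all rank assignments when
both groups have ≤ 8 observations (ties handled by midranks) and by the
tie-corrected normal approximation with continuity correction otherwise.
Parent–child Spearman correlation matrices pair by family id over the full
child-chemical × parent-chemical grid, with cells under 5 complete pairs
missing rather than zero. Reference-median ratios round half away from
zero to one decimal, reproducing the published comparison table exactly
from its printed medians.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-tied Kruskal–Wallis values
(including values tied within numerical precision, so quantitation
round-off cannot masquerade as a batch effect) give H = 0, p = 1; constant
vectors give a missing Spearman cell; weighting-choice ties go to
unweighted; fewer than two detected calibration levels yield a curve with
no slope and `acceptable = FALSE` rather than a silent extrapolation.

The simulation-based checks use deliberately moderate problem sizes so the
whole suite runs in minutes on one core: the censored-recovery study uses
200 replicate cohorts of 60 subjects with 3 chemicals over 2 batches and an
LOD at the 30th exposure percentile (realizing ~27% censoring; mean
per-chemical median bias stays under 10%, and is dominated not by the
substitution but by calibration-intercept estimation error, which is
symmetric and averages out across replicates); the null calibration of the
batch gate uses 1000 simulated chemicals at 5 × 6; family-correlation
recovery uses 100 mother/proband families and averages the diagonal
Spearman cells over 4 chemicals (independent draws per chemical), because a
single cell at n = 100 has a standard error near 0.07.

## Known limitations

The pipeline consumes integrated peak tables; peak picking, deconvolution
of coeluting MRM traces, and vendor-format ingestion are out of scope.
Recovery surrogates are not used to correct concentrations. Reference
medians are consumed as given numbers (no survey weighting). The screening
and targeted steps run on the same simulated acquisition rather than two
instrument runs; the gates do not depend on that simplification.
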