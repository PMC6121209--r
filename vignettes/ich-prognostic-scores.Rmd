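---
title: "Prognostic scoring and ROC evaluation for primary intracerebral hemorrhage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic scoring and ROC evaluation for primary intracerebral hemorrhage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichscores)
```

## The problem

Early mortality prediction in primary intracerebral hemorrhage (ICH) is
usually done with component-sum admission scores: a handful of bedside
variables, each binned into a small number of point levels, summed to an
ordinal 0–6 risk grade. This package implements the three scores built
from the Glasgow Coma Scale, CT findings and vital signs (ICH score, New
ICH score, and the Modified New ICH score in which the Modified Rankin
Scale replaces the NIHSS), and evaluates any such ordinal score against
30-day mortality the way such validation studies do: stratified mortality,
an empirical ROC curve, the AUC, and cutoff-level diagnostic metrics.

## Scores as data: point-allocation tables

Each score is a `score_definition`: an ordered set of non-overlapping bins
per component with explicit inclusive/exclusive bounds and integer points.
Integer-valued fields (GCS, MRS, NIHSS, age in years) use inclusive
integer bounds on both sides, so there are no floating-point bin edges on
discrete scales; continuous fields (volume, temperature, pulse pressure)
use half-open bins meeting at the threshold. Construction validates that
bins tile the domain exactly once and that `max_score` equals the sum of
per-component maxima.

```{r}
ich_score_definition()
```

Two choices behind the shipped defaults deserve comment:

* **ICH score thresholds.** The canonical allocation is used: GCS 3–4 → 2,
  5–12 → 1, 13–15 → 0; one point each for volume ≥ 30 cm³, IVH,
  infratentorial origin, and age ≥ 80 years, with "≥" semantics at both
  boundaries (an exactly-80-year-old scores the point).
* **New-type score thresholds.** The temperature and pulse-pressure
  cutpoints of the New / Modified New ICH scores are not consistently
  published. The defaults — temperature ≥ 37.5 °C, pulse pressure
  ≥ 85 mmHg — are explicit package assumptions: the components carry
  `assumed = TRUE`, the flag travels into every JSON report, and both
  thresholds are arguments of `modified_new_ich_score_definition()`. None
  of the package's reference results depend on them, because all
  calibration quantities are computed from the fixture frequency table,
  not from raw covariates.

When both an explicit `volume_cm3` and the ABC/2 diameters are present,
the explicit volume wins and a warning is raised; scoring fails with the
offending row numbers when neither is available or a field leaves its
domain (GCS outside 3–15, MRS outside 0–5 — MRS 6 codes death and is not a
valid admission value; the source study is ambiguous about whether
admission MRS 0 occurred, and this package simply accepts the full 0–5
admission range).

## The evaluation model

For an ordinal score $S$ and outcome $D$ (death by day 30), a cutoff $c$
classifies $S \ge c$ as predicted death — the convention matching how such
scores are reported ("≥ 2", "≥ 3"). From the per-score-value counts of
deceased and survivors the package computes, as exact count ratios:

* sensitivity $\Pr(S \ge c \mid D)$, specificity $\Pr(S < c \mid \bar D)$,
  predictive values at the cohort's prevalence, likelihood ratios
  $LR^+ = Se/(1-Sp)$ (reported as `Inf` when $Sp = 1$, not an error) and
  $LR^- = (1-Se)/Sp$, and Youden's $J = Se + Sp - 1$;
* the empirical ROC: one operating point per distinct score value,
  bracketed by the $(0,0)$ and $(1,1)$ endpoints (the endpoints are always
  included as rows, so a $k$-valued score yields $k+2$ rows);
* the AUC by the tie-corrected pairwise (Mann–Whitney) estimator,
  $\Pr(S_{dead} > S_{alive}) + \tfrac12 \Pr(\text{tie})$. Ties get half
  credit — the standard convention, stated explicitly. Both the pairwise
  count and the trapezoidal area under the ROC are reduced to the same
  integer numerator over $2\,n_{dead}\,n_{alive}$, so the two routes agree
  *exactly*, not merely to tolerance, and the test suite asserts identity
  on a thousand random tables;
* the Youden-optimal cutoff by exhaustive scan over all candidate cutoffs
  (every observed value plus one past the maximum), ties broken toward the
  lower cutoff to favor sensitivity, making the result deterministic.

Rounding happens only at presentation, half away from zero (integer
percents for sensitivity/specificity, 2–3 decimals elsewhere), and reports
carry counts, exact proportions and rounded values side by side so no
downstream check depends on rendering.

```{r}
fx <- table_fixtures()
ev <- evaluate_table(fx$ich_score, "ich_score", cutoffs = 2)
glance(ev)
tidy(ev)[, c("cutoff", "sensitivity", "specificity", "lr_pos", "lr_neg", "youden_j")]
```

### Known discrepancies in the reference table

The packaged fixture is the joint score-outcome frequency table of a
107-patient reference cohort (61 deceased, 46 survivors). Its headline
statistics reproduce exactly from the counts: AUC 0.855 (ICH) and 0.826
(Modified), ICH ≥ 2 sensitivity 53/61 ≈ 87% and specificity 29/46 ≈ 63%,
mortality 18.2% at ICH score 0 and 100% at Modified score 6, deceased-group
mean scores 2.90 and 3.90. Four published cells are *not* reproducible
from the same counts and are documented rather than chased: the ICH-row
PPV 0.70 and NPV 0.83 (counts give 53/70 ≈ 0.76 and 29/37 ≈ 0.78), the
Modified-row specificity 53% (counts give 24/46 ≈ 52.2%) and LR+ 1.87
(apparently computed from pre-rounded percentages). The Modified-row
sensitivity 54/61 = 88.52% appears in print as 88, i.e. truncated rather
than rounded. Finally, the reported cutoffs (≥ 2 and ≥ 3) do not maximize
Youden's J on these counts — J peaks at 3 (0.580) and 4 (0.569)
respectively, and the selection rule actually used is unstated — so every
evaluation reports metrics at both the requested and the J-maximizing
cutoffs.

## The synthetic-cohort generator

`generate_cohort()` emulates the reference cohort in two modes, both
driven by a single integer seed through one RNG stream (the caller's RNG
state is saved and restored):

* **`score_level`** draws each patient's outcome Bernoulli at the
  fixture's mortality (61/107) and then each system's score from the
  score distribution conditional on that outcome. Drawing the two systems
  from their printed joints independently would break the shared outcome
  per patient, so the joint is factorized as outcome margin × conditional;
  each system's (score, outcome) joint is exactly the configured one in
  expectation. This mode reproduces the reference discrimination (a
  50,000-patient draw recovers both AUCs within 0.02) and is the mode all
  calibration checks use.
* **`component_level`** draws raw admission covariates per outcome group —
  truncated normals for continuous fields, integer-rounded for ordinal
  scales, Bernoulli flags — and computes the scores from them with
  `score_cohort()`. Defaults are the reference cohort's per-outcome
  means/SDs (e.g. bleeding volume 31.65 ± 18.93 cm³ among the deceased vs
  18.67 ± 10.99 among survivors) and event rates (IVH 40/61 vs 16/46,
  SAH 13/61 vs 4/46, infratentorial 10/61 vs 6/46). Truncation ranges keep
  draws physiologic: GCS 3–15, MRS 0–5, temperature 30–43 °C, volume
  > 0 cm³, adult ages. The published sex row is internally inconsistent
  with the group totals, so the generator uses P(male) = 0.5 in both
  groups, matching the near-even overall split. Diastolic pressure has no
  published summary; an assumed 85 ± 13 mmHg truncated normal is used
  only to split the published pulse pressure into systolic/diastolic
  pairs.

What `component_level` does *not* model: correlations among covariates
within an outcome group (no correlation structure is published, so
covariates are outcome-conditionally independent), the anatomical-site
distribution, and secular/treatment effects. Its score distribution also
depends on the assumed New-type thresholds above. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and
calibration to the printed joint distribution — not validity of the scores
on new clinical data.

The ordinal scales are a numerical judgment call: the source reports GCS
and MRS only as mean ± SD of integer scales, so the generator rounds
truncated-normal draws to integers. Rounding near a truncation boundary
(e.g. MRS 5 ± 1 truncated to [0, 5]) biases the mean slightly; the
parameter-recovery property test therefore checks continuous covariates
against the closed-form truncated-normal mean at 3 standard errors, and
the integer scales against their domains.

`recover_parameters()` closes the loop, returning empirical per-outcome
means/SDs, flag rates and joint cell frequencies; materializing the
fixture patient-wise and re-tabulating reproduces it exactly.

## Problem sizes and determinism

The test suite runs entirely at desk scale: exact identities on 1,000
random small tables, oracle comparisons on a few hundred, one 50,000-patient
score-level draw, and twenty 10,000-patient component-level draws for
parameter recovery — a couple of minutes end to end. The pipeline
(`run_simulate()` → `run_score()` → `run_evaluate()`) is deterministic
given the seed: repeated runs produce byte-identical CSV and JSON outputs,
and every report embeds the exact score definitions (assumed flags
included) that produced it.

## Limitations

The evaluation is purely empirical: no confidence intervals for AUC or
sensitivity, and no paired comparison of two AUCs — matching the scope of
the reference analysis. Scores are validated against 30-day mortality
only; functional outcomes are out of scope, as are NIHSS item-level
scoring and CT segmentation (diameters and volumes are inputs).
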