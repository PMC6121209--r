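# ichscores

Admission prognostic scores for primary intracerebral hemorrhage (ICH) and
a complete diagnostic-evaluation engine for ordinal scores against 30-day
mortality.

Clinicians triaging ICH in the emergency department use simple
component-sum scores to estimate early mortality risk. This package
implements three of them and everything needed to evaluate such a score on
a cohort:

* **ICH score** (0–6): GCS bin (3–4 → 2, 5–12 → 1, 13–15 → 0), hematoma
  volume ≥ 30 cm³, intraventricular hemorrhage, infratentorial origin, and
  age ≥ 80 years (1 point each).
* **New ICH score** (0–6): NIHSS bin (0–10 → 0, 11–20 → 1, 21–40 → 2),
  elevated body temperature, elevated pulse pressure, IVH, SAH.
* **Modified New ICH score** (0–6): the New ICH score with the NIHSS bin
  replaced by its Modified Rankin Scale equivalent
  (MRS 0–2 → 0, 3–4 → 1, 5 → 2), so it can be scored without a full NIHSS
  examination.
* **ABC/2 hematoma volumetry**: volume ≈ A·B·C/2 (cm³) from two orthogonal
  CT diameters and the slice extent.

The evaluation engine treats an ordinal score S against a binary outcome D
(death by day 30) with the positivity convention S ≥ c ⇒ predicted death.
It computes the empirical ROC, the tie-corrected Mann–Whitney AUC
(P(S_dead > S_alive) + ½·P(tie), identically the trapezoidal area under
the ROC), sensitivity/specificity/PPV/NPV/LR±/Youden J at any cutoff,
the Youden-optimal cutoff (J = Se + Sp − 1, ties to the lower cutoff),
per-score-stratum mortality, and outcome-group mean scores — all as exact
count ratios, rounding only at presentation.

A synthetic-cohort generator calibrated to a published 107-patient
score-outcome distribution (61 deceased / 46 survivors) makes every stage
testable without patient data.

## Worked example

```r
library(ichscores)

cohort <- tibble::tibble(
  age = c(50, 82, 70), sex = c("male", "female", "male"),
  gcs = c(13, 4, 7), mrs = c(2, 5, 5),
  temperature = c(36.8, 38.2, 36.5), sbp = c(130, 180, 150),
  dbp = c(80, 80, 95), location = c("supra", "infra", "supra"),
  ivh = c(FALSE, TRUE, TRUE), sah = c(FALSE, TRUE, FALSE),
  volume_cm3 = c(10, 35, 20), dead_30d = c(FALSE, TRUE, TRUE)
)
score_cohort(cohort)[, c("ich_score", "modified_new_ich_score")]
#> # A tibble: 3 × 2
#>   ich_score modified_new_ich_score
#>       <int>                  <int>
#> 1         0                      0
#> 2         6                      6
#> 3         2                      3
```

Patient 1 is mild on every component (score 0 on both systems); patient 2
is maximal on every component (6/6); patient 3 collects ICH points for
GCS 7 (1) and IVH (1), and Modified points for MRS 5 (2) and IVH (1).

Evaluating the packaged reference frequency table:

```r
fx <- table_fixtures()
ev <- evaluate_table(fx$ich_score, "ich_score", cutoffs = 2)
glance(ev)
#> # A tibble: 1 × 9
#>   system        n n_dead n_alive   auc youden_cutoff youden_j mean_score_dead
#>   <chr>     <int>  <int>   <int> <dbl>         <dbl>    <dbl>           <dbl>
#> 1 ich_score   107     61      46 0.855             3    0.579            2.90
```

An AUC of 0.855 means a randomly chosen deceased patient outscores a
randomly chosen survivor 85.5% of the time (ties counted half). At the
reported cutoff ≥ 2, `tidy(ev)` gives sensitivity 53/61 ≈ 87%, specificity
29/46 ≈ 63%, LR+ 2.35, LR− 0.21, J 0.50. Note the Youden-maximizing cutoff
on these counts is 3 (J ≈ 0.58), not the reported 2; the package always
reports both. `autoplot(ev)` draws the ROC curves.

A full file-to-file pipeline (also scriptable via
`inst/cli/ichscores.R <simulate|score|evaluate|fixtures>`):

```r
run_simulate("cohort.csv", cohort_config(n = 107, seed = 1, mode = "component_level"))
run_score("cohort.csv", "scored.csv")
run_evaluate("scored.csv", "report/")   # report.json, metrics.csv, roc_*.csv
```

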