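# Random small score-outcome tables and brute-force oracles used by the
# property tests. Oracles work patient-by-patient on materialized records,
# independent of the count-based implementation they check.

random_table <- function() {
  k <- sample(2:6, 1)
  scores <- sort(sample(0:9, k))
  repeat {
    dead <- rpois(k, 2)
    alive <- rpois(k, 2)
    if (sum(dead) > 0 && sum(alive) > 0) break
  }
  new_score_outcome_table(scores, dead, alive)
}

# Patient-materializing oracle for metrics_at_cutoff: expand counts to
# individual patients and classify them one at a time.
brute_metrics <- function(table, cutoff) {
  pts <- materialize_table(table)
  pos <- pts$score >= cutoff
  tp <- sum(pos & pts$dead_30d); fp <- sum(pos & !pts$dead_30d)
  fn <- sum(!pos & pts$dead_30d); tn <- sum(!pos & !pts$dead_30d)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec,
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
       lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
       youden_j = sens + spec - 1)
}

# Pairwise AUC oracle: loop over every deceased-survivor pair of
# materialized patients; ties get half credit.
brute_auc <- function(table) {
  pts <- materialize_table(table)
  d <- pts$score[pts$dead_30d]; a <- pts$score[!pts$dead_30d]
  tot <- 0
  for (x in d) tot <- tot + sum(x > a) + 0.5 * sum(x == a)
  tot / (length(d) * length(a))
}

example_cohort <- function() {
  tibble::tibble(
    age = c(50, 82, 70), sex = c("male", "female", "male"),
    gcs = c(13, 4, 7), mrs = c(2, 5, 5),
    temperature = c(36.8, 38.2, 36.5), sbp = c(130, 180, 150),
    dbp = c(80, 80, 95), location = c("supra", "infra", "supra"),
    ivh = c(FALSE, TRUE, TRUE), sah = c(FALSE, TRUE, FALSE),
    volume_cm3 = c(10, 35, 20), dead_30d = c(FALSE, TRUE, TRUE)
  )
}
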