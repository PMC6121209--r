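#' Score-outcome tables
#'
#' The per-score-value tally of deceased and surviving patients that all
#' diagnostic evaluation in this package runs on: one row per ordinal score
#' value with columns `score`, `dead`, `alive`. Build one from per-patient
#' data with `score_outcome_table()` (tidy-eval column selection) or
#' directly from count vectors with `new_score_outcome_table()`.
#'
#' @param data per-patient data frame.
#' @param score unquoted column holding the ordinal score.
#' @param outcome unquoted column holding the 30-day vital status
#'   (logical or 0/1; `TRUE`/1 = dead).
#' @return a tibble with columns `score`, `dead`, `alive`, sorted by score.
#' @export
#' @examples
#' pts <- tibble::tibble(s = c(0, 0, 1, 2, 2), dead = c(0, 0, 0, 1, 1))
#' score_outcome_table(pts, s, dead)
score_outcome_table <- function(data, score, outcome) {
  score <- enquo(score); outcome <- enquo(outcome)
  data |>
    dplyr::mutate(.dead = as_flag(!!outcome, as_name(outcome))) |>
    dplyr::group_by(score = !!score) |>
    dplyr::summarise(dead = sum(.data$.dead), alive = sum(!.data$.dead), .groups = "drop") |>
    dplyr::arrange(.data$score)
}

#' @param score_values,dead_counts,alive_counts parallel vectors: ordered
#'   integer score values and non-negative counts per value.
#' @rdname score_outcome_table
#' @export
new_score_outcome_table <- function(score_values, dead_counts, alive_counts) {
  stopifnot(length(score_values) == length(dead_counts),
            length(score_values) == length(alive_counts))
  tab <- tibble::tibble(score = as.numeric(score_values),
                        dead = as.integer(dead_counts),
                        alive = as.integer(alive_counts))
  if (any(tab$dead < 0) || any(tab$alive < 0)) abort("Counts must be non-negative.")
  if (is.unsorted(tab$score, strictly = TRUE)) abort("Score values must be strictly increasing.")
  tab
}

check_outcome_table <- function(table, require_both = TRUE) {
  stopifnot(all(c("score", "dead", "alive") %in% names(table)))
  if (require_both && (sum(table$dead) == 0 || sum(table$alive) == 0)) {
    abort("Degenerate score-outcome table: need at least one deceased and one surviving patient.")
  }
  invisible(table)
}

#' Diagnostic metrics at a cutoff
#'
#' Classifies `score >= cutoff` as predicted death and tabulates the test
#' against observed 30-day mortality. All quantities are exact count ratios;
#' apply [round_half_away()] only for presentation. When specificity is 1
#' the positive likelihood ratio is `Inf` (no false positives), and
#' predictive values are `NaN` when no patient falls on that side of the
#' cutoff.
#'
#' @param table a [score_outcome_table()].
#' @param cutoff numeric cutoff; a score at or above it is test-positive.
#' @return one-row tibble: `cutoff`, the four cell counts `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`, `ppv`, `npv`, `lr_pos`, `lr_neg`,
#'   `youden_j`.
#' @export
#' @examples
#' tab <- table_fixtures()$ich_score
#' metrics_at_cutoff(tab, 2)
metrics_at_cutoff <- function(table, cutoff) {
  check_outcome_table(table)
  pos <- table$score >= cutoff
  tp <- sum(table$dead[pos]);  fn <- sum(table$dead[!pos])
  fp <- sum(table$alive[pos]); tn <- sum(table$alive[!pos])
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec,
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
    lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
    youden_j = sens + spec - 1
  )
}

#' Empirical ROC curve of an ordinal score
#'
#' One operating point per distinct observed score value (positivity
#' `score >= cutoff`, cutoffs descending) bracketed by the (0, 0) and (1, 1)
#' endpoints. Coordinates are exact count ratios, monotone non-decreasing
#' along the curve.
#'
#' @inheritParams metrics_at_cutoff
#' @return tibble with columns `cutoff` (`Inf`/`-Inf` on the endpoints),
#'   false/true positive counts `fp`, `tp`, and rates `fpr`, `tpr`.
#' @export
roc_points <- function(table) {
  check_outcome_table(table)
  n_dead <- sum(table$dead); n_alive <- sum(table$alive)
  cuts <- sort(unique(table$score), decreasing = TRUE)
  pts <- purrr::map_dfr(cuts, function(ct) {
    pos <- table$score >= ct
    tibble::tibble(cutoff = ct, fp = sum(table$alive[pos]), tp = sum(table$dead[pos]))
  })
  dplyr::bind_rows(
    tibble::tibble(cutoff = Inf, fp = 0L, tp = 0L),
    pts,
    tibble::tibble(cutoff = -Inf, fp = n_alive, tp = n_dead)
  ) |>
    dplyr::mutate(fpr = .data$fp / n_alive, tpr = .data$tp / n_dead)
}

#' Area under the empirical ROC curve
#'
#' The tie-corrected pairwise estimator: the probability over all
#' deceased-survivor pairs that the deceased patient has the higher score,
#' ties counting one half. Identically equal to the trapezoidal area under
#' [roc_points()]; both routes are computed from integer pair counts over a
#' common denominator, so `method` changes the algorithm, never the value.
#'
#' @inheritParams metrics_at_cutoff
#' @param method `"pairs"` (Mann-Whitney pair counting, default) or
#'   `"trapezoid"` (area under the empirical ROC).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(table_fixtures()$ich_score)
auc <- function(table, method = c("pairs", "trapezoid")) {
  check_outcome_table(table)
  method <- match.arg(method)
  n_dead <- sum(table$dead); n_alive <- sum(table$alive)
  num <- if (method == "pairs") {
    cum_alive_below <- cumsum(dplyr::lag(table$alive, default = 0L))
    concordant <- sum(table$dead * cum_alive_below)
    ties <- sum(table$dead * table$alive)
    2 * concordant + ties
  } else {
    r <- roc_points(table)
    # 2 * n_dead * n_alive * trapezoid area, integer by construction
    sum(diff(r$fp) * (head(r$tp, -1) + tail(r$tp, -1)))
  }
  num / (2 * n_dead * n_alive)
}

#' Youden-optimal cutoff
#'
#' Scans every candidate cutoff (each observed score value plus one past the
#' maximum) and returns the one maximizing Youden's J = sensitivity +
#' specificity - 1; ties go to the lower cutoff, favoring sensitivity.
#'
#' @inheritParams metrics_at_cutoff
#' @return one-row tibble `cutoff`, `youden_j`.
#' @export
youden_optimal_cutoff <- function(table) {
  check_outcome_table(table)
  cand <- c(sort(unique(table$score)), max(table$score) + 1)
  js <- vapply(cand, function(ct) metrics_at_cutoff(table, ct)$youden_j, double(1))
  best <- which.max(js)  # first max = lowest cutoff on ties
  tibble::tibble(cutoff = cand[best], youden_j = js[best])
}

#' Per-score-value 30-day mortality
#'
#' @inheritParams metrics_at_cutoff
#' @return tibble `score`, `dead`, `alive`, `n`, `mortality`; empty strata
#'   (zero patients) carry `NA` mortality rather than 0.
#' @export
stratum_mortality <- function(table) {
  check_outcome_table(table, require_both = FALSE)
  table |>
    dplyr::mutate(n = .data$dead + .data$alive,
                  mortality = dplyr::if_else(.data$n > 0, .data$dead / .data$n, NA_real_)) |>
    dplyr::select("score", "dead", "alive", "n", "mortality")
}

#' Mean score in an outcome group
#'
#' Count-weighted mean score among the deceased or the survivors.
#'
#' @inheritParams metrics_at_cutoff
#' @param group `"dead"` or `"alive"`.
#' @return a single number.
#' @export
group_mean_score <- function(table, group = c("dead", "alive")) {
  group <- match.arg(group)
  check_outcome_table(table, require_both = FALSE)
  w <- table[[group]]
  if (sum(w) == 0) abort(sprintf("No patients in the '%s' group.", group))
  sum(table$score * w) / sum(w)
}
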