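#' Evaluate ordinal prognostic scores against 30-day mortality
#'
#' The full diagnostic report for one or more score columns: the
#' score-outcome tally, tie-corrected AUC, empirical ROC, per-stratum
#' mortality, group mean scores, and cutoff metrics both at any requested
#' cutoffs and at the Youden-optimal one. `evaluate_scores()` starts from
#' per-patient data; `evaluate_table()` starts from an already tabulated
#' [score_outcome_table()] (e.g. a published frequency table).
#'
#' The result is an `ich_eval` object with [tidy()] (cutoff metrics, one row
#' per system x cutoff), [glance()] (one row per system: AUC, Youden
#' optimum, group means) and [autoplot()] (ROC curves) methods.
#'
#' @param data per-patient data frame holding the score column(s) and the
#'   outcome column.
#' @param ... unquoted score columns to evaluate (tidyselect).
#' @param outcome unquoted outcome column; `TRUE`/1 = dead by day 30.
#' @param cutoffs named list (by score column) of cutoff vectors to report
#'   in addition to the Youden optimum, or a single vector applied to every
#'   system.
#' @return an `ich_eval` object (named list of per-system evaluations).
#' @export
#' @examples
#' fx <- table_fixtures()
#' ev <- evaluate_table(fx$ich_score, name = "ich_score", cutoffs = 2)
#' glance(ev)
#' tidy(ev)
evaluate_scores <- function(data, ..., outcome, cutoffs = NULL) {
  outcome <- enquo(outcome)
  sel <- tidyselect::eval_select(rlang::expr(c(...)), data)
  if (!length(sel)) abort("Select at least one score column to evaluate.")
  systems <- lapply(names(sel), function(col) {
    tab <- score_outcome_table(data, !!rlang::sym(col), !!outcome)
    evaluate_one(tab, col, cutoffs_for(cutoffs, col))
  })
  new_ich_eval(setNames(systems, names(sel)), n = nrow(data))
}

#' @param table a [score_outcome_table()].
#' @param name label for the scoring system.
#' @rdname evaluate_scores
#' @export
evaluate_table <- function(table, name = "score", cutoffs = NULL) {
  new_ich_eval(setNames(list(evaluate_one(table, name, cutoffs_for(cutoffs, name))), name),
               n = sum(table$dead) + sum(table$alive))
}

cutoffs_for <- function(cutoffs, col) {
  if (is.null(cutoffs)) return(NULL)
  if (is.list(cutoffs)) cutoffs[[col]] else cutoffs
}

evaluate_one <- function(tab, name, cutoffs = NULL) {
  check_outcome_table(tab)
  yo <- youden_optimal_cutoff(tab)
  cuts <- sort(unique(c(cutoffs, yo$cutoff)))
  metrics <- purrr::map_dfr(cuts, ~ metrics_at_cutoff(tab, .x)) |>
    dplyr::mutate(youden_optimal = .data$cutoff == yo$cutoff, .after = "cutoff")
  list(
    name = name,
    table = tab,
    n_dead = sum(tab$dead),
    n_alive = sum(tab$alive),
    auc = auc(tab),
    roc = roc_points(tab),
    youden = yo,
    metrics = metrics,
    strata = stratum_mortality(tab),
    mean_dead = group_mean_score(tab, "dead"),
    mean_alive = group_mean_score(tab, "alive")
  )
}

new_ich_eval <- function(systems, n) {
  structure(list(systems = systems, n = n), class = "ich_eval")
}

#' @export
print.ich_eval <- function(x, ...) {
  cat(sprintf("<ich_eval> %d patients, %d scoring system(s)\n", x$n, length(x$systems)))
  for (s in x$systems) {
    cat(sprintf(
      "  %s: AUC %.3f (%d dead / %d alive); Youden-optimal cutoff >= %g (J = %.3f)\n",
      s$name, s$auc, s$n_dead, s$n_alive, s$youden$cutoff, s$youden$youden_j))
  }
  cat("Cutoff metrics: tidy(); per-system summary: glance(); ROC: autoplot().\n")
  invisible(x)
}

#' @describeIn evaluate_scores cutoff-level metrics, one row per system and
#'   cutoff (exact proportions, unrounded).
#' @param x an `ich_eval` object.
#' @method tidy ich_eval
#' @export
tidy.ich_eval <- function(x, ...) {
  purrr::map_dfr(x$systems, function(s) {
    dplyr::mutate(s$metrics, system = s$name, .before = 1)
  })
}

#' @describeIn evaluate_scores one-row-per-system summary: counts, AUC,
#'   Youden optimum, group mean scores.
#' @method glance ich_eval
#' @export
glance.ich_eval <- function(x, ...) {
  purrr::map_dfr(x$systems, function(s) {
    tibble::tibble(
      system = s$name, n = s$n_dead + s$n_alive,
      n_dead = s$n_dead, n_alive = s$n_alive, auc = s$auc,
      youden_cutoff = s$youden$cutoff, youden_j = s$youden$youden_j,
      mean_score_dead = s$mean_dead, mean_score_alive = s$mean_alive
    )
  })
}

#' @describeIn evaluate_scores empirical ROC curves, one per system, with
#'   the chance diagonal.
#' @param object an `ich_eval` object.
#' @method autoplot ich_eval
#' @export
autoplot.ich_eval <- function(object, ...) {
  d <- purrr::map_dfr(object$systems, function(s) {
    dplyr::mutate(s$roc, system = sprintf("%s (AUC %.3f)", s$name, s$auc))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$system)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  title = "30-day mortality ROC") +
    ggplot2::theme_minimal()
}

#' Plot per-stratum mortality
#'
#' Bar chart of observed 30-day mortality by score value for each system in
#' an `ich_eval`.
#'
#' @param x an `ich_eval` object.
#' @return a ggplot.
#' @export
plot_stratum_mortality <- function(x) {
  stopifnot(inherits(x, "ich_eval"))
  d <- purrr::map_dfr(x$systems, function(s) dplyr::mutate(s$strata, system = s$name))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$score), y = .data$mortality)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::facet_wrap(~system) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "Score", y = "30-day mortality") +
    ggplot2::theme_minimal()
}
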