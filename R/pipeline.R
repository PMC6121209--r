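#' Reproducible pipeline runs: simulate, score, evaluate, fixtures
#'
#' File-to-file wrappers tying the package's stages into one deterministic
#' run; each is also exposed as a subcommand of the `inst/cli/ichscores.R`
#' command-line wrapper. Data products go to files; progress notes go to
#' stderr via [message()]; nothing prompts.
#'
#' * `run_simulate()` draws a synthetic cohort ([generate_cohort()]) and
#'   writes the cohort CSV, logging the seed and a checksum of the
#'   configuration used.
#' * `run_score()` reads a cohort CSV, appends both study scores
#'   ([score_cohort()]) and writes the result; input columns are preserved.
#' * `run_evaluate()` reads a scored cohort and writes the full diagnostic
#'   report: `report.json` (counts, exact proportions, and
#'   presentation-rounded values — rounding half away from zero — plus the
#'   exact score definitions used, including their `assumed` flags),
#'   `metrics.csv`, and one `roc_<system>.csv` (`fpr,tpr,cutoff`) per
#'   system. Byte-identical across repeated runs on the same input.
#' * `run_fixtures()` dumps the packaged score-outcome fixture CSV.
#'
#' @param input input CSV path.
#' @param output,output_dir output CSV path / directory (created if needed).
#' @param config a [cohort_config()].
#' @param definitions named list of [score_definition()]s as in
#'   [score_cohort()]; embedded verbatim in the evaluation report.
#' @param cutoffs named list of extra cutoffs to report per system (the
#'   Youden optimum is always included).
#' @param outcome name of the outcome column in the scored cohort.
#' @return the main data product of the stage, invisibly.
#' @export
run_simulate <- function(output, config = cohort_config()) {
  cohort <- generate_cohort(config)
  cfg_json <- jsonlite::toJSON(config[c("n", "seed", "mode", "prevalence")],
                               auto_unbox = TRUE)
  message(sprintf("simulate: n=%d seed=%d mode=%s config=%s",
                  config$n, config$seed, config$mode, cfg_json))
  write_cohort(cohort, output)
  invisible(cohort)
}

#' @rdname run_simulate
#' @export
run_score <- function(input, output, definitions = default_score_definitions()) {
  cohort <- read_cohort(input)
  required <- c("age", "gcs", "mrs", "temperature", "sbp", "dbp", "location",
                "ivh", "sah")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(sprintf("Cohort is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  scored <- score_cohort(cohort, definitions)
  message(sprintf("score: %d row(s) scored", nrow(scored)))
  write_cohort(scored, output)
  invisible(scored)
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(input, output_dir,
                         cutoffs = list(ich_score = 2, modified_new_ich_score = 3),
                         definitions = default_score_definitions(),
                         outcome = "dead_30d") {
  cohort <- read_cohort(input)
  systems <- intersect(c("ich_score", "modified_new_ich_score", "new_ich_score"),
                       names(cohort))
  if (!length(systems)) abort("No score columns found; run the scoring stage first.")
  if (!outcome %in% names(cohort)) {
    abort(sprintf("Outcome column '%s' not found.", outcome))
  }
  dead <- as_flag(cohort[[outcome]], outcome)
  if (length(unique(dead)) < 2) {
    abort("Degenerate cohort: the outcome has a single class; ROC evaluation needs both deceased and surviving patients.")
  }
  ev <- evaluate_scores(cohort, dplyr::all_of(systems),
                        outcome = !!rlang::sym(outcome), cutoffs = cutoffs)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  jsonlite::write_json(report_as_list(ev, definitions),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(render_metrics(tidy(ev)), file.path(output_dir, "metrics.csv"))
  for (s in ev$systems) {
    readr::write_csv(dplyr::select(s$roc, "fpr", "tpr", "cutoff"),
                     file.path(output_dir, paste0("roc_", s$name, ".csv")))
  }
  message(sprintf("evaluate: %d system(s), report in %s", length(systems), output_dir))
  invisible(ev)
}

#' @rdname run_simulate
#' @export
run_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  out <- file.path(output_dir, "score_outcome_fixture.csv")
  file.copy(fixture_path(), out, overwrite = TRUE)
  message(sprintf("fixtures: wrote %s", out))
  invisible(out)
}

# Metrics with presentation-rounded companions (percent for sens/spec,
# 2 dp elsewhere), rounding half away from zero; exact columns untouched.
render_metrics <- function(metrics) {
  dplyr::mutate(
    metrics,
    sensitivity_pct = round_half_away(100 * .data$sensitivity),
    specificity_pct = round_half_away(100 * .data$specificity),
    ppv_rounded = round_half_away(.data$ppv, 2),
    npv_rounded = round_half_away(.data$npv, 2),
    lr_pos_rounded = round_half_away(.data$lr_pos, 2),
    lr_neg_rounded = round_half_away(.data$lr_neg, 2),
    youden_j_rounded = round_half_away(.data$youden_j, 2)
  )
}

report_as_list <- function(ev, definitions) {
  list(
    n = ev$n,
    rounding = "half away from zero; integer percent for sensitivity/specificity, 2 dp otherwise",
    positivity = "score >= cutoff predicts 30-day death",
    definitions = lapply(definitions, score_definition_to_list),
    systems = lapply(ev$systems, function(s) {
      list(
        name = s$name,
        n_dead = s$n_dead, n_alive = s$n_alive,
        auc = list(value = s$auc, value_rounded = round_half_away(s$auc, 3)),
        youden_optimal = as.list(s$youden),
        table = s$table,
        strata = s$strata,
        metrics = render_metrics(s$metrics),
        mean_score = list(
          dead = s$mean_dead, alive = s$mean_alive,
          dead_rounded = round_half_away(s$mean_dead, 2),
          alive_rounded = round_half_away(s$mean_alive, 2))
      )
    })
  )
}
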