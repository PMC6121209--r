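FIXTURE_MD5 <- "add3c05dea9a329659da53ce56accbd7"

#' Packaged score-outcome fixture tables
#'
#' The joint frequency of score value and 30-day vital status observed in
#' the 107-patient reference cohort (61 deceased, 46 survivors) for both
#' scoring systems, shipped as a checksummed CSV. These tables are the
#' calibration target of the synthetic-cohort generator and the input to
#' every desk-scale evaluation in the package.
#'
#' @return named list of two [score_outcome_table()] tibbles:
#'   `ich_score` and `modified_new_ich_score`.
#' @export
#' @examples
#' sapply(table_fixtures(), function(t) c(dead = sum(t$dead), alive = sum(t$alive)))
table_fixtures <- function() {
  path <- fixture_path()
  if (!identical(unname(tools::md5sum(path)), FIXTURE_MD5)) {
    abort("Packaged fixture CSV failed its checksum; reinstall the package.")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    system = readr::col_character(), score = readr::col_double(),
    dead = readr::col_integer(), alive = readr::col_integer()))
  lapply(split(raw, raw$system), function(d) {
    new_score_outcome_table(d$score, d$dead, d$alive)
  })[c("ich_score", "modified_new_ich_score")]
}

#' @rdname table_fixtures
#' @export
fixture_path <- function() {
  system.file("extdata", "score_outcome_fixture.csv", package = "ichscores",
              mustWork = TRUE)
}

#' Synthetic-cohort configuration
#'
#' Parameters of the admission-cohort generator. Two modes:
#'
#' * `"score_level"` draws each patient's outcome from the fixture's
#'   mortality (61/107), then each system's score from its score
#'   distribution conditional on outcome — it reproduces the reference
#'   joint score-outcome structure exactly in expectation and is the mode
#'   every calibration check uses.
#' * `"component_level"` draws raw admission covariates per outcome group
#'   (truncated normals for continuous fields, integer-rounded for ordinal
#'   scales, Bernoulli flags) and computes the scores from them with
#'   [score_cohort()]; useful for end-to-end pipeline exercises, but its
#'   score distribution depends on the assumed New-ICH cutpoints.
#'
#' Default covariate means/SDs per outcome group and the Bernoulli rates
#' are the reference cohort's descriptive statistics; truncation ranges
#' keep draws physiologic (GCS 3-15, temperature 30-43 deg C, volume > 0).
#'
#' @param n cohort size.
#' @param seed integer RNG seed; one seed governs the whole draw.
#' @param mode `"score_level"` or `"component_level"`.
#' @param prevalence probability of 30-day death.
#' @param joint_probs named list (per system) of tibbles `score`, `dead`,
#'   `alive` holding joint cell probabilities (must sum to 1 per system);
#'   defaults to the normalized fixture counts.
#' @param covariate_params tibble `covariate`, `group`, `mean`, `sd`,
#'   `lower`, `upper`, `integer`; defaults to the reference values.
#' @param flag_probs tibble `flag`, `group`, `prob` for ivh, sah,
#'   infratentorial location and male sex.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n = 107, seed = 1, mode = c("score_level", "component_level"),
                          prevalence = NULL, joint_probs = NULL,
                          covariate_params = NULL, flag_probs = NULL) {
  mode <- match.arg(mode)
  if (is.null(joint_probs)) {
    joint_probs <- lapply(table_fixtures(), function(t) {
      dplyr::mutate(t, dead = .data$dead / sum(t$dead + t$alive),
                    alive = .data$alive / sum(t$dead + t$alive))
    })
  }
  cfg <- structure(list(
    n = n, seed = seed, mode = mode,
    prevalence = prevalence %||% sum(joint_probs[[1]]$dead),
    joint_probs = joint_probs,
    covariate_params = covariate_params %||% default_covariate_params(),
    flag_probs = flag_probs %||% default_flag_probs()
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config a `cohort_config`.
#' @export
validate_cohort_config <- function(config) {
  with(config, {
    if (!(is.numeric(n) && length(n) == 1 && n >= 0 && n == round(n))) {
      abort("n must be a single non-negative integer.")
    }
    if (!(is.numeric(seed) && length(seed) == 1)) abort("seed must be a single number.")
    if (prevalence < 0 || prevalence > 1) abort("prevalence must lie in [0, 1].")
    for (nm in names(joint_probs)) {
      jp <- joint_probs[[nm]]
      if (any(jp$dead < 0) || any(jp$alive < 0)) {
        abort(sprintf("joint_probs[['%s']]: negative probabilities.", nm))
      }
      if (abs(sum(jp$dead) + sum(jp$alive) - 1) > 1e-8) {
        abort(sprintf("joint_probs[['%s']] must sum to 1.", nm))
      }
    }
    if (any(covariate_params$sd < 0)) abort("Covariate SDs must be >= 0.")
    if (any(flag_probs$prob < 0 | flag_probs$prob > 1)) {
      abort("Flag probabilities must lie in [0, 1].")
    }
  })
  invisible(config)
}

# Reference per-outcome covariate distributions (dead / alive): mean, SD,
# physiologic truncation range, and whether draws round to integers.
# dbp has no published summary; its parameters are a package assumption
# used only to split pulse pressure into sbp/dbp.
default_covariate_params <- function() {
  tibble::tribble(
    ~covariate,       ~group,  ~mean,  ~sd,    ~lower, ~upper, ~integer,
    "age",            "dead",  70.75,  16.82,  18,     110,    TRUE,
    "age",            "alive", 61.63,  13.82,  18,     110,    TRUE,
    "temperature",    "dead",  36.97,  0.47,   30,     43,     FALSE,
    "temperature",    "alive", 36.99,  0.36,   30,     43,     FALSE,
    "pulse_pressure", "dead",  76.46,  26.10,  10,     150,    FALSE,
    "pulse_pressure", "alive", 70.02,  19.57,  10,     150,    FALSE,
    "gcs",            "dead",  7,      4,      3,      15,     TRUE,
    "gcs",            "alive", 12,     3,      3,      15,     TRUE,
    "volume_cm3",     "dead",  31.65,  18.93,  0.5,    150,    FALSE,
    "volume_cm3",     "alive", 18.67,  10.99,  0.5,    150,    FALSE,
    "mrs",            "dead",  5,      1,      0,      5,      TRUE,
    "mrs",            "alive", 3,      1,      0,      5,      TRUE,
    "dbp",            "dead",  85,     13,     40,     130,    FALSE,
    "dbp",            "alive", 85,     13,     40,     130,    FALSE
  )
}

default_flag_probs <- function() {
  tibble::tribble(
    ~flag,            ~group,  ~prob,
    "ivh",            "dead",  40 / 61,
    "ivh",            "alive", 16 / 46,
    "sah",            "dead",  13 / 61,
    "sah",            "alive",  4 / 46,
    "infratentorial", "dead",  10 / 61,
    "infratentorial", "alive",  6 / 46,
    "male",           "dead",  0.5,
    "male",           "alive", 0.5
  )
}

#' Generate a synthetic admission cohort
#'
#' Draws `config$n` patients under the configured mode (see
#' [cohort_config()]). Deterministic given `config$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param config a [cohort_config()].
#' @return a tibble: in `score_level` mode columns `id`, `dead_30d` and one
#'   column per scoring system; in `component_level` mode the full cohort
#'   layout of [read_cohort()] plus the computed score columns.
#' @export
#' @examples
#' generate_cohort(cohort_config(n = 5, seed = 42))
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    if (config$mode == "score_level") generate_score_level(config)
    else generate_component_level(config)
  })
}

generate_score_level <- function(config) {
  n <- config$n
  dead <- runif(n) < config$prevalence
  out <- tibble::tibble(id = seq_len(n), dead_30d = dead)
  for (nm in names(config$joint_probs)) {
    jp <- config$joint_probs[[nm]]
    s <- numeric(n)
    for (grp in c(TRUE, FALSE)) {
      idx <- which(dead == grp)
      p <- if (grp) jp$dead else jp$alive
      if (length(idx)) {
        if (sum(p) == 0) abort(sprintf(
          "joint_probs[['%s']] has zero mass for the %s group.",
          nm, if (grp) "deceased" else "surviving"))
        s[idx] <- jp$score[sample.int(nrow(jp), length(idx), replace = TRUE,
                                      prob = p / sum(p))]
      }
    }
    out[[nm]] <- as.integer(s)
  }
  out
}

generate_component_level <- function(config) {
  n <- config$n
  dead <- runif(n) < config$prevalence
  grp <- ifelse(dead, "dead", "alive")
  cp <- config$covariate_params
  draw_cov <- function(covariate) {
    x <- numeric(n)
    for (g in c("dead", "alive")) {
      row <- cp[cp$covariate == covariate & cp$group == g, ]
      idx <- which(grp == g)
      if (length(idx)) {
        v <- rtruncnorm(length(idx), row$mean, row$sd, row$lower, row$upper)
        if (row$integer) v <- round(v)
        x[idx] <- v
      }
    }
    x
  }
  fp <- config$flag_probs
  draw_flag <- function(flag) {
    p <- setNames(fp$prob[fp$flag == flag], fp$group[fp$flag == flag])
    runif(n) < p[grp]
  }
  pp <- draw_cov("pulse_pressure")
  dbp <- draw_cov("dbp")
  cohort <- tibble::tibble(
    id = seq_len(n),
    age = draw_cov("age"),
    sex = ifelse(draw_flag("male"), "male", "female"),
    gcs = draw_cov("gcs"),
    mrs = draw_cov("mrs"),
    temperature = draw_cov("temperature"),
    sbp = dbp + pp,
    dbp = dbp,
    location = ifelse(draw_flag("infratentorial"), "infra", "supra"),
    ivh = draw_flag("ivh"),
    sah = draw_flag("sah"),
    volume_cm3 = draw_cov("volume_cm3"),
    dead_30d = dead
  )
  score_cohort(cohort)
}

#' Materialize a score-outcome table as per-patient rows
#'
#' Expands per-score counts into one row per patient; the exact inverse of
#' [score_outcome_table()] on the result (`score`, `dead_30d`).
#'
#' @param table a [score_outcome_table()].
#' @return tibble with columns `score`, `dead_30d`.
#' @export
materialize_table <- function(table) {
  check_outcome_table(table, require_both = FALSE)
  tibble::tibble(
    score = rep(table$score, times = table$dead + table$alive),
    dead_30d = rep(rep(c(TRUE, FALSE), nrow(table)),
                   times = as.vector(rbind(table$dead, table$alive)))
  )
}

#' Recover generator parameters from a cohort
#'
#' Closes the simulate-estimate loop: empirical per-outcome covariate means
#' and SDs, flag rates, and per-system joint (score, outcome) cell
#' frequencies for whichever columns the cohort carries.
#'
#' @param cohort a cohort tibble with a logical/0-1 `dead_30d` column.
#' @return list with `n`, `prevalence`, and (as available)
#'   `covariate_params`, `flag_probs`, `joint_freqs`.
#' @export
recover_parameters <- function(cohort) {
  dead <- as_flag(cohort$dead_30d, "dead_30d")
  if (sum(dead) < 2 || sum(!dead) < 2) {
    abort("Need at least two patients per outcome group to estimate parameters.")
  }
  grp <- ifelse(dead, "dead", "alive")
  out <- list(n = nrow(cohort), prevalence = mean(dead))

  covs <- c("age", "temperature", "gcs", "volume_cm3", "mrs", "dbp")
  covs <- covs[covs %in% names(cohort)]
  pp_avail <- all(c("sbp", "dbp") %in% names(cohort))
  cov_tbl <- purrr::map_dfr(c(covs, if (pp_avail) "pulse_pressure"), function(cv) {
    x <- if (cv == "pulse_pressure") cohort$sbp - cohort$dbp else cohort[[cv]]
    purrr::map_dfr(c("dead", "alive"), function(g) {
      tibble::tibble(covariate = cv, group = g,
                     mean = mean(x[grp == g]), sd = stats::sd(x[grp == g]))
    })
  })
  if (nrow(cov_tbl)) out$covariate_params <- cov_tbl

  flags <- list(ivh = "ivh", sah = "sah")
  flag_tbl <- purrr::map_dfr(names(flags), function(f) {
    if (!f %in% names(cohort)) return(tibble::tibble())
    x <- as_flag(cohort[[f]], f)
    purrr::map_dfr(c("dead", "alive"), function(g) {
      tibble::tibble(flag = f, group = g, prob = mean(x[grp == g]))
    })
  })
  if ("location" %in% names(cohort)) {
    x <- as_infratentorial(cohort$location)
    flag_tbl <- dplyr::bind_rows(flag_tbl, purrr::map_dfr(c("dead", "alive"), function(g) {
      tibble::tibble(flag = "infratentorial", group = g, prob = mean(x[grp == g]))
    }))
  }
  if (nrow(flag_tbl)) out$flag_probs <- flag_tbl

  systems <- intersect(c("ich_score", "modified_new_ich_score", "new_ich_score"),
                       names(cohort))
  if (length(systems)) {
    out$joint_freqs <- setNames(lapply(systems, function(sy) {
      tab <- score_outcome_table(cohort, !!rlang::sym(sy), !!rlang::sym("dead_30d"))
      dplyr::mutate(tab, dead = .data$dead / nrow(cohort),
                    alive = .data$alive / nrow(cohort))
    }), systems)
  }
  out
}
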