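#' ABC/2 hematoma volume
#'
#' Bedside estimate of hemorrhage volume from CT: `A` is the largest
#' diameter of the bleeding region on the reference slice, `B` the diameter
#' perpendicular to `A` on the same slice, and `C` the number of slices
#' showing blood multiplied by the slice spacing; all in centimeters. The
#' volume is the half ellipsoid `A * B * C / 2` in cm^3.
#'
#' @param diam_a,diam_b,slice_extent_c non-negative diameters/extent in cm;
#'   vectorized and recycled like arithmetic.
#' @return volume(s) in cm^3; zero when any factor is zero.
#' @export
#' @examples
#' abc2_volume(4, 3, 2)       # 12
#' abc2_volume(6.2, 4.0, 3.0) # 37.2
abc2_volume <- function(diam_a, diam_b, slice_extent_c) {
  if (any(c(diam_a, diam_b, slice_extent_c) < 0, na.rm = TRUE)) {
    abort("ABC/2 diameters must be non-negative.")
  }
  diam_a * diam_b * slice_extent_c / 2
}

#' Pulse pressure
#'
#' Systolic minus diastolic blood pressure, mmHg.
#'
#' @param sbp,dbp systolic and diastolic pressures (mmHg); `sbp >= dbp`.
#' @return pulse pressure(s) in mmHg.
#' @export
pulse_pressure <- function(sbp, dbp) {
  if (any(sbp < dbp, na.rm = TRUE)) {
    abort("Systolic pressure must be >= diastolic pressure.")
  }
  sbp - dbp
}

#' Severity bins for MRS and NIHSS
#'
#' The New ICH score bins the NIHSS as 0-10 -> 0, 11-20 -> 1, 21-40 -> 2
#' points. The Modified New ICH score replaces the NIHSS with the admission
#' Modified Rankin Scale using the equivalence MRS 0-2 -> 0, 3-4 -> 1,
#' 5 -> 2. MRS 6 denotes death and is not a valid admission value.
#'
#' @param mrs integer Modified Rankin Scale values, 0-5.
#' @return integer points in 0-2.
#' @export
#' @examples
#' mrs_bin_points(0:5)
#' nihss_bin_points(c(10, 11, 40))
mrs_bin_points <- function(mrs) {
  check_integerish(mrs, "mrs", 0, 5)
  bin_points(mrs, modified_new_ich_score_definition()$components[[1]]$bins)
}

#' @param nihss integer NIHSS values, 0-40.
#' @rdname mrs_bin_points
#' @export
nihss_bin_points <- function(nihss) {
  check_integerish(nihss, "nihss", 0, 40)
  bin_points(nihss, new_ich_score_definition()$components[[1]]$bins)
}

check_integerish <- function(x, field, lo, hi) {
  bad <- which(!is.na(x) & (x < lo | x > hi | x != round(x)))
  if (length(bad)) {
    abort(sprintf("Field '%s' must be an integer in %d-%d; offending value(s): %s.",
                  field, lo, hi, paste(unique(x[bad]), collapse = ", ")))
  }
  invisible(x)
}

# Hematoma volume for scoring: a supplied volume_cm3 wins over diameters
# (with a warning when both are present); otherwise ABC/2 from the three
# diameter fields. Rows with neither are left NA for the caller to report.
resolve_volume <- function(data) {
  n <- nrow(data)
  vol <- if ("volume_cm3" %in% names(data)) as.numeric(data$volume_cm3) else rep(NA_real_, n)
  have_diams <- all(c("diam_a", "diam_b", "slice_extent_c") %in% names(data))
  if (have_diams) {
    derivable <- !is.na(data$diam_a) & !is.na(data$diam_b) & !is.na(data$slice_extent_c)
    both <- which(!is.na(vol) & derivable)
    if (length(both)) {
      warn(sprintf(
        "Both volume_cm3 and diameters given for %d row(s); using volume_cm3.",
        length(both)))
    }
    use <- which(is.na(vol) & derivable)
    if (length(use)) {
      vol[use] <- abc2_volume(data$diam_a[use], data$diam_b[use], data$slice_extent_c[use])
    }
  }
  vol
}

# Pull the numeric vector a score component reads from a cohort tibble,
# deriving volume and pulse pressure where needed; errors name the missing
# field.
component_values <- function(data, field, score_name) {
  n <- nrow(data)
  get <- function(col) {
    if (!col %in% names(data)) {
      abort(sprintf("Cannot compute %s: required field '%s' is missing.", score_name, col))
    }
    data[[col]]
  }
  switch(field,
    volume_cm3 = {
      vol <- resolve_volume(data)
      if (anyNA(vol)) {
        abort(sprintf(
          "Cannot compute %s: row(s) %s have neither volume_cm3 nor complete diameters.",
          score_name, paste(which(is.na(vol)), collapse = ", ")))
      }
      vol
    },
    pulse_pressure = {
      if ("pulse_pressure" %in% names(data)) as.numeric(data$pulse_pressure)
      else pulse_pressure(get("sbp"), get("dbp"))
    },
    ivh = as.numeric(as_flag(get("ivh"), "ivh")),
    sah = as.numeric(as_flag(get("sah"), "sah")),
    infratentorial = as.numeric(as_infratentorial(get("location"))),
    as.numeric(get(field))
  )
}

# Shared engine: sum per-component bin points under a definition, reporting
# uncovered values (domain errors) with their row indices.
apply_score_definition <- function(data, defn, score_name = defn$name) {
  n <- nrow(data)
  total <- rep(0L, n)
  for (co in defn$components) {
    x <- component_values(data, co$field, score_name)
    pts <- bin_points(x, co$bins)
    bad <- which(is.na(pts))
    if (length(bad)) {
      abort(sprintf(
        "Cannot compute %s: field '%s' outside its valid domain at row(s) %s (value(s): %s).",
        score_name, co$field, paste(bad, collapse = ", "),
        paste(format(unique(x[bad])), collapse = ", ")))
    }
    total <- total + pts
  }
  as.integer(total)
}

#' Compute admission prognostic scores for a cohort
#'
#' Data-frame-first scorers: each takes a cohort tibble (one admission per
#' row, the column layout of [read_cohort()]) and returns it with the score
#' column appended. `ich_score()` needs `gcs`, a volume (either `volume_cm3`
#' or the `diam_a`/`diam_b`/`slice_extent_c` triplet, ABC/2-derived),
#' `ivh`, `location`, `age`. `modified_new_ich_score()` needs `mrs`,
#' `temperature`, `sbp`/`dbp` (or `pulse_pressure`), `ivh`, `sah`;
#' `new_ich_score()` swaps `mrs` for `nihss`. `score_cohort()` appends both
#' study scores in one call.
#'
#' Domain violations (GCS outside 3-15, MRS outside 0-5, missing fields)
#' abort with the offending field and row numbers.
#'
#' @param data cohort data frame.
#' @param definition a [score_definition()]; defaults to the shipped tables.
#' @param definitions named list with `ich_score` and
#'   `modified_new_ich_score` definitions.
#' @return the input as a tibble with integer score column(s) appended.
#' @export
#' @examples
#' cohort <- tibble::tibble(
#'   age = 50, gcs = 13, volume_cm3 = 10, ivh = FALSE, location = "supra",
#'   mrs = 2, temperature = 36.8, sbp = 130, dbp = 80, sah = FALSE
#' )
#' score_cohort(cohort)[, c("ich_score", "modified_new_ich_score")]
ich_score <- function(data, definition = ich_score_definition()) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, ich_score = apply_score_definition(data, definition, "ICH score"))
}

#' @rdname ich_score
#' @export
modified_new_ich_score <- function(data, definition = modified_new_ich_score_definition()) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(
    data,
    modified_new_ich_score =
      apply_score_definition(data, definition, "Modified New ICH score"))
}

#' @rdname ich_score
#' @export
new_ich_score <- function(data, definition = new_ich_score_definition()) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, new_ich_score = apply_score_definition(data, definition, "New ICH score"))
}

#' @rdname ich_score
#' @export
score_cohort <- function(data, definitions = default_score_definitions()) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(dplyr::mutate(data, ich_score = integer(), modified_new_ich_score = integer()))
  }
  data |>
    ich_score(definitions$ich_score) |>
    modified_new_ich_score(definitions$modified_new_ich_score)
}
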