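#' Read / write an admission-cohort CSV
#'
#' The cohort interchange format: one header row; columns `age, sex, gcs,
#' mrs, temperature, sbp, dbp, location, ivh, sah, diam_a, diam_b,
#' slice_extent_c, volume_cm3, dead_30d`; booleans encoded 0/1; `location`
#' as `supra`/`infra`; optional fields empty when absent. Reading converts
#' the 0/1 flags to logicals; writing converts them back. Extra columns
#' (ids, precomputed scores) pass through unchanged.
#'
#' @param path CSV path.
#' @return `read_cohort()` a tibble; `write_cohort()` `path`, invisibly.
#' @export
read_cohort <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols()))
  char_cols <- intersect(c("sex", "location"), header)
  spec <- c(setNames(rep(list(readr::col_character()), length(char_cols)), char_cols),
            list(.default = readr::col_double()))
  data <- readr::read_csv(path, col_types = do.call(readr::cols, spec))
  for (f in intersect(c("ivh", "sah", "dead_30d"), names(data))) {
    data[[f]] <- as_flag(data[[f]], f)
  }
  data
}

#' @param data cohort tibble.
#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(dplyr::where(is.logical), as.integer))
  readr::write_csv(out, path)
  invisible(path)
}
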