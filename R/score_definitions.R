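#' Score definitions: configurable point-allocation tables
#'
#' A score definition makes a component-based clinical score data rather than
#' code: each component names a patient field and an ordered set of
#' non-overlapping bins with explicit inclusive/exclusive bounds and integer
#' points. The shipped defaults encode the ICH score (GCS, hematoma volume,
#' IVH, infratentorial origin, age) and the New / Modified New ICH scores
#' (NIHSS or MRS bin, body temperature, pulse pressure, IVH, SAH).
#'
#' Temperature and pulse-pressure cutpoints for the New-type scores are not
#' universally standardized; the shipped defaults (temperature >= 37.5 deg C,
#' pulse pressure >= 85 mmHg) are explicit assumptions, carry
#' `assumed = TRUE`, and are embedded in every report so a run is always
#' interpretable. Override them via [score_definition()] or a JSON file.
#'
#' @param name score name.
#' @param components list of components as built by [score_component()].
#' @return A `score_definition`: list with `name`, `components`, `max_score`.
#' @seealso [read_score_definition()], [write_score_definition()]
#' @export
#' @examples
#' defn <- ich_score_definition()
#' defn$max_score
score_definition <- function(name, components) {
  stopifnot(is.character(name), length(name) == 1, is.list(components))
  defn <- structure(
    list(
      name = name,
      components = components,
      max_score = sum(vapply(components, function(co) max(co$bins$points), double(1)))
    ),
    class = "score_definition"
  )
  validate_score_definition(defn)
  defn
}

#' @param field patient field the component reads.
#' @param bins data frame with columns `lo`, `hi`, `points`, `lo_inclusive`,
#'   `hi_inclusive`; bins must be ordered and tile the field's valid domain.
#' @param assumed flag a component whose cutpoints are package assumptions
#'   rather than published values.
#' @rdname score_definition
#' @export
score_component <- function(field, bins, assumed = FALSE) {
  bins <- tibble::as_tibble(bins)
  stopifnot(all(c("lo", "hi", "points", "lo_inclusive", "hi_inclusive") %in% names(bins)))
  list(field = field, bins = bins, assumed = isTRUE(assumed))
}

# One bin row; integer-valued fields use inclusive integer bounds throughout
# (no floating-point edges on discrete scales).
bin <- function(lo, hi, points, lo_inclusive = TRUE, hi_inclusive = TRUE) {
  tibble::tibble(lo = lo, hi = hi, points = as.integer(points),
                 lo_inclusive = lo_inclusive, hi_inclusive = hi_inclusive)
}

#' @rdname score_definition
#' @param defn a `score_definition`.
#' @export
validate_score_definition <- function(defn) {
  stopifnot(inherits(defn, "score_definition") || is.list(defn))
  for (co in defn$components) {
    b <- co$bins
    if (any(b$points < 0)) {
      abort(sprintf("Component '%s': negative points are not allowed.", co$field))
    }
    if (nrow(b) > 1) {
      if (is.unsorted(b$lo)) {
        abort(sprintf("Component '%s': bins must be ordered by lower bound.", co$field))
      }
      for (i in seq_len(nrow(b) - 1)) {
        hi <- b$hi[i]; lo_next <- b$lo[i + 1]
        touching <- hi == lo_next && xor(b$hi_inclusive[i], b$lo_inclusive[i + 1])
        # integer scales step by one with both bounds inclusive
        integer_step <- b$hi_inclusive[i] && b$lo_inclusive[i + 1] &&
          is.finite(hi) && (lo_next - hi == 1)
        if (!touching && !integer_step) {
          abort(sprintf(
            "Component '%s': bins %d and %d leave a gap or overlap between %s and %s.",
            co$field, i, i + 1, format(hi), format(lo_next)
          ))
        }
      }
    }
  }
  expected_max <- sum(vapply(defn$components, function(co) max(co$bins$points), double(1)))
  if (!identical(as.numeric(defn$max_score), as.numeric(expected_max))) {
    abort("max_score must equal the sum of per-component maxima.")
  }
  invisible(defn)
}

# Points for values x under one component's bin table; NA where no bin covers
# x (callers turn that into a descriptive error).
bin_points <- function(x, bins) {
  pts <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(bins))) {
    lo_ok <- if (bins$lo_inclusive[i]) x >= bins$lo[i] else x > bins$lo[i]
    hi_ok <- if (bins$hi_inclusive[i]) x <= bins$hi[i] else x < bins$hi[i]
    sel <- which(is.na(pts) & !is.na(x) & lo_ok & hi_ok)
    pts[sel] <- bins$points[i]
  }
  pts
}

#' Default ICH score definition
#'
#' Point allocation of the original admission ICH score: GCS 3-4 scores 2,
#' 5-12 scores 1, 13-15 scores 0; hematoma volume >= 30 cm^3, presence of
#' intraventricular hemorrhage, infratentorial origin, and age >= 80 years
#' score 1 each (maximum 6). Boundary ages score the point: an 80-year-old
#' scores 1.
#'
#' @return a [score_definition()].
#' @export
ich_score_definition <- function() {
  score_definition(
    "ICH score",
    list(
      score_component("gcs", dplyr::bind_rows(
        bin(3, 4, 2), bin(5, 12, 1), bin(13, 15, 0))),
      score_component("volume_cm3", dplyr::bind_rows(
        bin(0, 30, 0, hi_inclusive = FALSE), bin(30, Inf, 1))),
      score_component("ivh", dplyr::bind_rows(bin(0, 0, 0), bin(1, 1, 1))),
      score_component("infratentorial", dplyr::bind_rows(bin(0, 0, 0), bin(1, 1, 1))),
      score_component("age", dplyr::bind_rows(
        bin(0, 80, 0, hi_inclusive = FALSE), bin(80, Inf, 1)))
    )
  )
}

#' Default New / Modified New ICH score definitions
#'
#' Both scores share four components — body temperature, pulse pressure,
#' IVH and SAH, one point each — plus a 0-2 neurological-severity bin:
#' the NIHSS bin (0-10 -> 0, 11-20 -> 1, 21-40 -> 2) for the New ICH score,
#' or its MRS replacement (0-2 -> 0, 3-4 -> 1, 5 -> 2) for the Modified
#' New ICH score. Temperature / pulse-pressure cutpoints are shipped
#' assumptions (see [score_definition()]), overridable here.
#'
#' @param temperature_threshold deg C; temperature at or above it scores 1.
#' @param pulse_pressure_threshold mmHg; pulse pressure at or above it scores 1.
#' @return a [score_definition()].
#' @export
modified_new_ich_score_definition <- function(temperature_threshold = 37.5,
                                              pulse_pressure_threshold = 85) {
  score_definition(
    "Modified New ICH score",
    c(list(score_component("mrs", dplyr::bind_rows(
        bin(0, 2, 0), bin(3, 4, 1), bin(5, 5, 2)))),
      new_ich_shared_components(temperature_threshold, pulse_pressure_threshold))
  )
}

#' @rdname modified_new_ich_score_definition
#' @export
new_ich_score_definition <- function(temperature_threshold = 37.5,
                                     pulse_pressure_threshold = 85) {
  score_definition(
    "New ICH score",
    c(list(score_component("nihss", dplyr::bind_rows(
        bin(0, 10, 0), bin(11, 20, 1), bin(21, 40, 2)))),
      new_ich_shared_components(temperature_threshold, pulse_pressure_threshold))
  )
}

new_ich_shared_components <- function(temperature_threshold, pulse_pressure_threshold) {
  list(
    score_component("temperature", dplyr::bind_rows(
      bin(0, temperature_threshold, 0, hi_inclusive = FALSE),
      bin(temperature_threshold, Inf, 1)), assumed = TRUE),
    score_component("pulse_pressure", dplyr::bind_rows(
      bin(0, pulse_pressure_threshold, 0, hi_inclusive = FALSE),
      bin(pulse_pressure_threshold, Inf, 1)), assumed = TRUE),
    score_component("ivh", dplyr::bind_rows(bin(0, 0, 0), bin(1, 1, 1))),
    score_component("sah", dplyr::bind_rows(bin(0, 0, 0), bin(1, 1, 1)))
  )
}

#' Shipped default definitions for both scoring systems
#'
#' @return named list with elements `ich_score` and `modified_new_ich_score`.
#' @export
default_score_definitions <- function() {
  list(ich_score = ich_score_definition(),
       modified_new_ich_score = modified_new_ich_score_definition())
}

#' Read / write a score definition as JSON
#'
#' The JSON layout is `{name, components: [{field, assumed, bins: [{lo, hi,
#' points, lo_inclusive, hi_inclusive}]}]}`; unbounded edges are serialized
#' as the strings `"Inf"` / `"-Inf"`. Round-trips exactly.
#'
#' @param path file path.
#' @return `read_score_definition()` returns a [score_definition()];
#'   `write_score_definition()` returns `path` invisibly.
#' @export
read_score_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(x$components, function(co) {
    bins <- dplyr::bind_rows(lapply(co$bins, function(b) {
      tibble::tibble(lo = as.numeric(b$lo), hi = as.numeric(b$hi),
                     points = as.integer(b$points),
                     lo_inclusive = isTRUE(b$lo_inclusive),
                     hi_inclusive = isTRUE(b$hi_inclusive))
    }))
    score_component(co$field, bins, assumed = isTRUE(co$assumed))
  })
  score_definition(x$name, comps)
}

#' @param defn a [score_definition()].
#' @rdname read_score_definition
#' @export
write_score_definition <- function(defn, path) {
  jsonlite::write_json(score_definition_to_list(defn), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Plain-list form used for JSON serialization and report embedding.
score_definition_to_list <- function(defn) {
  list(
    name = defn$name,
    max_score = defn$max_score,
    components = lapply(defn$components, function(co) {
      list(field = co$field, assumed = co$assumed,
           bins = lapply(seq_len(nrow(co$bins)), function(i) {
             b <- co$bins[i, ]
             list(lo = if (is.finite(b$lo)) b$lo else as.character(b$lo),
                  hi = if (is.finite(b$hi)) b$hi else as.character(b$hi),
                  points = b$points,
                  lo_inclusive = b$lo_inclusive, hi_inclusive = b$hi_inclusive)
           }))
    })
  )
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s (max %d)\n", x$name, as.integer(x$max_score)))
  for (co in x$components) {
    rng <- paste(
      sprintf("%s%s,%s%s -> %d",
              ifelse(co$bins$lo_inclusive, "[", "("), format(co$bins$lo),
              format(co$bins$hi), ifelse(co$bins$hi_inclusive, "]", ")"),
              co$bins$points),
      collapse = "; ")
    cat(sprintf("  %s%s: %s\n", co$field, if (co$assumed) " (assumed)" else "", rng))
  }
  invisible(x)
}
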