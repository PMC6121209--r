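#' Round half away from zero
#'
#' Presentation rounding used throughout report rendering: ties are rounded
#' away from zero (2.345 -> 2.35, -0.005 -> -0.01), unlike base [round()]'s
#' round-half-even. All internal arithmetic stays on exact count ratios;
#' this is applied only when a number is printed.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(c(0.125, 2.345, -0.005), 2)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  out <- sign(x) * floor(abs(x) * m + 0.5) / m
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

# Inverse-CDF sampler for a normal truncated to [lower, upper].
# sd = 0 collapses to the point mass at `mean` (clipped into range).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Closed-form mean of the truncated normal; oracle partner of rtruncnorm().
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (exp(-a^2 / 2) - exp(-b^2 / 2)) / sqrt(2 * pi) / z
}

# Run an expression under a private RNG stream: seeds with `seed`, restores
# the caller's .Random.seed afterwards. No hidden global state escapes.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Normalize the hemorrhage-location column to a logical infratentorial flag.
# Accepts "supra"/"infra" (the cohort CSV encoding), full words, or logicals.
as_infratentorial <- function(location) {
  if (is.logical(location)) return(location)
  loc <- tolower(trimws(as.character(location)))
  out <- rep(NA, length(loc))
  out[loc %in% c("infra", "infratentorial")] <- TRUE
  out[loc %in% c("supra", "supratentorial")] <- FALSE
  bad <- !is.na(loc) & is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "Unrecognized hemorrhage location value(s): %s (expected 'supra' or 'infra').",
      paste(unique(loc[bad]), collapse = ", ")
    ))
  }
  out
}

# Coerce 0/1, "0"/"1", TRUE/FALSE to logical, erroring on anything else.
as_flag <- function(x, field) {
  if (is.logical(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & (is.na(v) | !v %in% c(0, 1))
  if (any(bad)) {
    abort(sprintf("Field '%s' must be boolean (0/1); got: %s.",
                  field, paste(unique(x[bad]), collapse = ", ")))
  }
  v == 1
}
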