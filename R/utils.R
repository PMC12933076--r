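# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that simulation functions are pure
#' functions of their seed and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results independent across stages
# that share one global seed. Stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 1299709) %% 2147483647)
}

# Months as a single integer index: year*12 + (month - 1). Lag arithmetic on
# birth months then reduces to subtraction.
ym_index <- function(year, month) as.integer(year) * 12L + as.integer(month) - 1L
ym_year  <- function(ym) ym %/% 12L
ym_month <- function(ym) ym %% 12L + 1L

#' Number of days in a calendar month (leap-aware)
#' @noRd
days_in_month <- function(year, month) {
  n <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n + ifelse(month == 2L & leap, 1L, 0L)
}

#' Round half away from zero
#'
#' Displayed effect sizes use commercial rounding (half away from zero),
#' not the IEEE banker's rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
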