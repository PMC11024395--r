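#' Round half away from zero
#'
#' Display-style rounding: halves round up in magnitude (`0.175` at 2 digits
#' gives `0.18`), matching how clinical tables print percentages, unlike
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.175, 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a count as a printed percentage
#'
#' Computes `100 * num / den` rounded half-up, the convention used when a
#' table prints "n (%)" cells.
#'
#' @param num Numerator count.
#' @param den Denominator count; must be positive.
#' @param digits Decimal digits for the printed percentage (default 2).
#' @return Numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct(525, 1037) # 50.63
pct <- function(num, den, digits = 2) {
  if (any(den <= 0)) stop("pct(): denominator must be positive")
  round_half_up(100 * num / den, digits)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# Completed years lived at `at`, birthday-inclusive.
age_at <- function(birth_date, at) {
  birth_date <- as_date(birth_date)
  at <- as_date(at)
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  age - as.integer(before_birthday)
}
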