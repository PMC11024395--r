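# Comparison statistics used by the cohort tables: one-tailed Welch t test
# for continuous variables, Pearson chi-squared for categorical variables,
# and the relative risk including the printed-percentage convention.

#' One-tailed Welch t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom; the
#' alternative direction is fixed a priori from clinical context.
#'
#' @param a,b Numeric samples (each `n >= 2` with nonzero variance).
#' @param direction `"a_greater"` (alternative: mean of `a` exceeds mean of
#'   `b`) or `"b_greater"`.
#' @return List with `statistic`, `df`, `p_value`, `direction`.
#' @export
welch_t_one_tailed <- function(a, b, direction = c("a_greater", "b_greater")) {
  direction <- match.arg(direction)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_t_one_tailed(): each group needs at least 2 observations")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("welch_t_one_tailed(): degenerate zero variance")
  sa <- va / length(a)
  sb <- vb / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1L) + sb^2 / (length(b) - 1L))
  p <- if (direction == "a_greater") {
    stats::pt(t_stat, df, lower.tail = FALSE)
  } else {
    stats::pt(t_stat, df, lower.tail = TRUE)
  }
  list(statistic = t_stat, df = df, p_value = p, direction = direction)
}

#' Pearson chi-squared test
#'
#' Classic Pearson statistic on an r x c contingency table, without
#' continuity correction, df = (r-1)(c-1).
#'
#' @param table Matrix of counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("chi_square(): table must be at least 2 x 2")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) {
    bad <- which(expected <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("chi_square(): zero expected count in cell (%d, %d)",
                 bad[1L], bad[2L]))
  }
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Relative risk of an event between two groups
#'
#' `raw` mode divides the two event proportions directly.
#' `printed_percent` mode follows the display convention of clinical
#' reports: each proportion is first expressed as a percentage rounded to 2
#' decimals and the quotient is rounded to 2 decimals, so published counts
#' reproduce the published ratio (e.g. 305/1037 vs 262/16560 gives
#' 29.41 / 1.58 = 18.61).
#'
#' @param a Events in group 1; `n1` its size.
#' @param b Events in group 2; `n2` its size (must have `b > 0`).
#' @param n1,n2 Group sizes.
#' @param rounding `"raw"` or `"printed_percent"`.
#' @return The risk ratio (group 1 relative to group 2).
#' @export
#' @examples
#' relative_risk(305, 1037, 262, 16560, "printed_percent")
relative_risk <- function(a, n1, b, n2,
                          rounding = c("raw", "printed_percent")) {
  rounding <- match.arg(rounding)
  if (n1 <= 0 || n2 <= 0) stop("relative_risk(): group sizes must be positive")
  if (b <= 0) stop("relative_risk(): undefined, no events in the reference group")
  if (rounding == "raw") {
    (a / n1) / (b / n2)
  } else {
    round_half_up(pct(a, n1) / pct(b, n2), 2)
  }
}
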