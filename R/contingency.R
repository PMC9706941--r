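# Baseline-table contingency tests.

#' Chi-square / Fisher test for an r x c contingency table
#'
#' Pearson chi-square test without continuity correction (so the statistic
#' is the textbook sum of (O - E)^2 / E); for 2 x 2 tables with any
#' expected count below 5 it switches to Fisher's exact test.
#'
#' @param table matrix of non-negative integer counts (r x c).
#' @return list with `statistic` (NA for Fisher), `df`, `p_value`,
#'   `method` (`"chi-square"` or `"fisher"`), and `expected` counts.
#' @examples
#' contingency_test(matrix(c(10, 10, 10, 10), 2))$p_value  # 1
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  use_fisher <- all(dim(table) == c(2, 2)) && any(expected < 5)
  if (use_fisher) {
    p <- fisher.test(table)$p.value
    list(statistic = NA_real_, df = NA_integer_, p_value = p,
         method = "fisher", expected = expected)
  } else {
    stat <- sum((table - expected)^2 / expected)
    df <- (nrow(table) - 1L) * (ncol(table) - 1L)
    list(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         method = "chi-square", expected = expected)
  }
}
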