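# Log-rank test (k groups, hypergeometric variance at ties).

#' Log-rank test for k survival groups
#'
#' Standard log-rank statistic with the hypergeometric (permutation)
#' variance at tied event times; the p-value comes from a chi-square
#' distribution with (groups - 1) degrees of freedom.  With zero events in
#' total the statistic is 0 and p = 1.
#'
#' @param times follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group group labels (factor or coercible; >= 2 non-empty groups).
#' @return an object of class `logrank_result`: `chi_square`, `df`,
#'   `p_value`, and `table` with per-group observed and expected event
#'   counts.
#' @examples
#' lr <- logrank_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 0, 1),
#'                    c(1, 1, 1, 2, 2, 2))
#' lr$p_value
#' @export
logrank_test <- function(times, events, group) {
  if (!is.factor(group)) group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(group, nlevels(group)) == 0))
    stop("a group has zero subjects", call. = FALSE)
  if (length(times) != length(events) || length(times) != length(group))
    stop("length mismatch", call. = FALSE)
  k <- nlevels(group)
  dt <- sort(unique(times[events == 1]))
  obs <- tapply(events, group, sum)
  obs[is.na(obs)] <- 0
  if (length(dt) == 0) {
    out <- list(chi_square = 0, df = k - 1L, p_value = 1,
                table = data.frame(group = levels(group),
                                   n = as.integer(table(group)),
                                   observed = as.numeric(obs),
                                   expected = as.numeric(obs)))
    class(out) <- "logrank_result"
    return(out)
  }
  U <- numeric(k)
  V <- matrix(0, k, k)
  E <- numeric(k)
  for (t in dt) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n_gt <- tabulate(group[at_risk], k)
    dead <- times == t & events == 1
    d_t <- sum(dead)
    d_gt <- tabulate(group[dead], k)
    e_gt <- d_t * n_gt / n_t
    U <- U + (d_gt - e_gt)
    E <- E + e_gt
    if (n_t > 1) {
      p <- n_gt / n_t
      V <- V + d_t * (n_t - d_t) / (n_t - 1) * (diag(p, k) - tcrossprod(p))
    }
  }
  # drop one group (singular covariance); generalized solve for safety
  Vr <- V[-k, -k, drop = FALSE]
  Ur <- U[-k]
  chi <- tryCatch(drop(crossprod(Ur, solve(Vr, Ur))), error = function(e) NA_real_)
  if (!is.finite(chi)) chi <- 0
  chi <- max(chi, 0)
  out <- list(chi_square = chi, df = k - 1L,
              p_value = pchisq(chi, k - 1, lower.tail = FALSE),
              table = data.frame(group = levels(group),
                                 n = as.integer(table(group)),
                                 observed = as.numeric(obs),
                                 expected = as.numeric(E)))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> chi-square =", format(x$chi_square, digits = 5),
      "on", x$df, "df, p =", format(x$p_value, digits = 4), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Fast two-group log-rank over a grid of interval thresholds; the kernel
# behind the cut-point scan and its resampling correction.  Group 1 at
# candidate c is {interval <= c}.  Returns, per candidate: the chi-square,
# p-value, group sizes, per-arm death counts.  Candidates whose arms hold
# fewer than `min_events` deaths (or no variance) get p = NA.  Compiled;
# tests pin it to the (independent) logrank_test() implementation.
scan_logrank_kernel <- function(post_time, death, intervals, grid,
                                min_events = 5L) {
  .scan_logrank(as.numeric(post_time), as.integer(death),
                as.numeric(intervals), as.numeric(grid),
                as.integer(min_events))
}
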