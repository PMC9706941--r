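# Minimum-P-value cut-point scan with resampling correction.
#
# The failure cohort is the set of patients with the failure type under
# analysis; each candidate threshold c splits it into early (interval <= c)
# and late (interval > c), and the two arms' post-failure survival is
# compared by log-rank.  The threshold with the smallest P is selected, and
# the minimum P is corrected for the multiplicity of the scan by
# resampling.

#' Candidate cut-off grid for the minimum-P scan
#'
#' Integer-month candidates between the 10th and 90th percentile of the
#' failure-free intervals.  A candidate is admissible only if both arms
#' hold at least `min_fraction` of the failure cohort and (when `deaths`
#' is supplied) at least `min_events` post-failure deaths; these rules
#' keep boundary splits — which otherwise dominate minimum-P selection —
#' out of the scan.
#'
#' @param intervals failure-free intervals (months) of the failure cohort.
#' @param deaths optional post-failure death flags, same length.
#' @param min_fraction minimum fraction of the cohort per arm.
#' @param min_events minimum post-failure deaths per arm.
#' @return integer vector of admissible candidate months.
#' @export
admissible_grid <- function(intervals, deaths = NULL,
                            min_fraction = 0.10, min_events = 5L) {
  n <- length(intervals)
  if (n < 20) stopf("need >= 20 failure patients, got %d", n)
  qs <- quantile(intervals, c(0.10, 0.90), names = FALSE)
  lo <- ceiling(qs[1]); hi <- floor(qs[2])
  if (lo > hi)
    stopf("no integer month between the 10th (%.2f) and 90th (%.2f) percentile of the intervals",
          qs[1], qs[2])
  cand <- seq.int(lo, hi)
  early_n <- vapply(cand, function(c) sum(intervals <= c), numeric(1))
  ok <- early_n >= min_fraction * n & (n - early_n) >= min_fraction * n
  if (!is.null(deaths)) {
    ed <- vapply(cand, function(c) sum(deaths[intervals <= c]), numeric(1))
    td <- sum(deaths)
    ok <- ok & ed >= min_events & (td - ed) >= min_events
  }
  if (!any(ok))
    stopf(paste0("no admissible candidate: grid %d..%d, cohort n=%d, ",
                 "min_fraction=%.2f, min_events=%d"),
          lo, hi, n, min_fraction, min_events)
  cand[ok]
}

#' Scan candidate cut-offs by log-rank on post-failure survival
#'
#' For each candidate month c, splits the failure cohort into
#' early (interval <= c) and late (interval > c) and tests the post-failure
#' survival difference by the two-group log-rank test; the candidate with
#' the smallest P value is selected (ties: the smallest month).  Candidates
#' whose arms have fewer than `min_events` post-failure deaths, or where
#' the log-rank variance vanishes, are recorded with `NA` P values rather
#' than failing the scan.
#'
#' @param cohort data frame with columns `interval` (months to failure),
#'   `post_time` (months from failure to death/last contact) and `death`
#'   (flag), as built by [failure_cohort()].
#' @param grid integer candidate months, e.g. from [admissible_grid()].
#' @param min_events per-arm post-failure death minimum for admissibility.
#' @return an object of class `cutpoint_scan`: `candidate_months`,
#'   `p_values`, `chi_square`, `early_n`, `late_n`, `selected_cutoff`,
#'   `min_p`, and `n` (failure-cohort size).  `corrected_p`,
#'   `n_resamples`, `method` and `seed` are filled in by
#'   [correct_min_p()].
#' @export
scan_cutpoints <- function(cohort, grid, min_events = 5L) {
  stopifnot(all(c("interval", "post_time", "death") %in% names(cohort)))
  if (!length(grid)) stop("empty candidate grid", call. = FALSE)
  grid <- as.integer(grid)
  res <- scan_logrank_kernel(cohort$post_time, cohort$death,
                             cohort$interval, grid, min_events = min_events)
  if (all(is.na(res$p)))
    stop("no admissible candidate produced a valid log-rank test", call. = FALSE)
  sel <- which.min(res$p)                  # NA-ignoring; first = smallest month
  structure(list(candidate_months = grid,
                 p_values = res$p,
                 chi_square = res$chi,
                 early_n = res$early_n,
                 late_n = res$late_n,
                 selected_cutoff = grid[sel],
                 min_p = res$p[sel],
                 n = nrow(cohort),
                 corrected_p = NA_real_,
                 n_resamples = NA_integer_,
                 method = NA_character_,
                 seed = NA_integer_),
            class = "cutpoint_scan")
}

#' Resampling correction of the minimum P value
#'
#' The raw minimum P over a scan of thresholds is anti-conservative
#' (selection over many correlated tests).  This builds the null
#' distribution of the minimum P by resampling and returns the add-one
#' Monte-Carlo estimate
#' `(1 + #(null minima <= observed minimum)) / (n_resamples + 1)`.
#'
#' Under `"permutation"` (default) the failure-free intervals are permuted
#' against the `(post_time, death)` pairs — exact exchangeability under the
#' null of no interval-survival association.  Under `"bootstrap"` the
#' pairs are resampled with replacement and the intervals are resampled
#' independently.
#'
#' For the permutation correction to be exactly valid the candidate grid
#' must be a function of the intervals alone (e.g.
#' `admissible_grid(intervals)` without the death flags): the per-arm
#' death-count admissibility rule is applied *inside* the scan,
#' identically for the observed and every permuted labelling.  Passing a
#' grid prefiltered on the observed death pairing makes the observed
#' minimum range over more admissible candidates than the null minima and
#' biases the corrected P downwards.
#'
#' @inheritParams scan_cutpoints
#' @param n_resamples number of resamples (a value below 100 is allowed
#'   but recorded as a warning on the result).
#' @param method `"permutation"` or `"bootstrap"`.
#' @param seed integer seed for the resampling stream.
#' @param scan optional `cutpoint_scan` already computed on the same
#'   cohort/grid (saves recomputation); one is computed if omitted.
#' @return the `cutpoint_scan` with `corrected_p`, `null_min_p`,
#'   `n_resamples`, `method`, `seed` and any `warnings` filled in.
#' @export
correct_min_p <- function(cohort, grid, n_resamples = 1000L,
                          method = c("permutation", "bootstrap"),
                          seed = 1L, min_events = 5L, scan = NULL) {
  method <- match.arg(method)
  grid <- as.integer(grid)
  if (is.null(scan)) scan <- scan_cutpoints(cohort, grid, min_events)
  warnings <- character(0)
  if (n_resamples < 100)
    warnings <- c(warnings,
                  sprintf("n_resamples=%d is below 100; the corrected P is coarse",
                          n_resamples))
  null_min <- numeric(0)
  if (n_resamples > 0) {
    n <- nrow(cohort)
    null_min <- with_preserved_seed(seed, {
      if (method == "permutation") {
        .scan_perm_min_p(as.numeric(cohort$post_time),
                         as.integer(cohort$death),
                         as.numeric(cohort$interval),
                         as.numeric(grid), as.integer(min_events),
                         as.integer(n_resamples))
      } else {
        vapply(seq_len(n_resamples), function(r) {
          pick <- sample.int(n, replace = TRUE)
          iv <- cohort$interval[sample.int(n, replace = TRUE)]
          ks <- scan_logrank_kernel(cohort$post_time[pick],
                                    cohort$death[pick], iv, grid,
                                    min_events = min_events)
          if (all(is.na(ks$p))) 1 else min(ks$p, na.rm = TRUE)
        }, numeric(1))
      }
    })
  }
  scan$corrected_p <- (1 + sum(null_min <= scan$min_p)) / (n_resamples + 1)
  scan$null_min_p <- null_min
  scan$n_resamples <- as.integer(n_resamples)
  scan$method <- method
  scan$seed <- as.integer(seed)
  if (length(warnings)) scan$warnings <- warnings
  scan
}

#' Label failures as early or late at a cut-off
#'
#' Early means the failure-free interval is at or below the cut-off
#' (matching the "within c months" convention); the boundary case
#' `interval == cutoff` is early.
#'
#' @param cohort failure cohort (needs column `interval`), or a numeric
#'   vector of intervals.
#' @param cutoff months.
#' @return factor with levels `c("early", "late")`, one per failure patient.
#' @export
split_failures <- function(cohort, cutoff) {
  iv <- if (is.data.frame(cohort)) cohort$interval else cohort
  factor(ifelse(iv <= cutoff, "early", "late"), levels = c("early", "late"))
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat("<cutpoint_scan> n =", x$n, "failures,",
      sum(!is.na(x$p_values)), "admissible of", length(x$candidate_months),
      "candidates\n")
  cat("  selected cut-off:", x$selected_cutoff, "months, min p =",
      format(x$min_p, digits = 4), "\n")
  if (!is.na(x$corrected_p))
    cat("  corrected p =", format(x$corrected_p, digits = 4),
        sprintf("(%s, %d resamples)\n", x$method, x$n_resamples))
  invisible(x)
}
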