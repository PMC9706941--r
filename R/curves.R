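# Covariate-adjusted group curves and monthly time-specific probabilities.

#' Covariate-adjusted cumulative failure curves per treatment group
#'
#' G-computation / partial dependence over the empirical covariate
#' distribution: for each level g of the group covariate, every cohort
#' member's group value is set to g while their other covariates are kept,
#' the forest predicts each member's cumulative failure probability, and
#' the curves are averaged.  Differences between the resulting group
#' curves are therefore adjusted for the cohort's covariate mix rather
#' than confounded by it.
#'
#' @param model an `rsf_model` whose covariates include `group_covariate`.
#' @param cohort data frame with the model covariates (typically the
#'   training cohort).
#' @param group_covariate name of the treatment-group column.
#' @param time_grid integer-month grid (must start at 0 for the monthly
#'   decomposition to conserve mass).
#' @param smoothing_window centred moving-average window (months) passed to
#'   [monthly_probability()].
#' @param groups group levels to evaluate; defaults to the training levels.
#'   A level absent from the training data is an error.
#' @return an object of class `hazard_curve_set`: `time_grid`, `groups`,
#'   `cumulative` (groups x times matrix F), `monthly` (groups x months
#'   matrix f), `adjustment_covariates`, `smoothing`.
#' @export
adjusted_group_curves <- function(model, cohort, group_covariate, time_grid,
                                  smoothing_window = 3L, groups = NULL) {
  stopifnot(inherits(model, "rsf_model"))
  if (!group_covariate %in% model$covariates)
    stopf("'%s' is not a model covariate", group_covariate)
  train_lev <- model$levels_map[[group_covariate]]
  if (is.null(groups)) {
    groups <- if (!is.null(train_lev)) train_lev
              else sort(unique(cohort[[group_covariate]]))
  }
  if (!is.null(train_lev)) {
    bad <- setdiff(as.character(groups), train_lev)
    if (length(bad))
      stopf("group level(s) absent from training data: %s",
            paste(bad, collapse = ", "))
  }
  F_mat <- matrix(NA_real_, length(groups), length(time_grid),
                  dimnames = list(as.character(groups), as.character(time_grid)))
  # the covariates are categorical, so the cohort collapses to few distinct
  # profiles: predict once per profile and weight by its frequency
  prof <- cohort[, model$covariates, drop = FALSE]
  for (g in seq_along(groups)) {
    cf <- prof
    if (is.factor(cf[[group_covariate]]))
      cf[[group_covariate]] <- factor(as.character(groups[g]),
                                      levels = levels(cf[[group_covariate]]))
    else cf[[group_covariate]] <- groups[g]
    other <- setdiff(model$covariates, group_covariate)
    okey <- do.call(paste, c(lapply(cf[, other, drop = FALSE], as.character),
                             sep = "\r"))
    first <- !duplicated(okey)
    w <- as.vector(table(factor(okey, levels = okey[first])))
    Fg <- predict_cumulative(model, cf[first, , drop = FALSE], time_grid)
    F_mat[g, ] <- colSums(Fg * w) / sum(w)
  }
  monthly <- t(apply(F_mat, 1, monthly_probability,
                     window = smoothing_window))
  colnames(monthly) <- as.character(time_grid[-1])
  structure(list(time_grid = time_grid, groups = as.character(groups),
                 cumulative = F_mat, monthly = monthly,
                 adjustment_covariates = setdiff(model$covariates,
                                                 group_covariate),
                 smoothing = sprintf("centred moving average, %d-month window, edge-truncated",
                                     as.integer(smoothing_window))),
            class = "hazard_curve_set")
}

#' Monthly time-specific event probabilities from a cumulative curve
#'
#' Takes the discrete derivative `f(m) = F(m) - F(m-1)` of a cumulative
#' failure-probability curve on an integer-month grid, smooths it with a
#' centred moving average (window truncated at the edges), clips at zero,
#' and rescales so the running sum re-matches the cumulative curve at the
#' horizon: `sum(f) = F(horizon) - F(0)` exactly.
#'
#' @param F cumulative probabilities on consecutive integer months
#'   (first element = month 0), non-decreasing.
#' @param window moving-average window in months (odd; 1 = no smoothing).
#' @return numeric vector `f`, one value per month `1..horizon`.
#' @examples
#' F <- 1 - exp(-0.02 * 0:60)
#' f <- monthly_probability(F, window = 1)
#' all.equal(f, diff(F))
#' @export
monthly_probability <- function(F, window = 3L) {
  if (any(diff(F) < -1e-12))
    stop("cumulative curve is not non-decreasing; project it first",
         call. = FALSE)
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0)
    stop("window must be a positive odd integer", call. = FALSE)
  f <- diff(F)
  n <- length(f)
  if (n == 0) return(numeric(0))
  if (window > 1) {
    half <- (window - 1L) %/% 2L
    sm <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      mean(f[lo:hi])
    }, numeric(1))
    f <- sm
  }
  f[f < 0] <- 0
  total <- F[length(F)] - F[1]
  s <- sum(f)
  if (s > 0) f <- f * (total / s)
  names(f) <- NULL
  f
}

#' @export
print.hazard_curve_set <- function(x, ...) {
  cat("<hazard_curve_set>", length(x$groups), "groups on months",
      min(x$time_grid), "-", max(x$time_grid), "\n")
  cat("  adjusted for:", paste(x$adjustment_covariates, collapse = ", "), "\n")
  cat("  smoothing:", x$smoothing, "\n")
  horizon <- as.character(max(x$time_grid))
  cat("  F(horizon):",
      paste(sprintf("%s=%.3f", x$groups, x$cumulative[, horizon]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy data frame of a curve set
#'
#' One row per (group, month) with the cumulative and monthly
#' probabilities; the format written to CSV for replotting.
#'
#' @param x a `hazard_curve_set`.
#' @return data frame with columns `group`, `month`, `cumulative`,
#'   `monthly`.
#' @export
curves_as_data_frame <- function(x) {
  stopifnot(inherits(x, "hazard_curve_set"))
  months <- x$time_grid[-1]
  do.call(rbind, lapply(seq_along(x$groups), function(g) {
    data.frame(group = x$groups[g],
               month = months,
               cumulative = unname(x$cumulative[g, -1]),
               monthly = unname(x$monthly[g, ]),
               stringsAsFactors = FALSE)
  }))
}
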