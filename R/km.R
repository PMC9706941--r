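# Kaplan-Meier and Nelson-Aalen estimators.

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with the usual censoring convention:
#' subjects censored at `t` remain in the risk set for events at `t`
#' (events precede censorings at tied times).
#'
#' @param times non-negative follow-up times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @return an object of class `km_curve`: `time` (ascending distinct event
#'   times), `surv` S(t), `n_risk`, `n_event`, and `n` (subjects).
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 0, 1))
#' survival_at(km, 4)  # 4/9
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (length(times) != length(events)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  n <- length(times)
  dt <- sort(unique(times[events == 1]))
  if (length(dt) == 0) {
    out <- list(time = numeric(0), surv = numeric(0), n_risk = integer(0),
                n_event = integer(0), n = n)
    class(out) <- "km_curve"
    return(out)
  }
  n_risk <- vapply(dt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(dt, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = dt, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = n),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function lookup: S(t) is the value after the last
#' event at or before `t`; S(0) = 1 and the last value carries forward
#' beyond the final event time.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t time (months), vectorised.
#' @return survival probabilities.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  if (length(curve$time) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1]
}

# Nelson-Aalen cumulative hazard (step values at distinct event times).
# Exposed because the degenerate single-tree forest must reproduce it.
#' Nelson-Aalen cumulative hazard estimate
#'
#' @inheritParams km_estimate
#' @return list with `time` (distinct event times) and `chf` (cumulative
#'   hazard, the running sum of d_i / n_i).
#' @export
nelson_aalen <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  dt <- sort(unique(times[events == 1]))
  n_risk <- vapply(dt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(dt, function(t) sum(times == t & events == 1), numeric(1))
  list(time = dt, chf = cumsum(n_event / n_risk))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, "subjects,", sum(x$n_event), "events at",
      length(x$time), "distinct times\n")
  if (length(x$time)) {
    last <- length(x$time)
    cat("  S(", format(x$time[last], digits = 4), ") = ",
        format(x$surv[last], digits = 4), "\n", sep = "")
  }
  invisible(x)
}
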