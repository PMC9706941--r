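# Synthetic cohort generation.

# Per-subject piecewise rate matrix for one latent process.  Break grid is
# the union of the baseline breaks and (when a window-restricted effect
# exists) the true cut-off; returns list(breaks=, rates = n x K matrix).
subject_rates <- function(params, endpoint, Z) {
  bh <- params$baseline_hazards[[endpoint]]
  early_key <- paste0(endpoint, "_early")
  eff <- params$log_hazard_effects[[endpoint]]
  eff_early <- params$log_hazard_effects[[early_key]]
  cutoff <- switch(endpoint,
                   locoregional = params$true_cutoff_lrf_months,
                   distant = params$true_cutoff_df_months,
                   NULL)
  breaks <- bh$breaks
  if (length(eff_early) && !is.null(cutoff))
    breaks <- sort(unique(c(breaks, cutoff)))
  # baseline rate per piece on the refined grid
  starts <- c(0, breaks)
  base <- vapply(starts, function(s) {
    k <- findInterval(s + 1e-9, c(0, bh$breaks))
    bh$rates[k]
  }, numeric(1))
  eta <- if (length(eff)) drop(Z[, names(eff), drop = FALSE] %*% eff) else numeric(nrow(Z))
  mult <- exp(eta)
  rate_mat <- outer(mult, base)
  if (length(eff_early) && !is.null(cutoff)) {
    eta_e <- drop(Z[, names(eff_early), drop = FALSE] %*% eff_early)
    early_piece <- starts < cutoff
    rate_mat[, early_piece] <- rate_mat[, early_piece] * exp(eta_e)
  }
  list(breaks = breaks, rates = rate_mat)
}

#' Generate a synthetic right-censored LANPC cohort
#'
#' Draws covariates independently from the configured marginals, latent
#' locoregional-failure, distant-failure and failure-free death times from
#' piecewise-constant proportional hazards, then a post-failure residual
#' survival time whose hazard is multiplied by
#' `exp(post_failure_early_loghr)` when the first failure precedes its
#' endpoint's true cut-off.  Administrative censoring is uniform on the
#' follow-up window.  Identical parameters (including the stored seed) give
#' identical cohorts; the caller's RNG stream is left untouched.
#'
#' @param params a [cohort_params()] object.
#' @return a `data.frame` of class `lanpc_cohort` with one row per patient:
#'   `patient_id`, the twelve covariate factors, `post_treatment` (an
#'   independent salvage-treatment label, `"None"` for patients without an
#'   observed failure), and the event-time columns `t_locoregional` /
#'   `locoregional_event`, `t_distant` / `distant_event`, `t_os` /
#'   `death_event` (months; censored times carry flag 0).  The generating
#'   parameters are attached as attribute `"params"`.
#' @examples
#' coh <- generate_cohort(default_params(n_patients = 500, seed = 7))
#' mean(coh$locoregional_event)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_patients < 50)
    stop("n_patients < 50: downstream estimators are undefined at trivial sizes",
         call. = FALSE)
  lv <- cohort_levels()
  n <- params$n_patients
  with_preserved_seed(params$seed, {
    cov_cols <- lapply(names(params$covariate_marginals), function(nm) {
      p <- params$covariate_marginals[[nm]][lv[[nm]]]
      factor(sample(lv[[nm]], n, replace = TRUE, prob = p), levels = lv[[nm]])
    })
    names(cov_cols) <- names(params$covariate_marginals)
    cohort <- as.data.frame(cov_cols, stringsAsFactors = FALSE)
    Z <- cohort_indicators(cohort)

    rl <- subject_rates(params, "locoregional", Z)
    rd <- subject_rates(params, "distant", Z)
    r0 <- subject_rates(params, "death", Z)
    T_L <- rpch(rl$rates, rl$breaks)
    T_D <- rpch(rd$rates, rd$breaks)
    T_0 <- rpch(r0$rates, r0$breaks)

    t_f <- pmin(T_L, T_D)
    first_distant <- T_D <= T_L           # tie: treated as distant-first
    early <- ifelse(first_distant,
                    T_D <= params$true_cutoff_df_months,
                    T_L <= params$true_cutoff_lrf_months)
    pf <- params$baseline_hazards$post_failure
    pf_mult <- exp(params$post_failure_early_loghr * as.numeric(early))
    pf_mult[!is.finite(t_f)] <- 1
    R <- rpch(outer(pf_mult, pf$rates), pf$breaks)
    death_time <- ifelse(t_f < T_0, t_f + R, T_0)

    C <- runif(n, params$censoring[1], params$censoring[2])
    followup <- pmin(death_time, C)
    death_event <- as.numeric(death_time <= C)

    lr_event <- as.numeric(T_L <= followup)
    dm_event <- as.numeric(T_D <= followup)
    t_lr <- ifelse(lr_event == 1, T_L, followup)
    t_dm <- ifelse(dm_event == 1, T_D, followup)

    any_fail <- lr_event == 1 | dm_event == 1
    salvage <- factor(rep("None", n), levels = lv$post_treatment)
    if (any(any_fail)) {
      drawn <- sample(names(params$salvage_marginals), sum(any_fail),
                      replace = TRUE, prob = params$salvage_marginals)
      salvage[any_fail] <- drawn
    }
    cohort$post_treatment <- salvage

    out <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      cohort,
      t_locoregional = t_lr,
      locoregional_event = lr_event,
      t_distant = t_dm,
      distant_event = dm_event,
      t_os = followup,
      death_event = death_event,
      stringsAsFactors = FALSE)
    attr(out, "params") <- params
    class(out) <- c("lanpc_cohort", "data.frame")
    out
  })
}

#' Write / read a cohort as CSV
#'
#' The CSV uses the fixed, documented column order of [generate_cohort()].
#' `write_cohort()` also writes a sidecar JSON (`<path>.params.json`) with
#' the generating parameters when present.
#'
#' @param cohort an `lanpc_cohort` data frame.
#' @param path CSV file path.
#' @return `read_cohort()` returns the cohort with factor levels restored.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  params <- attr(cohort, "params")
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lv <- cohort_levels()
  for (nm in intersect(names(lv), names(df)))
    df[[nm]] <- factor(df[[nm]], levels = lv[[nm]])
  class(df) <- c("lanpc_cohort", "data.frame")
  df
}
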