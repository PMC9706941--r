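# End-to-end analysis pipeline.

#' Build an analysis configuration
#'
#' Collects every stage's settings behind one object.  Stage seeds are
#' derived from `master_seed` by fixed offsets so stages can be re-run in
#' isolation and the whole pipeline is reproducible from one integer.
#'
#' @param cohort_csv path to a cohort CSV (see [read_cohort()]); `NULL`
#'   simulates a cohort instead.
#' @param params `cohort_params` for simulation (ignored when
#'   `cohort_csv` is given); defaults to [default_params()].
#' @param master_seed integer master seed.
#' @param cutpoint list: `min_fraction`, `min_events`, `n_resamples`,
#'   `method` for the cut-point stage.
#' @param cox list: `candidates` (covariate names, defaulting to the
#'   baseline variable set), `screen_alpha`, `stay_alpha`, `ties`,
#'   `endpoints` (any of `os`, `ffs`, `lrffs`, `dffs`, `elrffs`, `llrffs`,
#'   `edffs`, `ldffs`).
#' @param rsf list: `n_trees`, `mtry`, `min_terminal_events`,
#'   `covariates` (adjustment set), `group` (treatment-group column),
#'   `endpoints` (subset of `failure`, `lrf`, `df`), `horizon` (months),
#'   `window` (smoothing).
#' @param output_dir directory for CSV/JSON outputs; `NULL` keeps the
#'   report in memory only.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(cohort_csv = NULL,
                            params = NULL,
                            master_seed = 20090401L,
                            cutpoint = list(),
                            cox = list(),
                            rsf = list(),
                            output_dir = NULL) {
  cp <- utils::modifyList(
    list(min_fraction = 0.10, min_events = 5L, n_resamples = 1000L,
         method = "permutation"), cutpoint)
  cx <- utils::modifyList(
    list(candidates = c("sex", "histology", "age_group", "family_history",
                        "t_stage", "n_stage", "overall_stage", "ebv_dna",
                        "ic_cycles", "ccd_group"),
         screen_alpha = 0.10, stay_alpha = 0.05, ties = "efron",
         endpoints = c("os", "ffs", "lrffs", "dffs", "edffs", "ldffs",
                       "elrffs", "llrffs")), cox)
  rf <- utils::modifyList(
    list(n_trees = 1000L, mtry = NULL, min_terminal_events = 15L,
         covariates = c("sex", "age_group", "smoking", "family_history",
                        "t_stage", "n_stage"),
         group = "ccd_group",
         endpoints = c("failure", "lrf", "df"),
         horizon = 120L, window = 3L), rsf)
  structure(list(cohort_csv = cohort_csv, params = params,
                 master_seed = as.integer(master_seed),
                 cutpoint = cp, cox = cx, rsf = rf,
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [analysis_config()]
#' (`cohort_csv`, `master_seed`, `cutpoint`, `cox`, `rsf`, `output_dir`),
#' plus `simulation: {n_patients: ...}` to size a simulated cohort.
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- NULL
  if (!is.null(raw$simulation))
    params <- default_params(n_patients = as.integer(raw$simulation$n_patients %||% 3123L))
  analysis_config(
    cohort_csv = raw$cohort_csv,
    params = params,
    master_seed = as.integer(raw$master_seed %||% 20090401L),
    cutpoint = raw$cutpoint %||% list(),
    cox = raw$cox %||% list(),
    rsf = raw$rsf %||% list(),
    output_dir = raw$output_dir)
}

# Fixed seed offsets per stage, all well below 2^31.
stage_seeds <- function(master_seed) {
  list(simulate = master_seed,
       cutpoint_lrf = master_seed + 101L,
       cutpoint_df = master_seed + 102L,
       rsf_failure = master_seed + 201L,
       rsf_lrf = master_seed + 202L,
       rsf_df = master_seed + 203L)
}

#' Validate a cohort table
#'
#' Structural and semantic checks on a cohort data frame: required
#' columns, numeric event-time columns, 0/1 flags, non-negative times,
#' failure times not exceeding the death/last-contact time, and known
#' factor levels.  Reports findings; never throws and never mutates.
#'
#' @param table a data frame (or `lanpc_cohort`).
#' @return data frame of findings with columns `row` (NA for table-level
#'   findings), `column`, `message`; zero rows when the table is clean.
#' @export
validate_cohort <- function(table) {
  findings <- list()
  note <- function(row, column, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      row = row, column = column, message = message, stringsAsFactors = FALSE)
  lv <- cohort_levels()
  required <- c(names(lv)[names(lv) != "post_treatment"],
                "t_locoregional", "locoregional_event", "t_distant",
                "distant_event", "t_os", "death_event")
  miss <- setdiff(required, names(table))
  for (m in miss) note(NA_integer_, m, "required column missing")
  time_cols <- intersect(c("t_locoregional", "t_distant", "t_os"), names(table))
  flag_cols <- intersect(c("locoregional_event", "distant_event", "death_event"),
                         names(table))
  for (cl in time_cols) {
    x <- suppressWarnings(as.numeric(table[[cl]]))
    bad <- which(is.na(x) & !is.na(table[[cl]]))
    for (r in bad) note(r, cl, "non-numeric time value")
    nas <- which(is.na(table[[cl]]))
    for (r in nas) note(r, cl, "missing time value")
    neg <- which(!is.na(x) & x < 0)
    for (r in neg) note(r, cl, "negative time")
  }
  for (cl in flag_cols) {
    x <- suppressWarnings(as.numeric(table[[cl]]))
    bad <- which(is.na(x) | !(x %in% c(0, 1)))
    for (r in bad) note(r, cl, "event flag not 0/1")
  }
  if (all(c("t_locoregional", "locoregional_event", "t_os") %in% names(table))) {
    tl <- suppressWarnings(as.numeric(table$t_locoregional))
    to <- suppressWarnings(as.numeric(table$t_os))
    ev <- suppressWarnings(as.numeric(table$locoregional_event))
    bad <- which(!is.na(tl) & !is.na(to) & ev == 1 & tl > to + 1e-9)
    for (r in bad) note(r, "t_locoregional", "failure time after death/last contact")
  }
  if (all(c("t_distant", "distant_event", "t_os") %in% names(table))) {
    td <- suppressWarnings(as.numeric(table$t_distant))
    to <- suppressWarnings(as.numeric(table$t_os))
    ev <- suppressWarnings(as.numeric(table$distant_event))
    bad <- which(!is.na(td) & !is.na(to) & ev == 1 & td > to + 1e-9)
    for (r in bad) note(r, "t_distant", "failure time after death/last contact")
  }
  for (nm in intersect(names(lv), names(table))) {
    vals <- as.character(table[[nm]])
    bad <- which(!is.na(vals) & !(vals %in% lv[[nm]]))
    for (r in bad) note(r, nm, sprintf("unknown level '%s'", vals[r]))
  }
  if (!length(findings))
    return(data.frame(row = integer(0), column = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

# (time, event) pairs for the early/late window variants of an endpoint.
# Early: follow-up truncated at the cut-off, event iff failure at or
# before it.  Late: patients still failure-free past the cut-off, clock
# restarted at the cut-off.
window_endpoint <- function(time, event, cutoff, side = c("early", "late")) {
  side <- match.arg(side)
  if (side == "early") {
    list(time = pmin(time, cutoff),
         event = as.numeric(event == 1 & time <= cutoff),
         keep = rep(TRUE, length(time)))
  } else {
    keep <- time > cutoff
    list(time = time - cutoff, event = as.numeric(event == 1), keep = keep)
  }
}

km_summary <- function(times, events, at = c(12, 36, 60)) {
  km <- km_estimate(times, events)
  list(time = km$time, surv = km$surv,
       n = km$n, n_events = sum(km$n_event),
       rates = setNames(as.list(survival_at(km, at)),
                        paste0("month_", at)))
}

#' Run the full failure-timing analysis
#'
#' Executes every stage in order — cohort (simulate or load + validate),
#' endpoint derivation, baseline contingency table, cut-point scan with
#' resampling correction for both failure endpoints, early/late
#' post-failure Kaplan-Meier comparison, group Kaplan-Meier curves,
#' multivariable Cox models with backward elimination, and adjusted
#' random-survival-forest curves — and assembles an `analysis_report`.
#' Identical configurations produce identical reports (the provenance
#' block records the configuration fingerprint and stage seeds, not wall
#' time).  A stage failure aborts with an error naming the stage.
#'
#' @param config an [analysis_config()].
#' @return an `analysis_report` list; written to `config$output_dir` as
#'   JSON + tidy CSVs when that is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- stage_seeds(config$master_seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      coh <- read_cohort(config$cohort_csv)
      v <- validate_cohort(coh)
      if (nrow(v)) {
        miss <- v[is.na(v$row), , drop = FALSE]
        if (nrow(miss))
          stopf("cohort schema mismatch: %s",
                paste(unique(miss$column), collapse = ", "))
        stopf("cohort failed validation with %d finding(s); first: row %s, %s: %s",
              nrow(v), v$row[1], v$column[1], v$message[1])
      }
      coh
    } else {
      p <- config$params %||% default_params()
      p$seed <- seeds$simulate
      generate_cohort(p)
    }
  })
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name)
    message(sprintf("[failtiming] stage %-12s done at %7.1fs", name,
                    proc.time()[["elapsed"]] - t0))

  endpoints <- stage("endpoints", derive_endpoints(cohort))
  log_stage("endpoints")

  baseline <- stage("baseline", {
    covs <- setdiff(names(cohort_levels()), c("ccd_group", "post_treatment"))
    covs <- intersect(covs, names(cohort))
    rows <- lapply(covs, function(cv) {
      tab <- table(cohort[[cv]], cohort$ccd_group)
      tst <- tryCatch(contingency_test(tab), error = function(e) NULL)
      data.frame(covariate = cv,
                 method = if (is.null(tst)) NA_character_ else tst$method,
                 statistic = if (is.null(tst)) NA_real_ else tst$statistic,
                 p_value = if (is.null(tst)) NA_real_ else tst$p_value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  log_stage("baseline")

  cutpoints <- list()
  post_failure_km <- list()
  for (epk in c("lrf", "df")) {
    cutpoints[[epk]] <- stage(paste0("cutpoint_", epk), {
      fc <- failure_cohort(cohort, epk)
      # interval-only grid keeps the permutation correction exact; the
      # per-arm death-count rule is applied inside the scan symmetrically
      grid <- admissible_grid(fc$interval,
                              min_fraction = config$cutpoint$min_fraction,
                              min_events = config$cutpoint$min_events)
      correct_min_p(fc, grid,
                    n_resamples = config$cutpoint$n_resamples,
                    method = config$cutpoint$method,
                    seed = seeds[[paste0("cutpoint_", epk)]],
                    min_events = config$cutpoint$min_events)
    })
    post_failure_km[[epk]] <- stage(paste0("post_failure_km_", epk), {
      fc <- failure_cohort(cohort, epk)
      lab <- split_failures(fc, cutpoints[[epk]]$selected_cutoff)
      lr <- logrank_test(fc$post_time, fc$death, lab)
      list(cutoff = cutpoints[[epk]]$selected_cutoff,
           early = km_summary(fc$post_time[lab == "early"],
                              fc$death[lab == "early"]),
           late = km_summary(fc$post_time[lab == "late"],
                             fc$death[lab == "late"]),
           early_n = sum(lab == "early"), late_n = sum(lab == "late"),
           logrank_p = lr$p_value)
    })
  }
  log_stage("cutpoints")

  group_km <- stage("group_km", {
    out <- list()
    for (epk in c("os", "ffs", "lrffs", "dffs")) {
      tm <- endpoints[[paste0(epk, "_time")]]
      ev <- endpoints[[paste0(epk, "_event")]]
      by_group <- lapply(levels(cohort$ccd_group), function(g) {
        sel <- cohort$ccd_group == g
        km_summary(tm[sel], ev[sel])
      })
      names(by_group) <- levels(cohort$ccd_group)
      lr <- logrank_test(tm, ev, cohort$ccd_group)
      out[[epk]] <- list(groups = by_group, logrank_p = lr$p_value)
    }
    out
  })
  log_stage("group_km")

  cox_tables <- stage("cox", {
    co_l <- cutpoints$lrf$selected_cutoff
    co_d <- cutpoints$df$selected_cutoff
    ep_def <- function(kind) {
      switch(kind,
        os = list(time = endpoints$os_time, event = endpoints$os_event,
                  keep = rep(TRUE, nrow(endpoints))),
        ffs = list(time = endpoints$ffs_time, event = endpoints$ffs_event,
                   keep = rep(TRUE, nrow(endpoints))),
        lrffs = list(time = endpoints$lrffs_time, event = endpoints$lrffs_event,
                     keep = rep(TRUE, nrow(endpoints))),
        dffs = list(time = endpoints$dffs_time, event = endpoints$dffs_event,
                    keep = rep(TRUE, nrow(endpoints))),
        elrffs = window_endpoint(endpoints$lrffs_time, endpoints$lrffs_event,
                                 co_l, "early"),
        llrffs = window_endpoint(endpoints$lrffs_time, endpoints$lrffs_event,
                                 co_l, "late"),
        edffs = window_endpoint(endpoints$dffs_time, endpoints$dffs_event,
                                co_d, "early"),
        ldffs = window_endpoint(endpoints$dffs_time, endpoints$dffs_event,
                                co_d, "late"),
        stopf("unknown cox endpoint '%s'", kind))
    }
    out <- list()
    for (kind in config$cox$endpoints) {
      d <- ep_def(kind)
      fit <- backward_eliminate(d$time[d$keep], d$event[d$keep],
                                cohort[d$keep, , drop = FALSE],
                                config$cox$candidates,
                                screen_alpha = config$cox$screen_alpha,
                                stay_alpha = config$cox$stay_alpha,
                                ties = config$cox$ties)
      out[[kind]] <- fit
    }
    out
  })
  log_stage("cox")

  rsf_time <- function(kind) {
    switch(kind,
      # composite treatment failure: first locoregional/distant failure,
      # death without failure censors
      failure = {
        fail <- endpoints$lrffs_event == 1 | endpoints$dffs_event == 1
        tm <- pmin(ifelse(endpoints$lrffs_event == 1, endpoints$lrffs_time, Inf),
                   ifelse(endpoints$dffs_event == 1, endpoints$dffs_time, Inf))
        tm[!fail] <- endpoints$os_time[!fail]
        list(time = tm, event = as.numeric(fail))
      },
      lrf = list(time = endpoints$lrffs_time, event = endpoints$lrffs_event),
      df = list(time = endpoints$dffs_time, event = endpoints$dffs_event),
      stopf("unknown rsf endpoint '%s'", kind))
  }
  rsf_curves <- list()
  for (kind in config$rsf$endpoints) {
    rsf_curves[[kind]] <- stage(paste0("rsf_", kind), {
      d <- rsf_time(kind)
      covs <- unique(c(config$rsf$covariates, config$rsf$group))
      model <- fit_rsf(d$time, d$event, cohort, covs,
                       n_trees = config$rsf$n_trees,
                       mtry = config$rsf$mtry,
                       min_terminal_events = config$rsf$min_terminal_events,
                       seed = seeds[[paste0("rsf_", if (kind == "failure") "failure" else kind)]])
      adjusted_group_curves(model, cohort, config$rsf$group,
                            time_grid = 0:config$rsf$horizon,
                            smoothing_window = config$rsf$window)
    })
  }
  log_stage("rsf")

  ep <- endpoints
  event_fractions <- c(
    locoregional = mean(cohort$locoregional_event),
    distant = mean(cohort$distant_event),
    death = mean(cohort$death_event))

  config_json <- jsonlite::toJSON(config_serializable(config),
                                  auto_unbox = TRUE, digits = NA,
                                  null = "null")
  report <- structure(list(
    provenance = list(
      package_version = as.character(packageVersion("failtiming")),
      config_hash = fnv1a32(as.character(config_json)),
      master_seed = config$master_seed,
      stage_seeds = seeds,
      n_patients = nrow(cohort)),
    event_fractions = event_fractions,
    baseline = baseline,
    cutpoints = cutpoints,
    post_failure_km = post_failure_km,
    group_km = group_km,
    cox = cox_tables,
    rsf = rsf_curves),
    class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# Strip closures/environments so a config can be serialised reproducibly.
config_serializable <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$params)) cfg$params <- unclass(cfg$params)
  cfg
}

#' Serialise an analysis report to JSON
#'
#' Times are serialised in months with 6 decimal places and probabilities
#' with 10, which keeps reports byte-stable across runs of the same
#' configuration.
#'
#' @param report an `analysis_report`.
#' @return a JSON string.
#' @export
report_to_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "cox_fit"))
      return(list(coefficients = x$coefficients,
                  screen = x$screen,
                  elimination_trace = x$elimination_trace,
                  converged = x$converged, flag = x$flag,
                  ties_method = x$ties_method,
                  n = x$n, n_events = x$n_events))
    if (inherits(x, "cutpoint_scan"))
      return(list(candidate_months = x$candidate_months,
                  p_values = x$p_values,
                  early_n = x$early_n, late_n = x$late_n,
                  selected_cutoff = x$selected_cutoff,
                  min_p = x$min_p, corrected_p = x$corrected_p,
                  n_resamples = x$n_resamples, method = x$method,
                  seed = x$seed, n = x$n,
                  warnings = x$warnings))
    if (inherits(x, "hazard_curve_set"))
      return(list(groups = x$groups,
                  adjustment_covariates = x$adjustment_covariates,
                  smoothing = x$smoothing,
                  curves = curves_as_data_frame(x)))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, simplify))
    x
  }
  round_num <- function(x) {
    if (is.data.frame(x)) { x[] <- lapply(x, round_num); return(x) }
    if (is.list(x)) return(lapply(x, round_num))
    if (is.numeric(x)) {
      # months to 6 dp, probabilities (and everything in [0,1]) to 10 dp
      r <- if (all(abs(x[is.finite(x)]) <= 1)) round(x, 10) else round(x, 6)
      return(r)
    }
    x
  }
  body <- round_num(simplify(unclass(report)))
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE))
}

#' Write report artefacts to a directory
#'
#' Writes `report.json` plus tidy CSVs: one per cut-point scan (candidate,
#' p-value, arm sizes), the Cox coefficient tables, the baseline table and
#' the forest curves.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_to_json(report), file.path(dir, "report.json"))
  write.csv(report$baseline, file.path(dir, "baseline_tests.csv"),
            row.names = FALSE)
  for (epk in names(report$cutpoints)) {
    sc <- report$cutpoints[[epk]]
    write.csv(data.frame(candidate = sc$candidate_months,
                         p_value = sc$p_values,
                         early_n = sc$early_n, late_n = sc$late_n),
              file.path(dir, sprintf("cutpoint_scan_%s.csv", epk)),
              row.names = FALSE)
  }
  for (kind in names(report$cox)) {
    cf <- report$cox[[kind]]$coefficients
    if (is.data.frame(cf) && nrow(cf))
      write.csv(cf, file.path(dir, sprintf("cox_%s.csv", kind)),
                row.names = FALSE)
  }
  for (kind in names(report$rsf))
    write.csv(curves_as_data_frame(report$rsf[[kind]]),
              file.path(dir, sprintf("rsf_curves_%s.csv", kind)),
              row.names = FALSE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> n =", x$provenance$n_patients,
      "| config", x$provenance$config_hash,
      "| master seed", x$provenance$master_seed, "\n")
  cat("  event fractions:",
      sprintf("locoregional %.1f%%, distant %.1f%%, death %.1f%%",
              100 * x$event_fractions["locoregional"],
              100 * x$event_fractions["distant"],
              100 * x$event_fractions["death"]), "\n")
  for (epk in names(x$cutpoints)) {
    sc <- x$cutpoints[[epk]]
    cat(sprintf("  %s cut-off: %d months (min p %.3g, corrected %.3g)\n",
                epk, sc$selected_cutoff, sc$min_p, sc$corrected_p))
  }
  invisible(x)
}
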