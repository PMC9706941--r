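# Endpoint derivation from patient records.

#' Derive the study endpoints from patient records
#'
#' Builds the five endpoints used throughout the pipeline, all clocked from
#' treatment initiation: overall survival (OS), failure-free survival (FFS,
#' first failure of any type or death), locoregional failure-free survival
#' (LRFFS) and distant failure-free survival (DFFS), plus post-failure OS
#' (survival from the failure event to death/censoring, defined only for
#' patients with the corresponding failure; the clock starts at the failure
#' type under analysis).  Deaths without the relevant failure censor LRFFS
#' and DFFS at death — there is no competing-risk estimator here, a known
#' source of bias that matches the conventional KM/Cox usage in this
#' setting.
#'
#' @param records an `lanpc_cohort` data frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @return a data frame, one row per patient, with columns
#'   `patient_id`, `os_time`, `os_event`, `ffs_time`, `ffs_event`,
#'   `lrffs_time`, `lrffs_event`, `dffs_time`, `dffs_event`,
#'   `pf_lr_time`, `pf_lr_event`, `pf_dm_time`, `pf_dm_event`
#'   (the `pf_*` columns are `NA` for patients without that failure).
#' @examples
#' coh <- generate_cohort(default_params(n_patients = 200, seed = 1))
#' ep <- derive_endpoints(coh)
#' stopifnot(all(ep$ffs_time <= ep$os_time))
#' @export
derive_endpoints <- function(records) {
  need <- c("t_locoregional", "locoregional_event", "t_distant",
            "distant_event", "t_os", "death_event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("records are missing columns: %s", paste(miss, collapse = ", "))
  tl <- records$t_locoregional; el <- records$locoregional_event
  td <- records$t_distant; ed <- records$distant_event
  to <- records$t_os; dth <- records$death_event
  ids <- records$patient_id %||% as.character(seq_len(nrow(records)))

  bad <- !is.finite(tl) | !is.finite(td) | !is.finite(to) |
    tl < 0 | td < 0 | to < 0 |
    (el == 1 & tl > to + 1e-9) | (ed == 1 & td > to + 1e-9)
  if (any(bad))
    stopf("invalid records (negative/missing times or failure after death/last contact): %s",
          paste(head(ids[bad], 10), collapse = ", "))

  lr <- el == 1
  dm <- ed == 1
  ffs_time <- pmin(ifelse(lr, tl, Inf), ifelse(dm, td, Inf), to)
  ffs_time[!is.finite(ffs_time)] <- to[!is.finite(ffs_time)]
  ffs_event <- as.numeric(lr | dm | dth == 1)

  data.frame(
    patient_id = ids,
    os_time = to, os_event = dth,
    ffs_time = ffs_time, ffs_event = ffs_event,
    lrffs_time = ifelse(lr, tl, to), lrffs_event = el,
    dffs_time = ifelse(dm, td, to), dffs_event = ed,
    pf_lr_time = ifelse(lr, to - tl, NA_real_),
    pf_lr_event = ifelse(lr, dth, NA_real_),
    pf_dm_time = ifelse(dm, to - td, NA_real_),
    pf_dm_event = ifelse(dm, dth, NA_real_),
    stringsAsFactors = FALSE)
}

# Failure cohort for the cut-point scan: one row per patient with the given
# failure type, holding the failure-free interval and post-failure survival.
#' Extract the failure cohort for one endpoint
#'
#' @param records an `lanpc_cohort` data frame.
#' @param endpoint `"lrf"` (locoregional) or `"df"` (distant).
#' @return data frame with `patient_id`, `interval` (months from treatment
#'   initiation to the failure), `post_time` (months from failure to
#'   death/last contact) and `death` flag.
#' @export
failure_cohort <- function(records, endpoint = c("lrf", "df")) {
  endpoint <- match.arg(endpoint)
  ep <- derive_endpoints(records)
  if (endpoint == "lrf") {
    sel <- which(ep$lrffs_event == 1)
    data.frame(patient_id = ep$patient_id[sel],
               interval = ep$lrffs_time[sel],
               post_time = ep$pf_lr_time[sel],
               death = ep$pf_lr_event[sel],
               stringsAsFactors = FALSE)
  } else {
    sel <- which(ep$dffs_event == 1)
    data.frame(patient_id = ep$patient_id[sel],
               interval = ep$dffs_time[sel],
               post_time = ep$pf_dm_time[sel],
               death = ep$pf_dm_event[sel],
               stringsAsFactors = FALSE)
  }
}
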