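# Random survival forest interface.

# Encode the covariate columns as a numeric matrix.  Factors become their
# level codes (0-based), which treats them as ordinal — appropriate here
# because every cohort covariate is binary or an ordered dose group.
rsf_encode <- function(data, covariates, levels_map = NULL) {
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stopf("covariates not in data: %s", paste(miss, collapse = ", "))
  cols <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.factor(x) || is.character(x)) {
      lev <- if (!is.null(levels_map)) levels_map[[nm]] else levels(factor(x))
      bad <- !is.na(x) & !(as.character(x) %in% lev)
      if (any(bad))
        stopf("covariate '%s' has level(s) unseen in training: %s",
              nm, paste(unique(as.character(x)[bad]), collapse = ", "))
      as.numeric(factor(as.character(x), levels = lev)) - 1
    } else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  if (anyNA(X)) stop("missing values in covariates", call. = FALSE)
  X
}

rsf_levels_map <- function(data, covariates) {
  out <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.factor(x)) levels(x)
    else if (is.character(x)) levels(factor(x))
    else NULL
  })
  names(out) <- covariates
  out[!vapply(out, is.null, logical(1))]
}

#' Fit a random survival forest
#'
#' Grows `n_trees` survival trees, each on a bootstrap resample of the
#' cohort (same size, with replacement).  Splits maximise the two-group
#' log-rank statistic over `mtry` randomly chosen covariates with candidate
#' thresholds at the observed covariate values; ties are broken by the
#' first-encountered best split under the seeded covariate order, so a
#' fixed seed gives an identical forest.  A split is admissible only if
#' both children would hold at least `min_terminal_events` events; terminal
#' nodes store the Nelson-Aalen cumulative-hazard estimate of their in-bag
#' members.  Constant covariates are never selected (their splits carry no
#' log-rank variance).
#'
#' @param time,event follow-up times (months) and event flags.
#' @param data data frame holding the covariates.
#' @param covariates character vector of covariate column names.
#' @param n_trees number of bootstrap survival trees (default 1000).
#' @param mtry covariates tried per split; default `ceiling(sqrt(p))`.
#' @param min_terminal_events minimum events per terminal node (default 15).
#' @param bootstrap set `FALSE` to grow every tree on the full sample
#'   (useful for the degenerate single-tree check against the cohort
#'   Nelson-Aalen estimator).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return an object of class `rsf_model`.
#' @examples
#' coh <- generate_cohort(default_params(n_patients = 300, seed = 5))
#' ep <- derive_endpoints(coh)
#' m <- fit_rsf(ep$os_time, ep$os_event, coh, c("sex", "n_stage"),
#'              n_trees = 25, seed = 1)
#' f <- predict_cumulative(m, coh[1, ], time_grid = 0:60)
#' @export
fit_rsf <- function(time, event, data, covariates, n_trees = 1000L,
                    mtry = NULL, min_terminal_events = 15L,
                    bootstrap = TRUE, seed = NULL) {
  if (sum(event) < 1) stop("all-censored input: no events to model", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  levels_map <- rsf_levels_map(data, covariates)
  X <- rsf_encode(data, covariates, levels_map)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  mtry <- max(1L, min(as.integer(mtry), p))
  forest <- with_preserved_seed(seed, {
    .rsf_grow(as.numeric(time), as.integer(event), X,
              as.integer(n_trees), mtry, as.integer(min_terminal_events),
              isTRUE(bootstrap))
  })
  structure(list(forest = forest, covariates = covariates,
                 levels_map = levels_map, n_trees = as.integer(n_trees),
                 mtry = mtry, min_terminal_events = as.integer(min_terminal_events),
                 bootstrap = isTRUE(bootstrap), seed = seed,
                 n = length(time), n_events = sum(event),
                 max_time = max(time)),
            class = "rsf_model")
}

#' Predict cumulative failure probability curves
#'
#' Drops each profile down every tree, averages the terminal-node
#' Nelson-Aalen cumulative hazards across trees, and converts the ensemble
#' hazard to a cumulative probability `F(t) = 1 - exp(-H(t))`.  The curves
#' are right-continuous step functions evaluated on `time_grid`; `F` is
#' non-decreasing by construction.
#'
#' @param model an `rsf_model` from [fit_rsf()].
#' @param newdata data frame of covariate profiles (must cover all model
#'   covariates; unseen factor levels are an error naming the covariate).
#' @param time_grid evaluation times (months).
#' @return matrix (profiles x times) of cumulative failure probabilities,
#'   with the grid as column names and the ensemble cumulative hazard
#'   attached as attribute `"chf"`.
#' @export
predict_cumulative <- function(model, newdata, time_grid) {
  stopifnot(inherits(model, "rsf_model"))
  X <- rsf_encode(newdata, model$covariates, model$levels_map)
  H <- .rsf_predict(model$forest, X, as.numeric(time_grid))
  F_ <- 1 - exp(-H)
  dimnames(F_) <- list(NULL, as.character(time_grid))
  attr(F_, "chf") <- H
  F_
}

#' First split variable of each tree
#'
#' Name of the covariate each tree splits on at its root (`NA` for
#' root-only trees); useful for inspecting split behaviour.
#'
#' @param model an `rsf_model`.
#' @return character vector of length `n_trees`.
#' @export
first_splits <- function(model) {
  vars <- vapply(model$forest, function(tr) tr$split_var[1], integer(1))
  ifelse(vars < 0, NA_character_, model$covariates[vars + 1])
}

#' @export
print.rsf_model <- function(x, ...) {
  cat("<rsf_model>", x$n_trees, "trees, n =", x$n,
      "(", x$n_events, "events ), mtry =", x$mtry,
      ", min terminal events =", x$min_terminal_events, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
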