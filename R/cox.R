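# Cox proportional-hazards fitting: damped Newton on the partial
# likelihood, Efron (default) or Breslow handling of tied event times.

# Internal engine.  X is the n x p model matrix (no intercept).
# Returns beta, vcov, loglik trace, convergence info.
cox_engine <- function(time, event, X, ties = "efron",
                       max_iter = 25L, tol = 1e-8) {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; X_s <- X[ord, , drop = FALSE]

  first_of_block <- c(TRUE, t_s[-1] != t_s[-n])
  block <- cumsum(first_of_block)
  first_idx <- which(first_of_block)
  d_tot <- rowsum(e_s, block)[, 1]
  ev <- which(d_tot > 0)                  # event blocks
  f_ev <- first_idx[ev]
  d_ev <- d_tot[ev]
  tied <- which(d_ev > 1)
  # pairs for the packed symmetric S2 accumulator
  pp <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)

  rev_cum <- function(m) {
    # reverse cumulative sums down the rows (vector or matrix)
    if (is.matrix(m)) apply(m[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
    else rev(cumsum(rev(m)))
  }

  deriv <- function(beta) {
    eta <- drop(X_s %*% beta)
    eta <- pmin(eta, 500)                 # overflow guard under separation
    w <- exp(eta)
    Xw <- X_s * w
    XXw <- X_s[, pp[, 1], drop = FALSE] * X_s[, pp[, 2], drop = FALSE] * w
    S0 <- rev_cum(w)[f_ev]
    S1 <- rev_cum(Xw)[f_ev, , drop = FALSE]
    S2 <- rev_cum(XXw)[f_ev, , drop = FALSE]
    if (!is.matrix(S1)) { S1 <- matrix(S1, ncol = p); S2 <- matrix(S2, ncol = nrow(pp)) }

    deaths <- e_s == 1
    sum_eta_d <- sum(eta[deaths])
    sum_x_d <- colSums(X_s[deaths, , drop = FALSE])

    unpack <- function(v) {
      M <- matrix(0, p, p)
      M[cbind(pp[, 1], pp[, 2])] <- v
      M[cbind(pp[, 2], pp[, 1])] <- v
      M
    }

    ll <- sum_eta_d
    grad <- sum_x_d
    info <- matrix(0, p, p)

    if (ties == "breslow" || length(tied) == 0) {
      D <- S0
      g <- S1 / D
      ll <- ll - sum(d_ev * log(D))
      grad <- grad - colSums(d_ev * g)
      info <- unpack(colSums(d_ev * S2 / D)) - crossprod(sqrt(d_ev) * g)
    } else {
      # Efron: singles vectorised, tied blocks handled explicitly
      singles <- which(d_ev == 1)
      if (length(singles)) {
        D <- S0[singles]
        g <- S1[singles, , drop = FALSE] / D
        ll <- ll - sum(log(D))
        grad <- grad - colSums(g)
        info <- unpack(colSums(S2[singles, , drop = FALSE] / D)) - crossprod(g)
      }
      s0d <- rowsum(w * e_s, block)[, 1][ev]
      s1d <- rowsum(Xw * e_s, block)[ev, , drop = FALSE]
      s2d <- rowsum(XXw * e_s, block)[ev, , drop = FALSE]
      for (j in tied) {
        d <- d_ev[j]
        for (l in seq_len(d) - 1) {
          frac <- l / d
          D <- S0[j] - frac * s0d[j]
          gv <- (S1[j, ] - frac * s1d[j, ]) / D
          ll <- ll - log(D)
          grad <- grad - gv
          info <- info + unpack((S2[j, ] - frac * s2d[j, ]) / D) - tcrossprod(gv)
        }
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- rep(0, p)
  cur <- deriv(beta)
  ll_trace <- cur$ll
  converged <- FALSE
  flag <- NULL
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) { flag <- "singular information matrix"; break }
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      nxt <- deriv(cand)
      if (nxt$ll >= cur$ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    cur <- nxt
    ll_trace <- c(ll_trace, cur$ll)
    if (sqrt(sum(cur$grad^2)) < tol) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 15) {
    converged <- FALSE
    flag <- "possible complete separation (diverging coefficient)"
  }
  vcov <- tryCatch(solve(cur$info), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vcov, loglik = cur$ll, loglik_trace = ll_trace,
       iterations = length(ll_trace) - 1L, converged = converged, flag = flag)
}

# Build the model matrix (indicator contrasts, first level as reference)
# and its term assignment for a covariate set.
cox_model_matrix <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stopf("covariates not in data: %s", paste(miss, collapse = ", "))
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(f, data = data)
  assign <- attr(mm, "assign")
  keep <- assign != 0
  list(X = mm[, keep, drop = FALSE], term = covariates[assign[keep]])
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood by damped Newton iteration (step
#' halving whenever a step would decrease the likelihood) to a gradient
#' norm of `tol`.  Ties are handled by the Efron approximation by default;
#' Breslow is available by flag.  Categorical covariates are encoded as
#' indicator contrasts against their first (reference) level.
#' Non-convergence and apparent complete separation are flagged on the
#' returned object rather than raised.
#'
#' @param time,event follow-up times and event flags.
#' @param data data frame holding the covariates.
#' @param covariates character vector of column names to enter the model.
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return an object of class `cox_fit`: `coefficients` (data frame with
#'   `term`, `contrast`, `coef`, `hazard_ratio`, `se`, `z`, `p_value`,
#'   `lower95`, `upper95`), `vcov`, `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `flag`, `ties_method`, `n`, `n_events`,
#'   and (after [backward_eliminate()]) `elimination_trace`.
#' @examples
#' coh <- generate_cohort(default_params(n_patients = 400, seed = 2))
#' ep <- derive_endpoints(coh)
#' fit <- cox_fit(ep$os_time, ep$os_event, coh, c("sex", "overall_stage"))
#' fit$coefficients
#' @export
cox_fit <- function(time, event, data, covariates,
                    ties = c("efron", "breslow"),
                    max_iter = 25L, tol = 1e-8) {
  ties <- match.arg(ties)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  mm <- cox_model_matrix(data, covariates)
  eng <- cox_engine(time, event, mm$X, ties = ties,
                    max_iter = max_iter, tol = tol)
  se <- sqrt(diag(eng$vcov))
  z <- eng$beta / se
  zq <- qnorm(0.975)
  coefs <- data.frame(
    term = mm$term,
    contrast = colnames(mm$X),
    coef = eng$beta,
    hazard_ratio = exp(eng$beta),
    se = se,
    z = z,
    p_value = 2 * pnorm(-abs(z)),
    lower95 = exp(eng$beta - zq * se),
    upper95 = exp(eng$beta + zq * se),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefs, vcov = eng$vcov,
                 loglik = eng$loglik, loglik_trace = eng$loglik_trace,
                 iterations = eng$iterations, converged = eng$converged,
                 flag = eng$flag, ties_method = ties,
                 n = length(time), n_events = sum(event),
                 elimination_trace = NULL),
            class = "cox_fit")
}

# Block Wald test for all coefficients belonging to one term.
term_wald_p <- function(fit, term) {
  sel <- which(fit$coefficients$term == term)
  if (!length(sel)) return(NA_real_)
  b <- fit$coefficients$coef[sel]
  V <- fit$vcov[sel, sel, drop = FALSE]
  chi <- tryCatch(drop(crossprod(b, solve(V, b))), error = function(e) NA_real_)
  if (!is.finite(chi)) return(NA_real_)
  pchisq(chi, length(sel), lower.tail = FALSE)
}

#' Univariable screening followed by backward elimination
#'
#' Mirrors the conventional two-stage model build: candidate covariates are
#' screened by a univariable Cox Wald test at `screen_alpha`; survivors
#' enter a multivariable model from which the largest-P term is removed
#' iteratively until every retained term has P < `stay_alpha`.
#' Multi-level factors are screened, tested and dropped as whole terms
#' (block Wald tests).  The full trace is recorded on the returned fit.
#'
#' @inheritParams cox_fit
#' @param candidates character vector of candidate covariate names.
#' @param screen_alpha univariable inclusion threshold (default 0.10).
#' @param stay_alpha multivariable retention threshold (default 0.05).
#' @return a `cox_fit` for the final model, with `screen` (per-candidate
#'   univariable P and kept flag) and `elimination_trace` (terms dropped
#'   from the multivariable model, in order, with their P at removal).
#'   When every candidate is screened out the fit has zero coefficients
#'   and `flag` explains why.
#' @export
backward_eliminate <- function(time, event, data, candidates,
                               screen_alpha = 0.10, stay_alpha = 0.05,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!length(candidates)) stop("candidate set is empty", call. = FALSE)
  uni_p <- vapply(candidates, function(cv) {
    f <- tryCatch(cox_fit(time, event, data, cv, ties = ties),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else term_wald_p(f, cv)
  }, numeric(1))
  screen <- data.frame(term = candidates, univariable_p = uni_p,
                       kept = !is.na(uni_p) & uni_p < screen_alpha,
                       stringsAsFactors = FALSE, row.names = NULL)
  current <- screen$term[screen$kept]
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_at_removal = numeric(0), stringsAsFactors = FALSE)
  if (!length(current)) {
    out <- structure(list(coefficients = data.frame(), vcov = matrix(0, 0, 0),
                          loglik = NA_real_, loglik_trace = numeric(0),
                          iterations = 0L, converged = TRUE,
                          flag = "all candidates screened out at screen_alpha",
                          ties_method = ties, n = length(time),
                          n_events = sum(event),
                          elimination_trace = trace),
                     class = "cox_fit")
    out$screen <- screen
    return(out)
  }
  step <- 0L
  repeat {
    fit <- cox_fit(time, event, data, current, ties = ties)
    pv <- vapply(current, function(tm) term_wald_p(fit, tm), numeric(1))
    worst <- which.max(pv)
    if (!length(worst) || pv[worst] < stay_alpha || length(current) == 0) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = current[worst],
                                     p_at_removal = pv[worst],
                                     stringsAsFactors = FALSE))
    current <- current[-worst]
    if (!length(current)) {
      fit <- structure(list(coefficients = data.frame(),
                            vcov = matrix(0, 0, 0),
                            loglik = NA_real_, loglik_trace = numeric(0),
                            iterations = 0L, converged = TRUE,
                            flag = "all screened candidates eliminated at stay_alpha",
                            ties_method = ties, n = length(time),
                            n_events = sum(event),
                            elimination_trace = trace),
                       class = "cox_fit")
      fit$screen <- screen
      return(fit)
    }
  }
  fit$elimination_trace <- trace
  fit$screen <- screen
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, "(", x$n_events, "events ), ties:",
      x$ties_method, "\n")
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  if (nrow(x$coefficients %||% data.frame())) {
    df <- x$coefficients
    df$hazard_ratio <- round(df$hazard_ratio, 3)
    df$p_value <- signif(df$p_value, 3)
    print(df[, c("contrast", "coef", "hazard_ratio", "lower95", "upper95",
                 "p_value")], row.names = FALSE, digits = 4)
  }
  if (!is.null(x$elimination_trace) && nrow(x$elimination_trace))
    cat("  eliminated:", paste(x$elimination_trace$dropped, collapse = ", "), "\n")
  invisible(x)
}
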