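# Analytic oracle for the generator: expected observed-event fractions by
# numerical integration of the latent-competing-times model.

# Indicator -> (factor column, exposed level) map.
indicator_map <- function() {
  list(male = c("sex", "Male"),
       age_gt45 = c("age_group", ">45"),
       who3 = c("histology", "WHO III"),
       smoking = c("smoking", "Yes"),
       drinking = c("drinking", "Yes"),
       family_history = c("family_history", "Yes"),
       t34 = c("t_stage", "T3-4"),
       n23 = c("n_stage", "N2-3"),
       iva = c("overall_stage", "IVa"),
       ebv = c("ebv_dna", ">=4000"),
       ic_gt2 = c("ic_cycles", ">2"),
       ccd_mid = c("ccd_group", "1-200"),
       ccd_high = c("ccd_group", ">200"))
}

# Enumerate the distinct covariate profiles that matter for the hazards
# (indicators appearing in some effect vector), with mixture weights.
# Returns list(Z = m x 13 indicator matrix, w = weights).
profile_mixture <- function(params) {
  imap <- indicator_map()
  used <- unique(unlist(lapply(params$log_hazard_effects, names)))
  used_ccd <- any(c("ccd_mid", "ccd_high") %in% used)
  used_bin <- setdiff(used, c("ccd_mid", "ccd_high"))

  grids <- lapply(used_bin, function(x) c(0, 1))
  names(grids) <- used_bin
  if (used_ccd) grids$..ccd <- c("0", "1-200", ">200")
  if (!length(grids)) {
    Z <- matrix(0, 1, length(imap), dimnames = list(NULL, names(imap)))
    return(list(Z = Z, w = 1))
  }
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  m <- nrow(combos)
  Z <- matrix(0, m, length(imap), dimnames = list(NULL, names(imap)))
  w <- rep(1, m)
  for (nm in used_bin) {
    fac <- imap[[nm]][1]; lev <- imap[[nm]][2]
    p1 <- params$covariate_marginals[[fac]][[lev]]
    Z[, nm] <- combos[[nm]]
    w <- w * ifelse(combos[[nm]] == 1, p1, 1 - p1)
  }
  if (used_ccd) {
    pc <- params$covariate_marginals$ccd_group
    Z[, "ccd_mid"] <- as.numeric(combos$..ccd == "1-200")
    Z[, "ccd_high"] <- as.numeric(combos$..ccd == ">200")
    w <- w * pc[combos$..ccd]
  }
  list(Z = Z, w = unname(w))
}

#' Expected observed-event fractions of the generating model
#'
#' Computes, by deterministic numerical integration over the covariate
#' mixture and the piecewise-constant latent hazards, the expected fraction
#' of patients whose locoregional failure, distant failure, and death are
#' observed before administrative censoring, together with the expected
#' fraction of observed failures that are "early" (at or before the true
#' change-point).  This is the analytic oracle the generator is tested
#' against: [generate_cohort()] must reproduce these fractions within
#' Monte-Carlo error.
#'
#' The integration discretises time into cells of width `dt` months,
#' uses exact piecewise-exponential cell probabilities, and approximates
#' the failure-then-death convolutions at cell midpoints; the
#' discretisation error is O(`dt`).
#'
#' @param params a [cohort_params()] object.
#' @param dt integration cell width in months.
#' @param horizon upper integration limit (months); defaults to the
#'   censoring maximum, beyond which no event can be observed.
#' @return `list(fractions, early_given_failure, dt, horizon)` where
#'   `fractions` is a named probability vector over
#'   `locoregional`/`distant`/`death` and `early_given_failure` gives the
#'   early fraction among observed locoregional / distant failures.
#' @export
expected_event_fractions <- function(params, dt = 0.25, horizon = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  cmin <- params$censoring[1]; cmax <- params$censoring[2]
  if (is.null(horizon)) horizon <- cmax
  horizon <- min(horizon, cmax)
  K <- ceiling(horizon / dt)
  edges <- seq(0, by = dt, length.out = K + 1)
  mid <- edges[-1] - dt / 2
  G <- pmin(1, pmax(0, (cmax - mid) / (cmax - cmin)))
  G[mid <= cmin] <- 1

  mix <- profile_mixture(params)
  pf <- params$baseline_hazards$post_failure
  gamma <- params$post_failure_early_loghr
  co_l <- params$true_cutoff_lrf_months
  co_d <- params$true_cutoff_df_months

  # residual-survival lookups on the offset grid, by early status
  S_R <- function(u, early) {
    H <- pch_cumhaz(u, pf$breaks, pf$rates) * exp(gamma * as.numeric(early))
    exp(-H)
  }
  i_seq <- seq_len(K)
  SRe_on <- lapply(c(FALSE, TRUE), function(e) S_R(i_seq * dt, e))
  qRe <- lapply(c(FALSE, TRUE), function(e) {
    # residual death-cell probabilities: offset 0 covers residual < dt/2,
    # offset i covers ((i - 1/2) dt, (i + 1/2) dt]
    c(1 - S_R(dt / 2, e),
      S_R((i_seq - 0.5) * dt, e) - S_R((i_seq + 0.5) * dt, e))
  })
  idx <- outer(i_seq, i_seq, "-")          # k - j

  tri_lookup <- function(v) {
    # matrix B with B[k, j] = v[k - j] for k > j else 0
    B <- matrix(0, K, K)
    pos <- idx >= 1
    B[pos] <- v[idx[pos]]
    B
  }
  conv_lag <- function(a, v) drop(tri_lookup(v) %*% a)

  totals <- c(locoregional = 0, distant = 0, death = 0)
  early_num <- c(locoregional = 0, distant = 0)

  for (g in seq_along(mix$w)) {
    Z <- mix$Z[g, , drop = FALSE]
    w <- mix$w[g]
    if (w == 0) next
    rl <- subject_rates(params, "locoregional", Z)
    rd <- subject_rates(params, "distant", Z)
    r0 <- subject_rates(params, "death", Z)
    SL <- pch_survival(edges, rl$breaks, drop(rl$rates))
    SD <- pch_survival(edges, rd$breaks, drop(rd$rates))
    S0 <- pch_survival(edges, r0$breaks, drop(r0$rates))
    SLm <- pch_survival(mid, rl$breaks, drop(rl$rates))
    SDm <- pch_survival(mid, rd$breaks, drop(rd$rates))
    S0m <- pch_survival(mid, r0$breaks, drop(r0$rates))
    pL <- SL[-(K + 1)] - SL[-1]
    pD <- SD[-(K + 1)] - SD[-1]
    p0 <- S0[-(K + 1)] - S0[-1]

    eL <- mid <= co_l                       # early status of an L-first failure
    eD <- mid <= co_d

    # observed locoregional failure: L at cell k with (no D, no death before)
    # or D-first at j < k with death postponed past k
    aD <- pD * S0m                          # D-first mass surviving the death race
    inner_L <- conv_lag(aD * (!eD), SRe_on[[1]]) + conv_lag(aD * eD, SRe_on[[2]])
    pLR_obs <- pL * G * (SDm * S0m + inner_L)
    totals["locoregional"] <- totals["locoregional"] + w * sum(pLR_obs)
    early_num["locoregional"] <- early_num["locoregional"] + w * sum(pLR_obs[eL])

    aL <- pL * S0m
    inner_D <- conv_lag(aL * (!eL), SRe_on[[1]]) + conv_lag(aL * eL, SRe_on[[2]])
    pDM_obs <- pD * G * (SLm * S0m + inner_D)
    totals["distant"] <- totals["distant"] + w * sum(pDM_obs)
    early_num["distant"] <- early_num["distant"] + w * sum(pDM_obs[eD])

    # observed death: failure-free death, or first failure then residual death
    dA <- p0 * SLm * SDm
    pfE <- pL * SDm * S0m * eL + pD * SLm * S0m * eD
    pfLt <- pL * SDm * S0m * (!eL) + pD * SLm * S0m * (!eD)
    convq <- function(a, q) {
      # offset-0 term lands in the failure's own cell
      a * q[1] + conv_lag(a, q[-1])
    }
    dB <- convq(pfLt, qRe[[1]]) + convq(pfE, qRe[[2]])
    totals["death"] <- totals["death"] + w * sum((dA + dB) * G)
  }

  early <- c(locoregional = unname(early_num["locoregional"] / totals["locoregional"]),
             distant = unname(early_num["distant"] / totals["distant"]))
  early[!is.finite(early)] <- NA_real_
  list(fractions = totals, early_given_failure = early, dt = dt, horizon = horizon)
}
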