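# Shared fixtures, built in code.

# Small parameter set for fast generator tests.
quick_params <- function(n = 500, seed = 1) default_params(n_patients = n, seed = seed)

# Direct simulator of a failure cohort (interval, post-failure survival)
# with an optional change-point in the post-failure death hazard; the
# fixture for cut-point scan tests that do not need a full cohort.
sim_failure_cohort <- function(n, cutoff, loghr, seed,
                               shape = c("lrf", "df"),
                               base_rate = 0.0117,
                               censor_range = c(12, 72)) {
  shape <- match.arg(shape)
  set.seed(seed)
  interval <- if (shape == "lrf") runif(n, 1, 70) else pmin(1 + rexp(n, 1 / 22), 80)
  early <- interval <= cutoff
  death_time <- rexp(n, base_rate * exp(loghr * early))
  cens <- runif(n, censor_range[1], censor_range[2])
  data.frame(interval = interval,
             post_time = pmin(death_time, cens),
             death = as.numeric(death_time <= cens))
}

# Two-group exponential survival data with a known log hazard ratio.
sim_two_group <- function(n_per_arm, loghr, seed, base_rate = 0.03,
                          censor_range = NULL) {
  set.seed(seed)
  x <- rep(c(0, 1), each = n_per_arm)
  tt <- rexp(2 * n_per_arm, base_rate * exp(loghr * x))
  if (is.null(censor_range)) {
    data.frame(time = tt, event = 1, x = x)
  } else {
    cc <- runif(2 * n_per_arm, censor_range[1], censor_range[2])
    data.frame(time = pmin(tt, cc), event = as.numeric(tt <= cc), x = x)
  }
}
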