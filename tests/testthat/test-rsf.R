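# Random survival forest and adjusted hazard curves.

test_that("a root-only single tree reproduces the cohort Nelson-Aalen estimator", {
  set.seed(5)
  n <- 150
  d <- data.frame(x1 = rbinom(n, 1, .5), x2 = rbinom(n, 1, .3))
  tt <- rexp(n, 0.03)
  ev <- rbinom(n, 1, 0.6)
  m <- fit_rsf(tt, ev, d, c("x1", "x2"), n_trees = 1,
               min_terminal_events = sum(ev) + 1, bootstrap = FALSE, seed = 3)
  na <- nelson_aalen(tt, ev)
  grid <- sort(unique(c(0, na$time, 40, 70)))
  F_ <- predict_cumulative(m, d[1, , drop = FALSE], grid)
  H <- drop(attr(F_, "chf"))
  H_ref <- vapply(grid, function(g) {
    i <- sum(na$time <= g); if (i == 0) 0 else na$chf[i]
  }, numeric(1))
  expect_equal(unname(H), H_ref, tolerance = 1e-12)
  expect_equal(unname(drop(F_)), 1 - exp(-H_ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("forests are deterministic under a fixed seed", {
  set.seed(6)
  n <- 200
  d <- data.frame(x1 = rbinom(n, 1, .5), x2 = rbinom(n, 1, .3))
  tt <- rexp(n, 0.03 * exp(0.8 * d$x1))
  m1 <- fit_rsf(tt, rep(1, n), d, c("x1", "x2"), n_trees = 25,
                min_terminal_events = 10, seed = 9)
  m2 <- fit_rsf(tt, rep(1, n), d, c("x1", "x2"), n_trees = 25,
                min_terminal_events = 10, seed = 9)
  expect_identical(m1$forest, m2$forest)
  m3 <- fit_rsf(tt, rep(1, n), d, c("x1", "x2"), n_trees = 25,
                min_terminal_events = 10, seed = 10)
  expect_false(identical(m1$forest, m3$forest))
})

test_that("a single strong covariate dominates the first split", {
  set.seed(7)
  n <- 2000
  d <- data.frame(strong = rbinom(n, 1, .5), weak = rbinom(n, 1, .5))
  tt <- rexp(n, 0.03 * exp(1.2 * d$strong))
  m <- fit_rsf(tt, rep(1, n), d, c("strong", "weak"), n_trees = 60,
               min_terminal_events = 15, mtry = 2, seed = 4)
  expect_gte(mean(first_splits(m) == "strong", na.rm = TRUE), 0.95)
})

test_that("bootstrap resamples have cohort size and predictions are monotone", {
  set.seed(8)
  n <- 120
  d <- data.frame(x = rbinom(n, 1, .5))
  tt <- rexp(n, 0.04)
  ev <- rbinom(n, 1, 0.7)
  m <- fit_rsf(tt, ev, d, "x", n_trees = 10, seed = 2)
  for (tr in m$forest) expect_length(tr$inbag, n)
  F_ <- predict_cumulative(m, data.frame(x = c(0, 1)), 0:60)
  expect_true(all(diff(F_[1, ]) >= -1e-15))
  expect_true(all(diff(F_[2, ]) >= -1e-15))
  expect_true(all(F_ >= 0 & F_ <= 1))
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- data.frame(x = c(0, 1, 0, 1))
  expect_error(fit_rsf(c(1, 2, 3, 4), c(0, 0, 0, 0), d, "x"), "all-censored")
  set.seed(9)
  n <- 80
  dd <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  m <- fit_rsf(rexp(n, .05), rep(1, n), dd, "g", n_trees = 5, seed = 1)
  expect_error(predict_cumulative(m, data.frame(g = "zz"), 0:10), "'g'.*unseen|unseen.*'g'")
})

test_that("adjusted group curves equal the individual prediction for a single profile", {
  set.seed(10)
  n <- 300
  d <- data.frame(x = rbinom(n, 1, .5),
                  g = factor(sample(c("lo", "hi"), n, TRUE)))
  tt <- rexp(n, 0.03 * exp(0.5 * (d$g == "hi")))
  m <- fit_rsf(tt, rep(1, n), d, c("x", "g"), n_trees = 40, seed = 6)
  one <- d[5, , drop = FALSE]
  cur <- adjusted_group_curves(m, one, "g", 0:48, smoothing_window = 1)
  for (lev in c("lo", "hi")) {
    prof <- one; prof$g <- factor(lev, levels = levels(d$g))
    expect_equal(unname(cur$cumulative[lev, ]),
                 unname(drop(predict_cumulative(m, prof, 0:48))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(adjusted_group_curves(m, one, "g", 0:48, groups = "none"),
               "absent")
})

test_that("a null group covariate yields adjusted curves within ensemble noise", {
  # dose effects switched off: any group separation is forest noise.  The
  # noise scale at n = 3000 with 1000 trees is ~0.01-0.03 in sup-norm for
  # partial-dependence curves (the same magnitude an independent forest
  # implementation shows on identical data), well below the ~0.1-scale
  # separations a real early-window dose effect produces.
  p <- default_params(n_patients = 3000L, seed = 71)
  p$log_hazard_effects$distant_early <- c()
  coh <- generate_cohort(p)
  ep <- derive_endpoints(coh)
  covs <- c("sex", "age_group", "smoking", "family_history", "t_stage",
            "n_stage", "ccd_group")
  m <- fit_rsf(ep$dffs_time, ep$dffs_event, coh, covs, n_trees = 1000,
               seed = 171)
  cur <- adjusted_group_curves(m, coh, "ccd_group", 0:60,
                               smoothing_window = 1)
  gap <- max(apply(cur$cumulative, 2, function(col) diff(range(col))))
  expect_lt(gap, 0.05)
})

test_that("monthly probabilities match the closed form for an exponential curve", {
  lam <- 0.02
  F_ <- 1 - exp(-lam * 0:60)
  f <- monthly_probability(F_, window = 1)
  expect_equal(f, exp(-lam * 0:59) - exp(-lam * 1:60), tolerance = 1e-12)
  # constant curve: nothing happens in any month
  expect_equal(monthly_probability(rep(0.3, 20), window = 3), rep(0, 19))
  expect_error(monthly_probability(c(0, 0.2, 0.1)), "non-decreasing")
  expect_error(monthly_probability(F_, window = 2), "odd")
})

test_that("smoothed monthly probabilities conserve the cumulative mass", {
  set.seed(13)
  F_ <- cumsum(c(0, abs(rnorm(120, 0.002, 0.002))))
  F_ <- F_ / max(F_) * 0.4
  for (w in c(1, 3, 5)) {
    f <- monthly_probability(F_, window = w)
    expect_lt(abs(sum(f) - (F_[length(F_)] - F_[1])), 1e-9)
    expect_true(all(f >= 0))
  }
})

test_that("a protective group effect lowers the predicted cumulative curve", {
  set.seed(14)
  n <- 1500
  d <- data.frame(g = factor(sample(c("ctl", "tx"), n, TRUE)))
  tt <- rexp(n, 0.015 * exp(log(0.5) * (d$g == "tx")))
  cc <- runif(n, 30, 90)
  m <- fit_rsf(pmin(tt, cc), as.numeric(tt <= cc), d, "g",
               n_trees = 150, seed = 15)
  F_ <- predict_cumulative(m, data.frame(g = factor(c("ctl", "tx"))), 0:60)
  expect_lt(F_[2, "60"], F_[1, "60"])
})

test_that("adjusted curves are stable in the number of trees", {
  covs <- c("sex", "age_group", "smoking", "family_history", "t_stage",
            "n_stage", "ccd_group")
  gaps <- vapply(1:2, function(s) {
    coh <- generate_cohort(default_params(seed = s))
    ep <- derive_endpoints(coh)
    m5 <- fit_rsf(ep$ffs_time, ep$ffs_event, coh, covs, n_trees = 500,
                  seed = 100 + s)
    m10 <- fit_rsf(ep$ffs_time, ep$ffs_event, coh, covs, n_trees = 1000,
                   seed = 200 + s)
    c5 <- adjusted_group_curves(m5, coh, "ccd_group", 0:120)
    c10 <- adjusted_group_curves(m10, coh, "ccd_group", 0:120)
    max(abs(c5$cumulative - c10$cumulative))
  }, numeric(1))
  expect_lt(mean(gaps), 0.01)
})

test_that("monthly failure probabilities peak inside the elevated-hazard window", {
  coh <- generate_cohort(default_params(seed = 16))
  ep <- derive_endpoints(coh)
  fail <- ep$lrffs_event == 1 | ep$dffs_event == 1
  tm <- pmin(ifelse(ep$lrffs_event == 1, ep$lrffs_time, Inf),
             ifelse(ep$dffs_event == 1, ep$dffs_time, Inf))
  tm[!fail] <- ep$os_time[!fail]
  covs <- c("sex", "age_group", "smoking", "family_history", "t_stage",
            "n_stage", "ccd_group")
  m <- fit_rsf(tm, as.numeric(fail), coh, covs, n_trees = 300, seed = 17)
  cur <- adjusted_group_curves(m, coh, "ccd_group", 0:120)
  peaks <- apply(cur$monthly, 1, which.max)
  expect_true(all(peaks <= 48))
})
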