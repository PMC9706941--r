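# Endpoint derivation, Kaplan-Meier, log-rank, Cox, contingency tests.

test_that("endpoint derivation follows the definitions", {
  rec <- data.frame(
    patient_id = c("a", "b"),
    t_locoregional = c(10, 60), locoregional_event = c(1, 0),
    t_distant = c(25, 60), distant_event = c(0, 0),
    t_os = c(25, 60), death_event = c(1, 0))
  ep <- derive_endpoints(rec)
  # failure at 10, death at 25 -> post-failure OS (15, death)
  expect_equal(ep$pf_lr_time[1], 15)
  expect_equal(ep$pf_lr_event[1], 1)
  expect_equal(ep$ffs_time[1], 10)
  expect_equal(ep$ffs_event[1], 1)
  # no failures, alive at 60 -> everything censored at 60
  expect_equal(ep$os_time[2], 60)
  expect_equal(unname(unlist(ep[2, c("os_event", "ffs_event", "lrffs_event",
                                     "dffs_event")])), rep(0, 4))
  expect_true(is.na(ep$pf_lr_time[2]))
})

test_that("endpoint derivation validates records and names offenders", {
  rec <- data.frame(
    patient_id = c("ok", "bad"),
    t_locoregional = c(5, 30), locoregional_event = c(0, 1),
    t_distant = c(5, 10), distant_event = c(0, 0),
    t_os = c(5, 20), death_event = c(0, 1))
  expect_error(derive_endpoints(rec), "bad")
  rec2 <- rec
  rec2$locoregional_event <- c(0, 0)
  rec2$t_locoregional <- c(5, 20)
  expect_silent(derive_endpoints(rec2))
  rec3 <- rec2
  rec3$t_os[1] <- -1
  expect_error(derive_endpoints(rec3), "ok")
})

test_that("ffs time is the minimum of the component endpoint times", {
  coh <- generate_cohort(quick_params(1500, seed = 21))
  ep <- derive_endpoints(coh)
  expect_true(all(ep$ffs_time <= ep$lrffs_time + 1e-12))
  expect_true(all(ep$ffs_time <= ep$dffs_time + 1e-12))
  expect_true(all(ep$ffs_time <= ep$os_time + 1e-12))
  expect_equal(ep$ffs_time,
               pmin(ep$lrffs_time, ep$dffs_time, ep$os_time))
  expect_true(all(ep$pf_lr_time >= 0, na.rm = TRUE))
})

test_that("derived failure fraction matches the generator oracle", {
  p <- default_params(n_patients = 50000L, seed = 31)
  coh <- generate_cohort(p)
  ep <- derive_endpoints(coh)
  ef <- expected_event_fractions(p)
  se <- sqrt(ef$fractions[["locoregional"]] *
               (1 - ef$fractions[["locoregional"]]) / nrow(coh))
  expect_lt(abs(mean(ep$lrffs_event) - ef$fractions[["locoregional"]]),
            3 * se + 5e-4)
})

test_that("Kaplan-Meier reproduces the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 0, 1))
  # (5/6) * (4/5) * (2/3) = 4/9 at t = 4
  expect_equal(survival_at(km, 4), 4 / 9)
  expect_equal(survival_at(km, 3.5), 2 / 3)     # step value between events
  expect_equal(survival_at(km, 0), 1)
  expect_equal(survival_at(km, 100), survival_at(km, 6))  # carries forward
})

test_that("Kaplan-Meier limits: all-censored and no-censoring cases", {
  km0 <- km_estimate(c(2, 4, 7), c(0, 0, 0))
  expect_equal(survival_at(km0, c(0, 3, 10)), c(1, 1, 1))
  set.seed(8)
  tt <- rexp(60, 0.1)
  km1 <- km_estimate(tt, rep(1, 60))
  for (t in c(2, 5, 12)) expect_equal(survival_at(km1, t), mean(tt > t))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier agrees with the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(17)
  tt <- round(rexp(80, 0.08), 1)
  ev <- rbinom(80, 1, 0.6)
  km <- km_estimate(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  ref <- summary(sf, times = km$time)
  expect_equal(km$surv, ref$surv, tolerance = 1e-12)
})

test_that("log-rank matches exhaustive hand computation and reference results", {
  tt <- c(1, 3, 5, 2, 4, 6, 7, 8)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  gg <- c(1, 1, 1, 1, 2, 2, 2, 2)
  # independent explicit computation over event times
  OE <- 0; V <- 0
  for (t in sort(unique(tt[ev == 1]))) {
    at <- tt >= t
    n <- sum(at); n1 <- sum(at & gg == 1)
    d <- sum(tt == t & ev == 1); d1 <- sum(tt == t & ev == 1 & gg == 1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  lr <- logrank_test(tt, ev, gg)
  expect_equal(lr$chi_square, OE^2 / V, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(OE^2 / V, 1, lower.tail = FALSE))
  # label order invariance
  lr2 <- logrank_test(tt, ev, 3 - gg)
  expect_equal(lr$chi_square, lr2$chi_square, tolerance = 1e-12)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)
})

test_that("log-rank degenerate cases behave as specified", {
  # two identical groups
  lr <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                     rep(1:2, each = 3))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  # zero events in total
  lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 1, 2, 2))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(c(1, 2), c(1, 1),
                            factor(c("a", "a"), levels = c("a", "b"))),
               "zero subjects")
})

test_that("log-rank equals the Cox score test on untied data", {
  skip_if_not_installed("survival")
  set.seed(33)
  d <- sim_two_group(40, 0.6, seed = 33)
  lr <- logrank_test(d$time, d$event, d$x)
  cs <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                        ties = "breslow")
  expect_equal(lr$chi_square, unname(summary(cs)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("log-rank has power against a strong two-group difference", {
  rejections <- vapply(1:60, function(s) {
    d <- sim_two_group(500, 1, seed = 4000 + s, censor_range = c(5, 80))
    logrank_test(d$time, d$event, d$x)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.99)
})

test_that("Cox fit matches the reference implementation on random datasets", {
  skip_if_not_installed("survival")
  set.seed(2)
  for (i in 1:10) {
    n <- 120
    d <- data.frame(x1 = rbinom(n, 1, .5), x2 = rnorm(n),
                    g = factor(sample(c("a", "b", "c"), n, TRUE)))
    tt <- round(rexp(n, 0.05 * exp(0.7 * d$x1 - 0.3 * d$x2)), 1)  # ties
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 5) next
    for (ties in c("efron", "breslow")) {
      f1 <- cox_fit(tt, ev, d, c("x1", "x2", "g"), ties = ties)
      f2 <- survival::coxph(survival::Surv(tt, ev) ~ x1 + x2 + g, data = d,
                            ties = ties)
      expect_lt(max(abs(f1$coefficients$coef - unname(coef(f2)))), 1e-4)
      expect_lt(max(abs(f1$coefficients$se -
                          unname(sqrt(diag(vcov(f2)))))), 1e-4)
    }
  }
})

test_that("Cox partial likelihood never decreases across Newton iterations", {
  d <- sim_two_group(300, 0.8, seed = 91, censor_range = c(5, 60))
  f <- cox_fit(d$time, d$event, d, "x")
  expect_true(all(diff(f$loglik_trace) >= -1e-10))
  expect_true(f$converged)
})

test_that("Cox null behaviour: small coefficients, non-significant p-values", {
  res <- vapply(1:30, function(s) {
    d <- sim_two_group(1000, 0, seed = 600 + s)
    f <- cox_fit(d$time, d$event, d, "x")
    c(abs(f$coefficients$coef) < 0.1, f$coefficients$p_value > 0.05)
  }, logical(2))
  expect_gte(mean(res[1, ] & res[2, ]), 0.9)
})

test_that("Cox flags separation instead of failing silently", {
  # perfectly separated: all events in one arm, far earlier
  d <- data.frame(x = rep(c(0, 1), each = 20))
  tt <- c(seq(50, 69), seq(1, 20))
  ev <- c(rep(0, 20), rep(1, 20))
  f <- cox_fit(tt, ev, d, "x")
  expect_false(f$converged)
  expect_match(f$flag, "separation")
})

test_that("backward elimination screens, then prunes to stay_alpha", {
  set.seed(55)
  n <- 2500
  d <- data.frame(true = rbinom(n, 1, .5), n1 = rbinom(n, 1, .5),
                  n2 = rbinom(n, 1, .5), n3 = rbinom(n, 1, .5))
  tt <- rexp(n, 0.02 * exp(1 * d$true))
  cc <- runif(n, 10, 80)
  f <- backward_eliminate(pmin(tt, cc), as.numeric(tt <= cc), d, names(d))
  expect_true("true" %in% f$coefficients$term)
  retained_p <- vapply(unique(f$coefficients$term),
                       function(tm) failtiming:::term_wald_p(f, tm), numeric(1))
  expect_true(all(retained_p < 0.05))
  expect_true(all(!f$elimination_trace$dropped %in% f$coefficients$term))
  expect_identical(sort(unique(c(f$coefficients$term, f$elimination_trace$dropped,
                                 f$screen$term[!f$screen$kept]))),
                   sort(names(d)))
})

test_that("a single candidate failing the screen yields an empty fit with status", {
  set.seed(77)
  n <- 400
  d <- data.frame(x = rbinom(n, 1, .5))
  tt <- rexp(n, 0.03)           # no effect
  p_uni <- cox_fit(tt, rep(1, n), d, "x")$coefficients$p_value
  # a candidate whose univariable P sits at or above the screen threshold
  # is never included
  f <- backward_eliminate(tt, rep(1, n), d, "x", screen_alpha = p_uni / 2)
  expect_equal(nrow(f$coefficients), 0)
  expect_match(f$flag, "screened out")
})

test_that("contingency tests: chi-square formula, Fisher switch, enumeration oracle", {
  r <- contingency_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$method, "chi-square")

  # small 2x2: Fisher selected, p equals exhaustive hypergeometric enumeration
  tab <- matrix(c(3, 1, 1, 3), 2)
  r2 <- contingency_test(tab)
  expect_equal(r2$method, "fisher")
  m <- sum(tab[1, ]); k <- sum(tab[, 1]); N <- sum(tab)
  probs <- dhyper(0:min(m, k), m, N - m, k)
  p_obs <- dhyper(tab[1, 1], m, N - m, k)
  expect_equal(r2$p_value, sum(probs[probs <= p_obs + 1e-12]),
               tolerance = 1e-10)

  # 2x3 balanced-ish random table matches the textbook formula
  set.seed(5)
  t3 <- matrix(rpois(6, 30), 2, 3)
  r3 <- contingency_test(t3)
  E <- outer(rowSums(t3), colSums(t3)) / sum(t3)
  expect_equal(r3$statistic, sum((t3 - E)^2 / E), tolerance = 1e-12)
  expect_equal(r3$method, "chi-square")

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})
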