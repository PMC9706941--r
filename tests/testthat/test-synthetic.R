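# Synthetic-cohort generator and its analytic oracle.

test_that("default parameters encode the study conditions", {
  p <- default_params()
  expect_equal(p$n_patients, 3123L)
  expect_equal(unname(p$covariate_marginals$sex["Male"]), 0.744)
  expect_equal(p$true_cutoff_lrf_months, 14)
  expect_equal(p$true_cutoff_df_months, 20)
  expect_equal(unname(p$log_hazard_effects$distant_early["ccd_high"]),
               log(0.351))
  expect_equal(unname(p$log_hazard_effects$distant_early["ccd_mid"]),
               log(0.763))
  # marginals sum to one over each covariate's categories
  for (m in p$covariate_marginals) expect_equal(sum(m), 1, tolerance = 1e-9)
})

test_that("parameter validation rejects malformed inputs", {
  p <- default_params()
  bad <- p$covariate_marginals
  bad$sex <- c(Female = 0.5, Male = 0.6)
  expect_error(cohort_params(100, bad, p$baseline_hazards,
                             p$log_hazard_effects, 14, 20, 1, c(48, 96)),
               "sum")
  expect_error(cohort_params(100, p$covariate_marginals, p$baseline_hazards,
                             p$log_hazard_effects, 60, 20, 1, c(48, 96)),
               "strictly inside")
  expect_error(cohort_params(100, p$covariate_marginals, p$baseline_hazards,
                             p$log_hazard_effects, 14, 20, 1, c(96, 48)),
               "min < max")
})

test_that("generation is deterministic under a fixed seed and rejects tiny cohorts", {
  p <- quick_params(300, seed = 42)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  p2 <- quick_params(300, seed = 43)
  expect_false(identical(generate_cohort(p2), c1))
  expect_error(generate_cohort(quick_params(20)), "n_patients < 50")
})

test_that("record invariants hold: non-negative times, failures precede death/last contact", {
  coh <- generate_cohort(quick_params(2000, seed = 3))
  expect_true(all(coh$t_locoregional >= 0))
  expect_true(all(coh$t_os >= 0))
  expect_true(all(coh$t_locoregional[coh$locoregional_event == 1] <=
                    coh$t_os[coh$locoregional_event == 1] + 1e-9))
  expect_true(all(coh$t_distant[coh$distant_event == 1] <=
                    coh$t_os[coh$distant_event == 1] + 1e-9))
  expect_true(all(coh$locoregional_event %in% 0:1))
})

test_that("zero failure hazards give a cohort with deaths and censorings only", {
  p <- quick_params(400, seed = 5)
  p$baseline_hazards$locoregional$rates[] <- 0
  p$baseline_hazards$distant$rates[] <- 0
  coh <- generate_cohort(p)
  expect_equal(sum(coh$locoregional_event), 0)
  expect_equal(sum(coh$distant_event), 0)
  expect_gt(sum(coh$death_event), 0)
})

test_that("covariate marginals are calibrated at n = 10,000", {
  p <- default_params(n_patients = 10000L, seed = 7)
  coh <- generate_cohort(p)
  for (nm in names(p$covariate_marginals)) {
    tab <- table(coh[[nm]]) / nrow(coh)
    for (lev in names(p$covariate_marginals[[nm]])) {
      target <- p$covariate_marginals[[nm]][[lev]]
      band <- 3 * sqrt(target * (1 - target) / nrow(coh))
      expect_lt(abs(tab[[lev]] - target), band + 1e-12,
                label = sprintf("%s=%s observed %0.4f vs target %0.4f",
                                nm, lev, tab[[lev]], target))
    }
  }
})

test_that("oracle fractions reduce to the competing-exponentials closed form", {
  p <- default_params()
  p$log_hazard_effects <- list()
  lam1 <- 0.02; lam2 <- 0.03
  p$baseline_hazards$locoregional <- list(breaks = numeric(0), rates = lam1)
  p$baseline_hazards$distant <- list(breaks = numeric(0), rates = lam2)
  p$baseline_hazards$death <- list(breaks = numeric(0), rates = 0)
  p$baseline_hazards$post_failure <- list(breaks = numeric(0), rates = 1e3)
  p$censoring <- c(1e5, 2e5)   # effectively no censoring
  ef <- expected_event_fractions(p, dt = 0.5, horizon = 600)
  expect_equal(unname(ef$fractions["locoregional"]), lam1 / (lam1 + lam2),
               tolerance = 2e-3)
  expect_equal(unname(ef$fractions["distant"]), lam2 / (lam1 + lam2),
               tolerance = 2e-3)
  # every failure is followed near-instantly by death
  expect_equal(unname(ef$fractions["death"]), 1, tolerance = 2e-3)
})

test_that("oracle fractions are zero when failure hazards vanish", {
  p <- default_params()
  p$baseline_hazards$locoregional$rates[] <- 0
  p$baseline_hazards$distant$rates[] <- 0
  ef <- expected_event_fractions(p)
  expect_equal(unname(ef$fractions["locoregional"]), 0)
  expect_equal(unname(ef$fractions["distant"]), 0)
})

test_that("generator event fractions match the integration oracle within Monte-Carlo error", {
  p <- default_params(n_patients = 400000L, seed = 20260901)
  coh <- generate_cohort(p)
  ef <- expected_event_fractions(p)
  emp <- c(locoregional = mean(coh$locoregional_event),
           distant = mean(coh$distant_event),
           death = mean(coh$death_event))
  for (k in names(emp)) {
    se <- sqrt(ef$fractions[[k]] * (1 - ef$fractions[[k]]) / nrow(coh))
    expect_lt(abs(emp[[k]] - ef$fractions[[k]]), 3 * se + 5e-4,
              label = sprintf("%s empirical %.4f vs oracle %.4f",
                              k, emp[[k]], ef$fractions[[k]]))
  }
  # early-failure fractions among observed failures, against the oracle
  fc <- failure_cohort(coh, "lrf")
  fd <- failure_cohort(coh, "df")
  expect_equal(mean(fc$interval <= 14),
               unname(ef$early_given_failure["locoregional"]), tolerance = 0.02)
  expect_equal(mean(fd$interval <= 20),
               unname(ef$early_given_failure["distant"]), tolerance = 0.02)
})

test_that("an early-failure survival penalty is visible in post-failure KM curves", {
  coh <- generate_cohort(default_params(seed = 12))
  fc <- failure_cohort(coh, "lrf")
  lab <- split_failures(fc, 14)
  km_e <- km_estimate(fc$post_time[lab == "early"], fc$death[lab == "early"])
  km_l <- km_estimate(fc$post_time[lab == "late"], fc$death[lab == "late"])
  expect_lt(survival_at(km_e, 24), survival_at(km_l, 24))
  expect_lt(survival_at(km_e, 36), survival_at(km_l, 36))
})

test_that("cohorts round-trip through CSV with factor levels intact", {
  coh <- generate_cohort(quick_params(120, seed = 9))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".params.json"))), add = TRUE)
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(levels(back$ccd_group), c("0", "1-200", ">200"))
  expect_equal(back$t_os, coh$t_os, tolerance = 1e-12)
  expect_equal(as.character(back$sex), as.character(coh$sex))
  expect_true(file.exists(paste0(path, ".params.json")))
})
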