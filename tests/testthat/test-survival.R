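# Kaplan-Meier, restricted mean survival, log-rank and Cox against
# closed-form and simulation oracles.

test_that("KM handles censoring-only and single-event data", {
  rec <- data.frame(time = c(10, 20, 30), event = c(0, 0, 0))
  km <- km_estimate(rec)
  expect_true(all(km$curve$surv == 1))
  expect_true(is.na(km$median$median))

  one <- km_estimate(data.frame(time = 5, event = 1))
  expect_equal(one$curve$surv[one$curve$time == 5], 0)
  expect_equal(one$median$median, 5)

  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("KM median matches the exponential closed form", {
  set.seed(60)
  lambda <- 0.02
  meds <- replicate(5, {
    t <- rexp(500, rate = lambda)
    cens <- runif(500, 100, 300)
    rec <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
    km_estimate(rec)$median$median
  })
  expect_equal(mean(meds), log(2) / lambda, tolerance = 0.1)
})

test_that("RMST equals tau without events and the exponential area with", {
  rec <- data.frame(time = rep(80, 12), event = 0)
  r <- rmst(rec, tau = 36)
  expect_equal(r$rmst, 36)
  expect_equal(r$se, 0)

  set.seed(61)
  lambda <- 0.03
  t <- rexp(2000, rate = lambda)
  rec2 <- data.frame(time = t, event = 1)
  for (tau in c(36, 60)) {
    r2 <- rmst(rec2, tau = tau)
    expect_equal(r2$rmst, (1 - exp(-lambda * tau)) / lambda, tolerance = 0.04)
    # closed form inside the 95% CI
    expect_gt((1 - exp(-lambda * tau)) / lambda, r2$lcl)
    expect_lt((1 - exp(-lambda * tau)) / lambda, r2$ucl)
  }

  # monotone in tau and bounded by tau
  r36 <- rmst(rec2, 36); r60 <- rmst(rec2, 60)
  expect_lte(r36$rmst, 36)
  expect_lte(r36$rmst, r60$rmst)

  # two groups: difference row with a normal-approximation P
  set.seed(62)
  g <- simulate_ph_cohort(300, hr = 3)
  rd <- rmst(g, 36, group = "group")
  expect_equal(rd$group, c("0", "1", "diff"))
  expect_false(is.na(rd$p[3]))
  expect_lt(rd$p[3], 0.05)

  expect_error(rmst(g[0, ], 36), "empty")
  expect_warning(rmst(data.frame(time = c(10, 12), event = c(1, 0)), 36),
                 "truncating")
})

test_that("log-rank is exact on clones, calibrated under the null, powered", {
  base <- data.frame(time = c(5, 8, 12, 20, 33), event = c(1, 0, 1, 1, 0))
  clones <- rbind(cbind(base, group = "A"), cbind(base, group = "B"))
  lr <- logrank(clones)
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-10)

  set.seed(63)
  ps <- replicate(400, {
    rec <- simulate_ph_cohort(60, hr = 1)
    logrank(rec)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  set.seed(64)
  strong <- simulate_ph_cohort(200, hr = 5, prevalence = 0.5)
  expect_lt(logrank(strong)$p, 0.001)

  expect_error(logrank(cbind(base, group = "A")), "two")
})

test_that("Cox recovers a known hazard ratio and rejects degeneracy", {
  set.seed(65)
  rec <- simulate_ph_cohort(1000, hr = 2.2)
  fit <- suppressWarnings(cox_hr(rec, "grp"))
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.9)
  expect_true(fit$lcl < 2.2 && fit$ucl > 2.2)

  # null covariate: CI covers 1
  set.seed(66)
  rec0 <- simulate_ph_cohort(400, hr = 1)
  f0 <- cox_hr(rec0, "grp")
  expect_true(f0$lcl < 1 && f0$ucl > 1)

  rec$grp2 <- rec$grp
  expect_error(cox_hr(rec, c("grp", "grp2")), "collinear")
  few <- data.frame(time = c(3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25,
                             27, 29, 31, 33),
                    event = c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0),
                    grp = rep(0:1, 8))
  expect_warning(cox_hr(few, "grp"), "events")
})
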