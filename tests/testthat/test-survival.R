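test_that("outcome derivation applies the censoring rules literally", {
  rec <- data.frame(
    patient_id = c("a", "b", "c"),
    source = "rwd", regimen = "Rd",
    followup_months = c(10, 6, 50), event = c(1L, 0L, 1L),
    censor_reason = c("none", "discontinued", "none"),
    discont_months = c(NA, 6, NA),
    itt_months = c(10, 20, 50), itt_event = c(1L, 0L, 1L),
    itt_censor_reason = c("none", "lost", "none"))
  on_trt <- derive_outcome(rec, outcome_spec("on_treatment", 48.5))
  expect_equal(on_trt$time, c(10, 6, 48.5))
  expect_equal(on_trt$event, c(1L, 0L, 0L))        # event past the cap censored
  itt <- derive_outcome(rec, outcome_spec("itt", 48.5))
  expect_equal(itt$time, c(10, 20, 48.5))          # discontinuation ignored
  expect_equal(itt$event, c(1L, 0L, 0L))
  bad <- rec; bad$followup_months[1] <- 0
  expect_error(derive_outcome(bad), "non-positive")
})

test_that("raising the cap beyond the largest time changes nothing", {
  rec <- simulate_cohorts(small_config(seed = 61))
  a <- derive_outcome(rec, outcome_spec("on_treatment", 48.5))
  b <- derive_outcome(rec, outcome_spec("on_treatment", 1e6))
  expect_equal(a$time, b$time)
  expect_equal(a$event, b$event)
})

test_that("the four-subject toy has partial-likelihood maximum exp(beta) = sqrt(2)", {
  d <- toy_sqrt2()
  est <- fit_cox(d, "A", "B")
  expect_equal(est$log_hr, log(sqrt(2)), tolerance = 1e-6)
  expect_equal(est$hr, sqrt(2), tolerance = 1e-6)
  # independent verification by grid search over the hand-written likelihood
  beta_grid <- grid_cox(d$time, d$event, as.numeric(d$regimen == "A"))
  expect_equal(beta_grid, log(sqrt(2)), tolerance = 1e-3)
})

test_that("fit_cox agrees with the grid-search oracle on small datasets", {
  set.seed(63)
  for (r in 1:12) {
    n <- sample(4:8, 1)
    d <- data.frame(regimen = sample(rep(c("A", "B"), length.out = n)),
                    time = round(rexp(n, 0.2), 3) + 0.01,
                    event = rbinom(n, 1, 0.8))
    w <- if (r %% 2 == 0) runif(n, 0.5, 2) else rep(1, n)
    x <- as.numeric(d$regimen == "A")
    if (sum(d$event[x == 1]) == 0 || sum(d$event[x == 0]) == 0) next
    beta_grid <- grid_cox(d$time, d$event, x, w)
    if (abs(beta_grid) > 4.5) next                  # near-boundary: skip draw
    est <- fit_cox(d, "A", "B", weights = w)
    expect_equal(est$log_hr, beta_grid, tolerance = 1e-3)
  }
})

test_that("unit weights equal the unweighted fit; constant weights match too", {
  set.seed(65)
  n <- 120
  d <- data.frame(regimen = rep(c("A", "B"), each = n / 2),
                  time = rexp(n, 0.1), event = rbinom(n, 1, 0.7))
  f0 <- fit_cox(d, "A", "B")
  f1 <- fit_cox(d, "A", "B", weights = rep(1, n))
  expect_equal(f1$log_hr, f0$log_hr, tolerance = 1e-8)
  expect_equal(f1$se, f0$se, tolerance = 1e-8)
  # doubled weights leave the point estimate unchanged
  f2 <- fit_cox(d, "A", "B", weights = rep(2, n))
  expect_equal(f2$log_hr, f0$log_hr, tolerance = 1e-8)
})

test_that("the hazard ratio is invariant to rescaling time", {
  set.seed(67)
  n <- 150
  d <- data.frame(regimen = rep(c("A", "B"), each = n / 2),
                  time = rexp(n, 0.1), event = rbinom(n, 1, 0.8))
  f1 <- fit_cox(d, "A", "B")
  d2 <- d; d2$time <- d2$time * 12
  f2 <- fit_cox(d2, "A", "B")
  expect_equal(f2$log_hr, f1$log_hr, tolerance = 1e-8)
  expect_equal(f2$se, f1$se, tolerance = 1e-8)
})

test_that("monotone-likelihood situations are signalled, not estimated", {
  d <- toy_sqrt2()
  d$regimen <- "A"                                  # constant treatment
  expect_error(fit_cox(d, "A", "B"), "monotone")
  d2 <- data.frame(regimen = rep(c("A", "B"), each = 4),
                   time = c(1, 2, 3, 4, 5, 6, 7, 8),
                   event = c(1, 1, 1, 1, 0, 0, 0, 0))  # no events in arm B
  expect_error(fit_cox(d2, "A", "B"), "monotone")
})

test_that("proportional-hazards p-values are calibrated under the null", {
  set.seed(69)
  ps <- vapply(1:200, function(r) {
    n <- 160
    treat <- rep(0:1, each = n / 2)
    t_ev <- rexp(n, 0.03 * exp(log(0.7) * treat))
    cens <- pmin(rexp(n, 0.015), 48.5)
    d <- data.frame(regimen = ifelse(treat == 1, "A", "B"),
                    time = pmin(t_ev, cens),
                    event = as.integer(t_ev <= cens))
    ph_check(d, "A", "B")$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("crossing hazards are detected far above the nominal rate", {
  set.seed(71)
  rej <- mean(vapply(1:40, function(r) {
    n <- 300
    treat <- rep(0:1, each = n / 2)
    # opposite effects before/after t0 = 10: strong PH violation
    u <- runif(n)
    h0 <- 0.05
    hr1 <- exp(1.0 * treat); hr2 <- exp(-1.0 * treat)
    t1 <- -log(u) / (h0 * hr1)
    t_ev <- ifelse(t1 <= 10, t1, 10 + (t1 - 10) * hr1 / hr2)
    cens <- rep(48.5, n)
    d <- data.frame(regimen = ifelse(treat == 1, "A", "B"),
                    time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
    ph_check(d, "A", "B")$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.5)
})

test_that("single-event data cannot support a proportional-hazards test", {
  d <- data.frame(regimen = c("A", "B", "A", "B"),
                  time = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L))
  d$event[2] <- 0L                  # a single event cannot support the test
  expect_error(ph_check(d, "A", "B"), "monotone likelihood|too few events")
})

test_that("subgroup interaction recovers a constructed effect difference", {
  set.seed(73)
  n <- 6000
  sub <- rbinom(n, 1, 0.5)
  treat <- rbinom(n, 1, 0.5)
  b <- -0.6 + 0.5 * sub                       # log HR differs by 0.5
  t_ev <- rexp(n, 0.04 * exp(b * treat))
  cens <- pmin(rexp(n, 0.01), 48.5)
  d <- data.frame(regimen = ifelse(treat == 1, "A", "B"),
                  time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
  res <- subgroup_interaction(d, "A", "B", sub)
  diff <- res$strata$subgroup_true$log_hr - res$strata$subgroup_false$log_hr
  se_diff <- sqrt(res$strata$subgroup_true$se^2 +
                    res$strata$subgroup_false$se^2)
  expect_lt(abs(diff - 0.5), 3 * se_diff)
  expect_lt(res$interaction_p, 0.05)
})

test_that("null interactions give matching strata and a large p-value", {
  set.seed(75)
  n <- 4000
  sub <- rbinom(n, 1, 0.5)
  treat <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.04 * exp(-0.5 * treat))
  d <- data.frame(regimen = ifelse(treat == 1, "A", "B"),
                  time = pmin(t_ev, 48.5), event = as.integer(t_ev <= 48.5))
  res <- subgroup_interaction(d, "A", "B", sub)
  diff <- res$strata$subgroup_true$log_hr - res$strata$subgroup_false$log_hr
  expect_lt(abs(diff),
            3 * sqrt(res$strata$subgroup_true$se^2 +
                       res$strata$subgroup_false$se^2))
})

test_that("empty or event-free strata are signalled", {
  d <- toy_sqrt2()
  expect_error(subgroup_interaction(d, "A", "B", rep(0L, 4)), "empty stratum")
  expect_error(subgroup_interaction(d, "A", "B", c(1L, 1L, 0L, 0L)),
               "zero events")
})
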