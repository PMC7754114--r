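test_that("simulation is byte-identical given the same config and seed", {
  cfg <- small_config(seed = 7)
  r1 <- simulate_cohorts(cfg)
  r2 <- simulate_cohorts(cfg)
  expect_identical(r1, r2)
  r3 <- simulate_cohorts(small_config(seed = 8))
  expect_false(identical(r1$followup_months, r3$followup_months))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_trial_per_arm = 0), "n_trial_per_arm")
  expect_error(simulation_config(admin_cap_months = -1), "admin_cap")
  expect_error(simulation_config(
    missing_rates = list(rwd = c(iss = 1.0))), "missing rates")
  expect_error(simulation_config(
    n_rwd_per_regimen = c(VRd = 100, Rd = 100, Zz = 100)), "Zz")
  # anchor log HR forced to zero by construction
  cfg <- simulation_config(true_log_hr = c(DRd = -0.5, VRd = -0.2,
                                           Vd = 0.1, Rd = 99))
  expect_equal(unname(cfg$true_log_hr["Rd"]), 0)
})

test_that("record-level invariants hold: censoring accounting and bounds", {
  rec <- simulate_cohorts(small_config(seed = 3))
  # event implies no censoring reason; censored records account for n - events
  expect_true(all(rec$censor_reason[rec$event == 1] == "none"))
  expect_equal(sum(rec$censor_reason != "none"), nrow(rec) - sum(rec$event))
  expect_true(all(rec$followup_months > 0))
  expect_true(all(rec$followup_months <= 48.5 + 1e-12))
  expect_true(all(rec$regimen[rec$source == "trial"] %in% c("DRd", "Rd")))
  expect_true(all(rec$regimen[rec$source == "rwd"] %in% c("VRd", "Rd", "Vd")))
  expect_true(all(is.na(rec$clinic_id[rec$source == "trial"])))
  expect_true(all(!is.na(rec$clinic_id[rec$source == "rwd"])))
  # trial randomization is exactly 1:1
  expect_equal(unname(table(rec$regimen[rec$source == "trial"])),
               c(150L, 150L), ignore_attr = TRUE)
})

test_that("null config gives coinciding survival across arms", {
  cfg <- simulation_config(
    n_trial_per_arm = 800, n_rwd_per_regimen = c(VRd = 800, Rd = 800, Vd = 800),
    true_log_hr = c(DRd = 0, VRd = 0, Vd = 0),
    prognostic_shift = list(), assignment_coefs = list(),
    dropout_rate = c(trial = 0, rwd = 0),
    discontinuation_rate = list(trial = c(DRd = 0, Rd = 0),
                                rwd = c(VRd = 0, Rd = 0, Vd = 0)),
    missing_rates = list(), seed = 21)
  rec <- simulate_cohorts(cfg)
  d <- derive_outcome(rec, outcome_spec())
  for (src in c("trial", "rwd")) {
    ds <- d[d$source == src, ]
    for (trt in setdiff(unique(ds$regimen), "Rd")) {
      est <- fit_cox(ds, trt, "Rd")
      expect_lt(abs(est$log_hr), 3 * est$se)   # within Monte-Carlo error of 0
    }
  }
})

test_that("unweighted Cox recovers a configured trial hazard ratio of 0.54", {
  cfg <- simulation_config(
    n_trial_per_arm = 5000, n_rwd_per_regimen = c(Rd = 10),
    prognostic_shift = list(), assignment_coefs = list(),
    discontinuation_rate = list(trial = c(DRd = 0, Rd = 0), rwd = c(Rd = 0)),
    missing_rates = list(), seed = 13)
  rec <- simulate_cohorts(cfg)
  d <- derive_outcome(rec[rec$source == "trial", ], outcome_spec())
  est <- fit_cox(d, "DRd", "Rd")
  expect_lt(abs(est$log_hr - log(0.54)), 3 * est$se)
})

test_that("raising a regimen's true log hazard ratio raises its estimate", {
  base <- list(n_trial_per_arm = 50, n_rwd_per_regimen = c(VRd = 1500, Rd = 1500),
               prognostic_shift = list(), assignment_coefs = list(),
               missing_rates = list(), seed = 17)
  lo <- do.call(simulation_config, c(base, list(
    true_log_hr = c(DRd = 0, VRd = -0.4))))
  hi <- do.call(simulation_config, c(base, list(
    true_log_hr = c(DRd = 0, VRd = 0.4))))
  est <- function(cfg) {
    d <- derive_outcome(simulate_cohorts(cfg), outcome_spec())
    fit_cox(d[d$source == "rwd", ], "VRd", "Rd")$log_hr
  }
  expect_lt(est(lo), est(hi))
})

test_that("missingness hits target rates and leaves rate-0 covariates intact", {
  cfg <- simulation_config(n_trial_per_arm = 50,
                           n_rwd_per_regimen = c(VRd = 5000, Rd = 5000),
                           missing_rates = list(), seed = 5)
  rec <- simulate_cohorts(cfg)
  expect_identical(apply_missingness(rec, c(iss = 0, ecog = 0), seed = 1), rec)
  # MCAR at the 47% ISS-stage rate, n = 10000
  out <- apply_missingness(rec[rec$source == "rwd", ], c(iss = 0.47),
                           mechanism = "MCAR", seed = 2)
  expect_lt(abs(mean(is.na(out$iss)) - 0.47), 0.01)
  expect_error(apply_missingness(rec, c(bogus = 0.2), seed = 1), "bogus")
})

test_that("MAR missingness depends on age with the configured slope sign", {
  cfg <- simulation_config(n_trial_per_arm = 50,
                           n_rwd_per_regimen = c(VRd = 4000, Rd = 4000),
                           missing_rates = list(), seed = 6)
  rwd <- simulate_cohorts(cfg)
  rwd <- rwd[rwd$source == "rwd", ]
  out <- apply_missingness(rwd, c(ecog = 0.40), mechanism = "MAR", seed = 3,
                           mar_coefs = c(age = 0.6, sexmale = 0.3))
  fit <- glm(is.na(out$ecog) ~ out$age, family = binomial())
  expect_gt(coef(fit)[2], 0)                       # positive age slope recovered
  expect_equal(mean(is.na(out$ecog)), 0.40, tolerance = 0.02)
  expect_error(apply_missingness(rwd, c(age = 0.1), mechanism = "MAR"),
               "cannot be made missing")
})

test_that("intent-to-treat columns extend on-treatment follow-up", {
  rec <- simulate_cohorts(small_config(seed = 9))
  disc <- rec$censor_reason == "discontinued"
  expect_gt(sum(disc), 0)
  expect_true(all(rec$itt_months[disc] >= rec$followup_months[disc]))
  expect_true(all(rec$itt_censor_reason %in% c("none", "lost", "admin")))
  # where no discontinuation occurred the two conventions coincide
  expect_equal(rec$followup_months[!disc], rec$itt_months[!disc])
})
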