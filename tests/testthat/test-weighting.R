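test_that("membership model recovers the analytic 2x2 logistic solution", {
  # single binary covariate: prevalence 0.6 in trial, 0.4 in the group;
  # the exact coefficient is log(odds(trial | x=1) / odds(trial | x=0))
  trial <- data.frame(age = rep(c(1, 0), c(60, 40)))
  group <- data.frame(age = rep(c(1, 0), c(40, 60)), regimen = "G")
  mm <- fit_membership_model(trial, group, covariates = "age")
  expect_equal(unname(coef(mm$model)["age"]),
               log((60 / 40) / (40 / 60)), tolerance = 1e-6)
  expect_true(all(mm$prob_group > 0 & mm$prob_group < 1))
})

test_that("identical populations give near-zero coefficients and flat weights", {
  set.seed(51)
  cfg <- simulation_config(n_trial_per_arm = 600,
                           n_rwd_per_regimen = c(VRd = 1200, Rd = 10),
                           prognostic_shift = list(), assignment_coefs = list(),
                           missing_rates = list(), seed = 51)
  rec <- simulate_cohorts(cfg)
  trial <- rec[rec$source == "trial", ]
  grp <- rec[rec$source == "rwd" & rec$regimen == "VRd", ]
  mm <- fit_membership_model(trial, grp)
  ws <- odds_weights(mm)
  expect_gt(ws$ess / ws$n, 0.9)     # near-constant weights
  # probabilities hover near the trial prevalence of the pooled sample
  expect_equal(mean(mm$prob_group), nrow(trial) / (nrow(trial) + nrow(grp)),
               tolerance = 0.05)
})

test_that("odds weights match the hand-worked two-patient example", {
  ws <- odds_weights(c(0.5, 0.8))
  expect_equal(ws$weights, c(0.4, 1.6))           # raw odds {1, 4} normalized
  expect_equal(ws$ess, 4 / (0.16 + 2.56))         # = 1.4706
  expect_equal(sum(ws$weights), ws$n)
  all_half <- odds_weights(rep(0.5, 10))
  expect_equal(all_half$weights, rep(1, 10))
  expect_equal(all_half$ess, 10)
  expect_error(odds_weights(c(0.5, 1)), "strictly")
})

test_that("effective sample size is bounded by n with equality iff constant", {
  set.seed(53)
  for (r in 1:20) {
    p <- runif(sample(5:50, 1), 0.05, 0.95)
    ws <- odds_weights(p)
    expect_lte(ws$ess, ws$n + 1e-9)
    if (length(unique(round(ws$weights, 12))) > 1) expect_lt(ws$ess, ws$n)
  }
})

test_that("standardized differences match the defining formulas", {
  set.seed(55)
  x <- rnorm(500)
  expect_equal(standardized_difference(x, x), 0)
  # means 1 vs 0, both sds 1 -> SMD 1 (computed on exact moments via scale)
  a <- as.numeric(scale(rnorm(400))) + 1
  b <- as.numeric(scale(rnorm(400)))
  expect_equal(standardized_difference(a, b), 1, tolerance = 1e-9)
  # binary variant
  pa <- rep(c(1, 0), c(60, 40)); pb <- rep(c(1, 0), c(40, 60))
  expect_equal(standardized_difference(pa, pb, binary = TRUE),
               0.2 / sqrt(0.24), tolerance = 1e-12)
  # sign antisymmetry, with and without weights
  w <- runif(400, 0.5, 2)
  expect_equal(standardized_difference(a, b, w_group = w),
               -standardized_difference(b, a, w_target = w), tolerance = 1e-12)
  expect_error(standardized_difference(rep(1, 5), rep(1, 5), binary = TRUE),
               "zero pooled variance")
})

test_that("balance report flags exactly the shifted covariate pre-weighting", {
  cfg <- simulation_config(
    n_trial_per_arm = 1500, n_rwd_per_regimen = c(VRd = 3000, Rd = 10),
    prognostic_shift = list(age = 2.0),     # ~0.38 SD shift in age only
    assignment_coefs = list(), missing_rates = list(), seed = 57)
  rec <- simulate_cohorts(cfg)
  trial <- rec[rec$source == "trial", ]
  rwd <- rec[rec$source == "rwd", ]
  unit <- list(VRd = odds_weights(rep(0.5, sum(rwd$regimen == "VRd")),
                                  group = "VRd"))
  rep_unw <- balance_report(trial, rwd, unit)
  flagged <- rep_unw$flagged$covariate
  expect_true("age" %in% flagged)
  expect_false(any(c("sexmale", "raceblack", "cyto_riskhigh") %in% flagged))
})

test_that("threshold logic flags covariates consistently", {
  tab_zero <- data.frame(x = rnorm(200))
  trial <- data.frame(age = rnorm(300, 74, 5), regimen = "T")
  rwd <- data.frame(age = rnorm(300, 74, 5), regimen = "G")
  ws <- list(G = odds_weights(rep(0.5, 300), group = "G"))
  br <- balance_report(trial, rwd, ws, covariates = "age", threshold = 1e9)
  expect_equal(nrow(br$flagged), 0)
  br2 <- balance_report(trial, rwd, ws, covariates = "age", threshold = 0)
  expect_equal(nrow(br2$flagged), nrow(br2$table))
})

test_that("odds weighting reduces the worst standardized difference", {
  # property over many simulated configs with moderate source shifts
  worse <- 0
  for (s in 1:50) {
    set.seed(400 + s)
    sh <- list(age = runif(1, -2, 2),
               crcl = runif(1, -0.1, 0.1),
               ecog = c(-1, runif(1, 0, 0.08), runif(1, 0, 0.06)),
               iss = c(-1, runif(1, 0, 0.08), runif(1, 0, 0.06)))
    sh$ecog[1] <- -sum(sh$ecog[-1]); sh$iss[1] <- -sum(sh$iss[-1])
    cfg <- simulation_config(
      n_trial_per_arm = 300, n_rwd_per_regimen = c(VRd = 400, Rd = 10),
      prognostic_shift = sh, assignment_coefs = list(),
      missing_rates = list(), seed = 400 + s)
    rec <- simulate_cohorts(cfg)
    trial <- rec[rec$source == "trial", ]
    rwd <- rec[rec$source == "rwd" & rec$regimen == "VRd", ]
    ws <- odds_weights(fit_membership_model(trial, rwd))
    br <- balance_report(trial, rec[rec$source == "rwd", ], list(VRd = ws))
    tab <- br$table
    if (max(abs(tab$smd_weighted)) >= max(abs(tab$smd_unweighted)) &&
        max(abs(tab$smd_unweighted)) > 0.05) worse <- worse + 1
  }
  expect_lte(worse, 2)   # allow rare sampling flukes out of 50 configs
})

test_that("separation is reported with the offending covariate named", {
  trial <- data.frame(age = c(rep(1, 30), rep(0, 0)), regimen = "T")
  group <- data.frame(age = rep(0, 30), regimen = "G")
  expect_error(fit_membership_model(trial, group, covariates = "age"),
               "separation.*age")
})
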