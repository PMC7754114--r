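#' Default baseline-covariate distributions
#'
#' Marginal distributions for the eight baseline covariates carried by both
#' cohorts, parameterized to match the weighted baseline table of the study
#' population the generator emulates (transplant-ineligible newly diagnosed
#' multiple myeloma, age >= 65): age ~ N(74.3, 5.3); 48% female; 3.5% Black;
#' ISS stage I/II/III = 28/43/29%; 14% high cytogenetic risk; ECOG 0/1/2 =
#' 35/49/16%; creatinine clearance lognormal with ~41% of patients <= 60
#' mL/min; months from diagnosis to first-line therapy gamma with mean 1.4.
#' Categorical levels are ordered reference-first (the reference level is
#' omitted when covariates are expanded to indicators).
#'
#' @return Named list of per-covariate distribution descriptors, each a list
#'   with a `type` (`"normal"`, `"lognormal"`, `"gamma"` or `"categorical"`)
#'   and its parameters.
#' @export
default_covariate_spec <- function() {
  list(
    age        = list(type = "normal",      mean = 74.3, sd = 5.3),
    sex        = list(type = "categorical", levels = c("female", "male"),
                      probs = c(0.48, 0.52)),
    race       = list(type = "categorical", levels = c("other", "black"),
                      probs = c(0.965, 0.035)),
    iss        = list(type = "categorical", levels = c("I", "II", "III"),
                      probs = c(0.28, 0.43, 0.29)),
    cyto_risk  = list(type = "categorical", levels = c("standard", "high"),
                      probs = c(0.86, 0.14)),
    ecog       = list(type = "categorical", levels = c("0", "1", "2"),
                      probs = c(0.35, 0.49, 0.16)),
    crcl       = list(type = "lognormal",   meanlog = log(64), sdlog = 0.35),
    dx_to_lot1 = list(type = "gamma",       mean = 1.4, sd = 1.8)
  )
}

#' Generative specification for paired trial and real-world cohorts
#'
#' Bundles everything needed to simulate a randomized trial cohort
#' (experimental regimen vs anchor, 1:1) and a confounded real-world cohort
#' sharing the anchor regimen: covariate distributions, true regimen effects
#' on the log-hazard scale, optional prognostic and effect-modifier
#' coefficients, a Weibull baseline event-time law, competing censoring
#' processes (administrative cap, loss to follow-up, non-progression
#' treatment discontinuation), covariate shifts and confounded treatment
#' assignment for the real-world source, and per-covariate missingness.
#'
#' Defaults emulate the emulated study's conditions: a 48.5-month
#' administrative cap, real-world discontinuation hazards ordered
#' triplet > doublet, and real-world missingness of 8% (race), 20% (labs),
#' 30% (cytogenetic risk), 40% (ECOG) and 47% (ISS stage), with 13%
#' missing cytogenetic risk in the trial.
#'
#' @param n_trial_per_arm Patients per randomized trial arm.
#' @param n_rwd_per_regimen Named vector of expected real-world group sizes;
#'   names define the real-world regimen set (must include the anchor for an
#'   anchored comparison).
#' @param anchor,experimental Regimen labels; the trial randomizes
#'   `experimental` vs `anchor`.
#' @param covariate_spec Per-covariate distributions, see
#'   [default_covariate_spec()].
#' @param true_log_hr Named vector of true log hazard ratios vs the anchor;
#'   the anchor itself is forced to 0.
#' @param effect_modifier_coefs Named vector of treatment-by-covariate
#'   interaction coefficients on the log-hazard scale (design-column names,
#'   e.g. `age`, `ecog2`); covariates are centered at their trial means so
#'   `true_log_hr` stays the trial-population average effect.
#' @param prognostic_coefs Named vector of covariate main effects on the
#'   log-hazard scale (design-column names).
#' @param prognostic_shift Named list of source-level covariate shifts for
#'   the real-world cohort: additive mean shift for `normal`/`gamma`
#'   covariates, additive log-scale shift for `lognormal`, and a vector of
#'   probability deltas (summing to 0) for categorical covariates.
#' @param assignment_coefs Named list (by real-world regimen) of multinomial
#'   log-odds coefficients on centered design columns; drives confounding by
#'   indication.  Regimens without an entry act as reference.
#' @param baseline_hazard Named vector `c(scale=, shape=)` of the Weibull
#'   event-time law in months (shape 1 = exponential).
#' @param admin_cap_months Administrative censoring cap (months).
#' @param dropout_rate Per-month loss-to-follow-up hazard per source,
#'   `c(trial=, rwd=)`.
#' @param discontinuation_rate List by source of named per-regimen per-month
#'   hazards of non-progression treatment discontinuation.
#' @param missing_rates List by source of named per-covariate missingness
#'   fractions in `[0, 1)`.
#' @param missing_mechanism `"MAR"` (default; missingness depends on the
#'   always-observed age and sex) or `"MCAR"`.
#' @param event_detection_prob Per-source probability that a progression
#'   event is ascertained (1 = perfect ascertainment; no published value
#'   exists for the real-world source, so the default is 1).
#' @param n_clinics Number of real-world clinics to spread patients over.
#' @param seed Integer seed; simulation is deterministic given the config.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    n_trial_per_arm = 358,
    n_rwd_per_regimen = c(VRd = 570, Rd = 432, Vd = 358),
    anchor = "Rd",
    experimental = "DRd",
    covariate_spec = default_covariate_spec(),
    true_log_hr = c(DRd = log(0.54), VRd = log(0.80), Vd = log(1.14)),
    effect_modifier_coefs = numeric(0),
    prognostic_coefs = numeric(0),
    prognostic_shift = list(age = 1.0, crcl = -0.06,
                            ecog = c(-0.06, 0.01, 0.05),
                            iss = c(-0.04, -0.01, 0.05)),
    assignment_coefs = list(VRd = c(age = -0.05, ecog2 = -0.5),
                            Vd  = c(age = 0.02, issIII = 0.3)),
    baseline_hazard = c(scale = 46, shape = 1),
    admin_cap_months = 48.5,
    dropout_rate = c(trial = 0.002, rwd = 0.012),
    discontinuation_rate = list(trial = c(DRd = 0.006, Rd = 0.008),
                                rwd = c(VRd = 0.055, Rd = 0.035, Vd = 0.045)),
    missing_rates = list(trial = c(cyto_risk = 0.13),
                         rwd = c(race = 0.08, crcl = 0.20, cyto_risk = 0.30,
                                 ecog = 0.40, iss = 0.47)),
    missing_mechanism = c("MAR", "MCAR"),
    event_detection_prob = c(trial = 1, rwd = 1),
    n_clinics = 40,
    seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_trial_per_arm = as.integer(n_trial_per_arm),
    n_rwd_per_regimen = n_rwd_per_regimen,
    anchor = anchor, experimental = experimental,
    covariate_spec = covariate_spec,
    true_log_hr = true_log_hr,
    effect_modifier_coefs = effect_modifier_coefs,
    prognostic_coefs = prognostic_coefs,
    prognostic_shift = prognostic_shift,
    assignment_coefs = assignment_coefs,
    baseline_hazard = baseline_hazard,
    admin_cap_months = admin_cap_months,
    dropout_rate = dropout_rate,
    discontinuation_rate = discontinuation_rate,
    missing_rates = missing_rates,
    missing_mechanism = missing_mechanism,
    event_detection_prob = event_detection_prob,
    n_clinics = as.integer(n_clinics),
    seed = as.integer(seed)
  )
  # anchor is the reference: force log HR 0 by construction
  cfg$true_log_hr[anchor] <- 0
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_trial_per_arm <= 0L) stop("n_trial_per_arm must be > 0")
  if (length(cfg$n_rwd_per_regimen) == 0 || any(cfg$n_rwd_per_regimen <= 0))
    stop("n_rwd_per_regimen must be positive counts")
  if (is.null(names(cfg$n_rwd_per_regimen)))
    stop("n_rwd_per_regimen must be named by regimen")
  if (cfg$admin_cap_months <= 0) stop("admin_cap_months must be > 0")
  if (any(unlist(cfg$dropout_rate) < 0) ||
      any(unlist(cfg$discontinuation_rate) < 0))
    stop("censoring-process rates must be >= 0")
  mr <- unlist(cfg$missing_rates)
  if (length(mr) && (any(mr < 0) || any(mr >= 1)))
    stop("missing rates must lie in [0, 1)")
  rwd_regs <- names(cfg$n_rwd_per_regimen)
  trial_has <- cfg$n_trial_per_arm > 0      # trial always carries the anchor arm
  if (!trial_has && !(cfg$anchor %in% rwd_regs))
    stop("anchor regimen absent from both sources")
  unknown <- setdiff(setdiff(rwd_regs, cfg$anchor), names(cfg$true_log_hr))
  if (length(unknown))
    stop("true_log_hr missing for regimen(s): ", paste(unknown, collapse = ", "))
  bh <- cfg$baseline_hazard
  if (!all(c("scale", "shape") %in% names(bh)) || any(bh <= 0))
    stop("baseline_hazard needs positive 'scale' and 'shape'")
  ed <- cfg$event_detection_prob
  if (any(ed <= 0) || any(ed > 1))
    stop("event_detection_prob must lie in (0, 1]")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Cohort simulation config\n")
  cat(sprintf("  trial: %d/arm (%s vs %s); real-world: %s\n",
              x$n_trial_per_arm, x$experimental, x$anchor,
              paste(sprintf("%s=%d", names(x$n_rwd_per_regimen),
                            x$n_rwd_per_regimen), collapse = ", ")))
  cat(sprintf("  true HR vs %s: %s\n", x$anchor,
              paste(sprintf("%s=%.2f", names(x$true_log_hr),
                            exp(x$true_log_hr)), collapse = ", ")))
  cat(sprintf("  Weibull(scale=%g mo, shape=%g), admin cap %.1f mo, seed %d\n",
              x$baseline_hazard[["scale"]], x$baseline_hazard[["shape"]],
              x$admin_cap_months, x$seed))
  invisible(x)
}

# --- covariate machinery ----------------------------------------------------

covariate_names <- function(spec) names(spec)

# draw n rows of baseline covariates; `shift` optionally perturbs the
# real-world source (see simulation_config docs for per-type semantics)
draw_covariates <- function(n, spec, shift = NULL) {
  out <- lapply(names(spec), function(v) {
    s <- spec[[v]]
    sh <- shift[[v]]
    switch(s$type,
      normal = stats::rnorm(n, s$mean + (sh %||% 0), s$sd),
      lognormal = stats::rlnorm(n, s$meanlog + (sh %||% 0), s$sdlog),
      gamma = {
        m <- s$mean + (sh %||% 0)
        if (m <= 0) stop("gamma mean shifted below zero for ", v)
        th <- s$sd^2 / m
        stats::rgamma(n, shape = m / th, scale = th)
      },
      categorical = {
        p <- s$probs
        if (!is.null(sh)) {
          if (length(sh) != length(p))
            stop("categorical shift for ", v, " must match number of levels")
          p <- pmax(p + sh, 1e-3); p <- p / sum(p)
        }
        factor(sample(s$levels, n, replace = TRUE, prob = p),
               levels = s$levels)
      },
      stop("unknown covariate type: ", s$type))
  })
  names(out) <- names(spec)
  as.data.frame(out, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand covariates to a numeric design matrix
#'
#' Continuous covariates pass through; factors become indicator columns for
#' each non-reference level named `<covariate><level>` (e.g. `ecog2`,
#' `issIII`); the derived name `crcl_le60` yields the creatinine-clearance
#' <= 60 mL/min indicator used in the baseline table.
#'
#' @param records Patient data frame.
#' @param covariates Covariate (or derived-indicator) names to expand.
#' @return Numeric matrix, one row per record.
#' @export
covariate_design <- function(records, covariates) {
  cols <- lapply(covariates, function(v) {
    if (v == "crcl_le60") {
      m <- matrix(as.numeric(records$crcl <= 60), ncol = 1)
      colnames(m) <- "crcl_le60"
      return(m)
    }
    if (!v %in% names(records)) stop("unknown covariate: ", v)
    x <- records[[v]]
    if (is.factor(x)) {
      lv <- levels(x)
      m <- sapply(lv[-1], function(l) as.numeric(x == l))
      m <- matrix(m, nrow = length(x))
      colnames(m) <- paste0(v, lv[-1])
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- v
      m
    }
  })
  do.call(cbind, cols)
}

# expected value of every design column under the trial covariate spec,
# used to center linear predictors
spec_design_means <- function(spec) {
  means <- list()
  for (v in names(spec)) {
    s <- spec[[v]]
    if (s$type == "categorical") {
      mm <- s$probs[-1]
      names(mm) <- paste0(v, s$levels[-1])
      means <- c(means, as.list(mm))
    } else {
      means[[v]] <- switch(s$type,
        normal = s$mean,
        lognormal = exp(s$meanlog + s$sdlog^2 / 2),
        gamma = s$mean)
    }
  }
  # derived indicator
  if (!is.null(spec$crcl))
    means$crcl_le60 <- stats::plnorm(60, spec$crcl$meanlog, spec$crcl$sdlog)
  unlist(means)
}

# linear predictor from named coefficients over centered design columns
lp_from_coefs <- function(records, coefs, spec) {
  if (length(coefs) == 0) return(rep(0, nrow(records)))
  X <- covariate_design(records, c(names(spec), "crcl_le60"))
  miss <- setdiff(names(coefs), colnames(X))
  if (length(miss))
    stop("coefficient(s) reference unknown design column(s): ",
         paste(miss, collapse = ", "))
  mu <- spec_design_means(spec)
  Xc <- sweep(X[, names(coefs), drop = FALSE], 2, mu[names(coefs)], "-")
  as.numeric(Xc %*% coefs)
}

# --- cohort simulation ------------------------------------------------------

#' Simulate paired trial and real-world survival cohorts
#'
#' Generates one randomized trial cohort (experimental vs anchor, exact 1:1)
#' and one real-world cohort whose regimen assignment follows a multinomial
#' logistic model on (centered) baseline covariates and whose covariate
#' distributions are offset by the configured source-level shifts.
#' Progression-free survival times follow a Weibull proportional-hazards
#' model with linear predictor
#' `prognostic effects + 1(regimen != anchor) * (log HR(regimen) +
#' effect-modifier interactions)`.  The observed on-treatment follow-up is
#' the minimum of the event time, the administrative cap, an exponential
#' loss-to-follow-up time and an exponential treatment-discontinuation time,
#' with `censor_reason` set to the earliest competing process.  The
#' intent-to-treat observation (discontinuation ignored) is kept alongside in
#' the `itt_*` columns.  Missingness is then applied per the config.
#'
#' @param config A [simulation_config()].
#' @return A data frame of patient records (one row per patient) with
#'   columns: `patient_id`, `source`, `regimen`, `clinic_id`, the baseline
#'   covariates, eligibility flags (`response_assessed`, `transplant_lot1`,
#'   `severe_cardiac`, `other_malignancy`), on-treatment outcome columns
#'   (`followup_months`, `event`, `censor_reason`, `discont_months`) and
#'   intent-to-treat columns (`itt_months`, `itt_event`, `itt_censor_reason`).
#'   The config is attached as attribute `"sim_config"`.
#' @examples
#' cfg <- simulation_config(n_trial_per_arm = 50,
#'                          n_rwd_per_regimen = c(VRd = 50, Rd = 50),
#'                          seed = 7)
#' rec <- simulate_cohorts(cfg)
#' table(rec$source, rec$regimen)
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)
  spec <- config$covariate_spec

  ## trial cohort: 1:1 randomization
  n_t <- 2L * config$n_trial_per_arm
  trial <- draw_covariates(n_t, spec)
  trial$regimen <- sample(rep(c(config$experimental, config$anchor),
                              config$n_trial_per_arm))
  trial$source <- "trial"
  trial$clinic_id <- NA_character_
  trial$response_assessed <- TRUE
  trial$transplant_lot1 <- FALSE
  trial$severe_cardiac <- FALSE
  trial$other_malignancy <- FALSE

  ## real-world cohort: confounded assignment via multinomial logit
  n_r <- sum(config$n_rwd_per_regimen)
  rwd <- draw_covariates(n_r, spec, shift = config$prognostic_shift)
  regs <- names(config$n_rwd_per_regimen)
  shares <- config$n_rwd_per_regimen / n_r
  lp <- sapply(regs, function(r) {
    log(shares[[r]] / shares[[1]]) +
      lp_from_coefs(rwd, config$assignment_coefs[[r]] %||% numeric(0), spec)
  })
  pr <- exp(lp - apply(lp, 1, max))
  pr <- pr / rowSums(pr)
  rwd$regimen <- regs[apply(pr, 1, function(p) sample.int(length(p), 1, prob = p))]
  rwd$source <- "rwd"
  clinic_sizes <- stats::rlnorm(config$n_clinics, 0, 0.7)
  rwd$clinic_id <- sample(sprintf("clinic_%02d", seq_len(config$n_clinics)),
                          n_r, replace = TRUE,
                          prob = clinic_sizes / sum(clinic_sizes))
  rwd$response_assessed <- stats::runif(n_r) < 0.96
  rwd$transplant_lot1 <- stats::runif(n_r) < 0.02
  rwd$severe_cardiac <- stats::runif(n_r) < 0.02
  rwd$other_malignancy <- stats::runif(n_r) < 0.03

  rec <- rbind(trial, rwd)
  rec$patient_id <- sprintf("%s_%05d", rec$source, seq_len(nrow(rec)))

  ## Weibull proportional-hazards event times
  treat <- as.numeric(rec$regimen != config$anchor)
  lp_out <- lp_from_coefs(rec, config$prognostic_coefs, spec) +
    treat * (config$true_log_hr[rec$regimen] +
               lp_from_coefs(rec, config$effect_modifier_coefs, spec))
  sc <- config$baseline_hazard[["scale"]]
  sh <- config$baseline_hazard[["shape"]]
  t_event <- sc * (-log(stats::runif(nrow(rec))) / exp(lp_out))^(1 / sh)
  detect <- config$event_detection_prob[rec$source]
  t_event[stats::runif(nrow(rec)) > detect] <- Inf

  rexp_or_inf <- function(n, rate)
    if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  t_drop <- rep(Inf, nrow(rec))
  t_disc <- rep(Inf, nrow(rec))
  for (src in c("trial", "rwd")) {
    i <- rec$source == src
    t_drop[i] <- rexp_or_inf(sum(i), config$dropout_rate[[src]])
    dr <- config$discontinuation_rate[[src]] %||% numeric(0)
    for (r in unique(rec$regimen[i])) {
      j <- i & rec$regimen == r
      t_disc[j] <- rexp_or_inf(sum(j), dr[[r]] %||% 0)
    }
  }
  cap <- config$admin_cap_months

  ## intent-to-treat observation (discontinuation ignored)
  itt <- pmin(t_event, t_drop, cap)
  rec$itt_months <- itt
  rec$itt_event <- as.integer(t_event <= pmin(t_drop, cap))
  rec$itt_censor_reason <- ifelse(rec$itt_event == 1, "none",
                                  ifelse(t_drop <= cap, "lost", "admin"))
  ## on-treatment observation: discontinuation is an additional censoring
  disc_first <- t_disc < itt
  rec$followup_months <- ifelse(disc_first, t_disc, itt)
  rec$event <- ifelse(disc_first, 0L, rec$itt_event)
  rec$censor_reason <- ifelse(disc_first, "discontinued",
                              rec$itt_censor_reason)
  rec$discont_months <- ifelse(disc_first, t_disc, NA_real_)

  cov_order <- names(spec)
  rec <- rec[, c("patient_id", "source", "regimen", "clinic_id", cov_order,
                 "response_assessed", "transplant_lot1", "severe_cardiac",
                 "other_malignancy", "followup_months", "event",
                 "censor_reason", "discont_months", "itt_months", "itt_event",
                 "itt_censor_reason")]
  rownames(rec) <- NULL

  rec <- apply_missingness(rec, config$missing_rates,
                           mechanism = config$missing_mechanism)
  attr(rec, "sim_config") <- config
  rec
}

#' Delete covariate values under a configured missingness mechanism
#'
#' Sets baseline-covariate cells to `NA` at per-covariate target rates.
#' Under `"MCAR"` each cell is deleted independently; under `"MAR"`
#' (missing-at-random-on-observed) the deletion probability follows a
#' logistic model on the always-observed age and sex, with the intercept
#' solved numerically so the expected missing fraction equals the target
#' rate exactly given the realized covariates.
#'
#' @param records Patient data frame.
#' @param missing_rates Either a named numeric vector of per-covariate rates
#'   applied to all records, or a list with elements `trial` and/or `rwd` of
#'   such vectors applied per source.
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param seed Optional seed (the generator calls this inside its own seeded
#'   stream and leaves it `NULL`).
#' @param mar_coefs Log-odds slopes of the MAR model on standardized age and
#'   the male indicator.
#' @return `records` with the selected cells set to `NA`.
#' @export
apply_missingness <- function(records, missing_rates,
                              mechanism = c("MAR", "MCAR"), seed = NULL,
                              mar_coefs = c(age = 0.6, sexmale = 0.3)) {
  mechanism <- match.arg(mechanism)
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(missing_rates)) {
    rates_by_source <- list(trial = missing_rates, rwd = missing_rates)
  } else rates_by_source <- missing_rates
  for (src in names(rates_by_source)) {
    rates <- rates_by_source[[src]]
    if (length(rates) == 0) next
    unknown <- setdiff(names(rates), names(records))
    if (length(unknown)) stop("unknown covariate(s): ",
                              paste(unknown, collapse = ", "))
    if (mechanism == "MAR" && any(names(rates) %in% c("age", "sex")))
      stop("MAR conditioning covariates (age, sex) cannot be made missing")
    i <- which(records$source == src)
    if (!length(i)) next
    n <- length(i)
    if (mechanism == "MAR") {
      z <- as.numeric(scale(records$age[i]))
      male <- as.numeric(records$sex[i] == "male") - mean(records$sex[i] == "male")
      eta <- mar_coefs[["age"]] * z + mar_coefs[["sexmale"]] * male
    }
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r <= 0) next
      if (mechanism == "MCAR") {
        p <- rep(r, n)
      } else {
        a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - r,
                            c(-30, 30))$root
        p <- stats::plogis(a + eta)
      }
      records[[v]][i[stats::runif(n) < p]] <- NA
    }
  }
  records
}
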