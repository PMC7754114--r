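#' Full-run configuration
#'
#' Bundles every setting of one analysis run: the data source (a
#' [simulation_config()] or a patient-table path), eligibility criteria,
#' imputation settings, the weighting covariate set, the outcome convention
#' and the analysis set.  Exactly one analysis set per run artifact; all
#' seeds are recorded in the artifact manifest.
#'
#' Analysis sets mirror the prespecified sensitivity analyses:
#' `primary_on_treatment` (PS-weighted on-treatment analysis),
#' `itt` (intent to treat), `doubly_robust` (weighting plus outcome-model
#' covariate adjustment for the real-world comparisons),
#' `clinics_ge12mo` / `patients_ge12mo` (restriction to clinics with mean
#' on-treatment follow-up >= 12 months / patients with >= 12 months),
#' and `subgroup_age75` (treatment-by-age(>=75) interaction with doubly
#' robust estimation).
#'
#' @param sim A [simulation_config()], or `NULL` with `input_path` set.
#' @param input_path Optional path to a patient table written by
#'   [write_patient_table()].
#' @param eligibility An [eligibility_criteria()] object.
#' @param m,n_cycles Imputation count and chained-equation cycles.
#' @param weighting_set `"full"` or `"demographics_only"`.
#' @param outcome An [outcome_spec()]; its convention is overridden to
#'   `"itt"` by the `itt` analysis set.
#' @param analysis_set One of the six analysis sets above.
#' @param seed Integer seed for imputation (simulation uses the seed inside
#'   `sim`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       input_path = NULL,
                       eligibility = eligibility_criteria(),
                       m = 10, n_cycles = 10,
                       weighting_set = c("full", "demographics_only"),
                       outcome = outcome_spec(),
                       analysis_set = c("primary_on_treatment", "itt",
                                        "doubly_robust", "clinics_ge12mo",
                                        "patients_ge12mo", "subgroup_age75"),
                       seed = 1L) {
  weighting_set <- match.arg(weighting_set)
  analysis_set <- match.arg(analysis_set)
  if (is.null(sim) && is.null(input_path))
    stop("supply a simulation config or an input path")
  structure(list(sim = sim, input_path = input_path,
                 eligibility = eligibility, m = m, n_cycles = n_cycles,
                 weighting_set = weighting_set, outcome = outcome,
                 analysis_set = analysis_set, seed = as.integer(seed)),
            class = "run_config")
}

#' Restrict real-world follow-up to mitigate early discontinuation
#'
#' `clinic_mean_ge_12` keeps all patients of real-world clinics whose mean
#' on-treatment follow-up is >= 12 months (trial records are kept — the
#' restriction targets clinics whose treatment patterns resemble the
#' treat-to-progression protocol); `patient_ge_12` keeps, in both sources,
#' only patients with >= 12 months of on-treatment follow-up.
#'
#' @param records Patient records.
#' @param mode `"clinic_mean_ge_12"` or `"patient_ge_12"`.
#' @param min_months Threshold (12 by default).
#' @return The restricted records.
#' @export
restrict_followup <- function(records,
                              mode = c("clinic_mean_ge_12", "patient_ge_12"),
                              min_months = 12) {
  mode <- match.arg(mode)
  if (mode == "patient_ge_12")
    return(records[records$followup_months >= min_months, , drop = FALSE])
  rwd <- records$source == "rwd"
  if (any(rwd & (is.na(records$clinic_id) | records$clinic_id == "")))
    stop("clinic_id required for the clinic-level restriction")
  mu <- tapply(records$followup_months[rwd], records$clinic_id[rwd], mean)
  keep_clinics <- names(mu)[mu >= min_months]
  records[!rwd | records$clinic_id %in% keep_clinics, , drop = FALSE]
}

pipeline_log <- function(lines, stage, msg) {
  c(lines, sprintf("[%s] %s: %s",
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg))
}

#' Run the anchored indirect-comparison pipeline
#'
#' Orchestrates one full analysis: simulate (or load) the paired cohorts,
#' apply the harmonized eligibility criteria, multiply impute missing
#' baseline covariates, and — per imputed dataset — weight each real-world
#' treatment group to the trial population, fit the direct Cox comparisons
#' (experimental vs anchor in the trial, unadjusted because of
#' randomization; each non-anchor real-world regimen vs the real-world
#' anchor, weighted), and combine them into anchored indirect comparisons.
#' Per-imputation log hazard ratios and variances are pooled by Rubin's
#' rules (combination before pooling; set `pool_before_combine = TRUE` for
#' the alternative order).  When no covariate cell is missing, the
#' imputation stage is skipped and the "pooled" results are the
#' single-dataset estimates.
#'
#' @param config A [run_config()].
#' @param pool_before_combine Pool the direct estimates across imputations
#'   first and combine the pooled estimates, instead of combining within
#'   each imputation and pooling the indirect estimates.
#' @return Object of class `itc_artifact`: `attrition`, `balance` (averaged
#'   over imputations), `per_imputation` (long table of direct and indirect
#'   log hazard ratios), `direct` (pooled [hr_estimate()]s), `itc` (pooled
#'   [bucher_combine()]-style results), `subgroup` (for the subgroup
#'   analysis set), `ph_checks`, `manifest`, `log`.
#' @examples
#' \donttest{
#' cfg <- run_config(sim = simulation_config(n_trial_per_arm = 150,
#'   n_rwd_per_regimen = c(VRd = 150, Rd = 150, Vd = 150), seed = 11),
#'   m = 2, n_cycles = 3, seed = 11)
#' art <- run_pipeline(cfg)
#' art$itc
#' }
#' @export
run_pipeline <- function(config, pool_before_combine = FALSE) {
  stopifnot(inherits(config, "run_config"))
  lg <- character(0)
  stage <- function(s, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", s, conditionMessage(e)), call. = FALSE))
  }

  ## data
  records <- stage("data", {
    if (!is.null(config$sim)) simulate_cohorts(config$sim)
    else read_patient_table(config$input_path)
  })
  simc <- attr(records, "sim_config")
  anchor <- if (!is.null(simc)) simc$anchor else "Rd"
  experimental <- if (!is.null(simc)) simc$experimental else
    setdiff(unique(records$regimen[records$source == "trial"]), anchor)[1]
  lg <- pipeline_log(lg, "data", sprintf("%d records (%d trial, %d rwd)",
                                         nrow(records),
                                         sum(records$source == "trial"),
                                         sum(records$source == "rwd")))

  ## eligibility
  el <- stage("eligibility", apply_eligibility(records, config$eligibility))
  records <- el$records
  lg <- pipeline_log(lg, "eligibility",
                     sprintf("%d records eligible", nrow(records)))

  ## follow-up restrictions
  if (config$analysis_set == "clinics_ge12mo")
    records <- stage("restriction",
                     restrict_followup(records, "clinic_mean_ge_12"))
  if (config$analysis_set == "patients_ge12mo")
    records <- stage("restriction", restrict_followup(records, "patient_ge_12"))
  if (config$analysis_set %in% c("clinics_ge12mo", "patients_ge12mo"))
    lg <- pipeline_log(lg, "restriction",
                       sprintf("%d records after follow-up restriction",
                               nrow(records)))

  rwd_regs <- setdiff(unique(records$regimen[records$source == "rwd"]), NA)
  if (!anchor %in% rwd_regs)
    stop("[stage data] anchor regimen absent from real-world cohort",
         call. = FALSE)

  ## imputation
  cov_all <- intersect(names(default_covariate_spec()), names(records))
  any_missing <- anyNA(records[, cov_all])
  imp <- stage("imputation", {
    if (any_missing)
      impute_chained(records, m = config$m, n_cycles = config$n_cycles,
                     seed = config$seed)
    else structure(list(m = 1L, datasets = list(records),
                        covariates = cov_all, n_cycles = 0L,
                        seed = config$seed),
                   class = "imputed_datasets")
  })
  lg <- pipeline_log(lg, "imputation",
                     sprintf("%d dataset(s)%s", imp$m,
                             if (any_missing) "" else " (no missing cells)"))

  ## outcome convention
  ospec <- config$outcome
  if (config$analysis_set == "itt") ospec$convention <- "itt"
  dr_covs <- if (config$analysis_set %in% c("doubly_robust", "subgroup_age75"))
    weighting_covariates(config$weighting_set) else character(0)
  w_covs <- weighting_covariates(config$weighting_set)
  rwd_nonanchor <- setdiff(rwd_regs, anchor)

  per_imp <- list()
  bal_tabs <- list()
  subgroup_rows <- list()
  ph_rows <- list()
  for (k in seq_len(imp$m)) {
    dat <- derive_outcome(imp$datasets[[k]], ospec)
    trial <- dat[dat$source == "trial", , drop = FALSE]
    rwd <- dat[dat$source == "rwd", , drop = FALSE]

    wsets <- stage("weighting", {
      out <- list()
      for (g in rwd_regs) {
        mm <- fit_membership_model(trial, rwd[rwd$regimen == g, , drop = FALSE],
                                   covariates = w_covs)
        out[[g]] <- odds_weights(mm)
      }
      out
    })
    bal_tabs[[k]] <- balance_report(trial, rwd, wsets, covariates = w_covs)$table

    rwd_w <- rep(NA_real_, nrow(rwd))
    for (g in rwd_regs) rwd_w[rwd$regimen == g] <- wsets[[g]]$weights

    if (config$analysis_set == "subgroup_age75") {
      trial$.age75 <- trial$age >= 75
      rwd$.age75 <- rwd$age >= 75
      sg_t <- stage("survival",
                    subgroup_interaction(trial, experimental, anchor, trial$.age75,
                                         covariates = dr_covs))
      for (g in rwd_nonanchor) {
        sub <- rwd$regimen %in% c(g, anchor)
        sg_r <- stage("survival",
                      subgroup_interaction(rwd[sub, ], g, anchor,
                                           rwd$.age75[sub],
                                           weights = rwd_w[sub],
                                           covariates = dr_covs))
        for (s in c("subgroup_false", "subgroup_true"))
          subgroup_rows[[length(subgroup_rows) + 1L]] <- data.frame(
            imputation = k, stratum = if (s == "subgroup_true") "age_ge_75"
                                      else "age_lt_75",
            comparison = paste(experimental, "vs", g),
            log_hr = bucher_combine(sg_t$strata[[s]], sg_r$strata[[s]])$log_hr,
            var = sg_t$strata[[s]]$se^2 + sg_r$strata[[s]]$se^2,
            interaction_p_trial = sg_t$interaction_p,
            interaction_p_rwd = sg_r$interaction_p)
      }
      next
    }

    direct_t <- stage("survival", fit_cox(trial, experimental, anchor))
    ph_rows[[length(ph_rows) + 1L]] <- data.frame(
      imputation = k, comparison = paste(experimental, "vs", anchor),
      source = "trial", p = ph_check(trial, experimental, anchor)$p)
    per_imp[[length(per_imp) + 1L]] <- data.frame(
      imputation = k, comparison = paste(experimental, "vs", anchor),
      type = "direct_trial", treatment = experimental, reference = anchor,
      log_hr = direct_t$log_hr, var = direct_t$se^2,
      n = direct_t$n, events = direct_t$events)
    for (g in rwd_nonanchor) {
      sub <- rwd$regimen %in% c(g, anchor)
      direct_r <- stage("survival",
                        fit_cox(rwd[sub, ], g, anchor, weights = rwd_w[sub],
                                covariates = dr_covs))
      ph_rows[[length(ph_rows) + 1L]] <- data.frame(
        imputation = k, comparison = paste(g, "vs", anchor), source = "rwd",
        p = ph_check(rwd[sub, ], g, anchor, weights = rwd_w[sub])$p)
      itc_k <- bucher_combine(direct_t, direct_r)
      per_imp[[length(per_imp) + 1L]] <- data.frame(
        imputation = k,
        comparison = c(paste(g, "vs", anchor),
                       paste(experimental, "vs", g)),
        type = c("direct_rwd", "itc"),
        treatment = c(g, experimental),
        reference = c(anchor, g),
        log_hr = c(direct_r$log_hr, itc_k$log_hr),
        var = c(direct_r$se^2, itc_k$se^2),
        n = c(direct_r$n, NA),
        events = c(direct_r$events, NA))
    }
  }
  lg <- pipeline_log(lg, "survival", "direct and indirect estimates fitted")

  ## pooling
  pool_tab <- function(tab) {
    if (imp$m == 1)
      return(list(point = tab$log_hr, var = tab$var,
                  ci = tab$log_hr + c(-1, 1) * stats::qnorm(0.975) * sqrt(tab$var),
                  p = 2 * stats::pnorm(-abs(tab$log_hr / sqrt(tab$var)))))
    pr <- pool_rubin(tab$log_hr, tab$var)
    list(point = pr$point, var = pr$total_var, ci = pr$ci, p = pr$p)
  }
  mk_pooled_hr <- function(tab, model) {
    pr <- pool_tab(tab)
    est <- hr_estimate(tab$treatment[1], tab$reference[1],
                       log_hr = pr$point, se = sqrt(pr$var),
                       source = if (tab$type[1] == "direct_trial") "trial"
                                else "rwd",
                       n = tab$n[1], events = round(mean(tab$events)),
                       model = model)
    est$ci95 <- exp(pr$ci)   # t-based once pooled over imputations
    est$p <- pr$p
    est
  }

  direct <- list()
  itc <- list()
  subgroup <- NULL
  per_imp_tab <- if (length(per_imp)) do.call(rbind, per_imp) else NULL
  if (config$analysis_set == "subgroup_age75") {
    sg <- do.call(rbind, subgroup_rows)
    subgroup <- do.call(rbind, lapply(
      split(sg, list(sg$stratum, sg$comparison), drop = TRUE),
      function(tab) {
        pr <- pool_tab(tab)
        data.frame(stratum = tab$stratum[1], comparison = tab$comparison[1],
                   hr = exp(pr$point), ci_lower = exp(pr$ci[1]),
                   ci_upper = exp(pr$ci[2]), p = pr$p,
                   interaction_p_trial = mean(tab$interaction_p_trial),
                   interaction_p_rwd = mean(tab$interaction_p_rwd))
      }))
    rownames(subgroup) <- NULL
  } else {
    rwd_model <- if (length(dr_covs)) "doubly_robust" else "weighted"
    for (cmp in unique(per_imp_tab$comparison[per_imp_tab$type != "itc"])) {
      tab <- per_imp_tab[per_imp_tab$comparison == cmp &
                           per_imp_tab$type != "itc", ]
      direct[[cmp]] <- mk_pooled_hr(tab, model = if (tab$type[1] ==
        "direct_trial") "unadjusted" else rwd_model)
    }
    if (!pool_before_combine) {
      for (cmp in unique(per_imp_tab$comparison[per_imp_tab$type == "itc"])) {
        tab <- per_imp_tab[per_imp_tab$comparison == cmp &
                             per_imp_tab$type == "itc", ]
        pr <- pool_tab(tab)
        a <- direct[[paste(tab$treatment[1], "vs", anchor)]]
        b <- direct[[paste(tab$reference[1], "vs", anchor)]]
        res <- structure(list(
          comparison = c(treatment = tab$treatment[1],
                         reference = tab$reference[1]),
          anchor = anchor, log_hr = pr$point, se = sqrt(pr$var),
          hr = exp(pr$point), ci95 = exp(pr$ci), p = pr$p,
          inputs = list(a = a, b = b)), class = "itc_result")
        itc[[cmp]] <- res
      }
    } else {
      for (g in rwd_nonanchor) {
        a <- direct[[paste(experimental, "vs", anchor)]]
        b <- direct[[paste(g, "vs", anchor)]]
        itc[[paste(experimental, "vs", g)]] <- bucher_combine(a, b)
      }
    }
  }
  lg <- pipeline_log(lg, "pooling",
                     sprintf("Rubin's rules over %d imputation(s)", imp$m))

  bal_mean <- NULL
  if (length(bal_tabs)) {
    bal_all <- do.call(rbind, bal_tabs)
    bal_mean <- stats::aggregate(
      cbind(smd_unweighted, smd_weighted) ~ group + covariate,
      data = bal_all, FUN = mean)
  }

  manifest <- list(
    analysis_set = config$analysis_set,
    weighting_set = config$weighting_set,
    outcome = unclass(ospec),
    eligibility = unclass(config$eligibility),
    m = imp$m, n_cycles = config$n_cycles,
    seed = config$seed,
    sim_seed = if (!is.null(simc)) simc$seed else NA,
    anchor = anchor, experimental = experimental,
    n_eligible = nrow(records),
    pool_before_combine = pool_before_combine,
    r_version = as.character(getRversion())
  )
  structure(list(attrition = el$attrition, balance = bal_mean,
                 per_imputation = per_imp_tab, direct = direct, itc = itc,
                 subgroup = subgroup,
                 ph_checks = if (length(ph_rows)) do.call(rbind, ph_rows)
                             else NULL,
                 manifest = manifest, log = lg),
            class = "itc_artifact")
}

#' @export
print.itc_artifact <- function(x, ...) {
  cat(sprintf("Anchored ITC run artifact [%s]\n", x$manifest$analysis_set))
  cat(sprintf("  %d eligible patients; %d imputation(s)\n",
              x$manifest$n_eligible, x$manifest$m))
  for (d in x$direct) print(d)
  for (i in x$itc) print(i)
  if (!is.null(x$subgroup)) {
    cat("Subgroup results:\n")
    print(x$subgroup, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Render a baseline-characteristics table
#'
#' Weighted means (continuous covariates, with weighted SDs) and percentages
#' (categorical levels) for each trial arm (unweighted) and each weighted
#' real-world treatment group, with the weighted standardized difference of
#' every indicator vs the pooled trial population.  Percentages within a
#' categorical block sum to 100 (up to rounding).
#'
#' @param trial Trial records (complete covariates).
#' @param rwd Real-world records.
#' @param weight_sets Named list of [odds_weights()] per real-world regimen.
#' @param covariates Covariates, in display order.
#' @param digits Rounding for display columns.
#' @return Data frame, one row per covariate or level.
#' @export
render_baseline_table <- function(trial, rwd, weight_sets,
                                  covariates = weighting_covariates("full"),
                                  digits = 1) {
  wmean <- function(x, w) sum(w * x) / sum(w)
  wsd <- function(x, w) sqrt(sum(w * (x - wmean(x, w))^2) / (sum(w) - 1))
  trial_arms <- split(trial, trial$regimen)
  groups <- c(lapply(trial_arms, function(d) list(data = d, w = rep(1, nrow(d)))),
              stats::setNames(lapply(names(weight_sets), function(g)
                list(data = rwd[rwd$regimen == g, , drop = FALSE],
                     w = weight_sets[[g]]$weights)), names(weight_sets)))
  X_t <- covariate_design(trial, covariates)
  rows <- list()
  for (v in covariates) {
    x0 <- if (v == "crcl_le60") as.numeric(trial$crcl <= 60) else trial[[v]]
    if (is.factor(x0)) {
      for (l in levels(x0)) {
        vals <- vapply(groups, function(gr) {
          xl <- as.numeric(gr$data[[v]] == l)
          100 * wmean(xl, gr$w)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = v, level = l, statistic = "%",
          t(round(vals, digits)), check.names = FALSE)
      }
    } else {
      vals <- vapply(groups, function(gr) {
        x <- if (v == "crcl_le60") as.numeric(gr$data$crcl <= 60)
             else gr$data[[v]]
        if (v == "crcl_le60") 100 * wmean(x, gr$w) else wmean(x, gr$w)
      }, numeric(1))
      sds <- if (v != "crcl_le60") vapply(groups, function(gr) {
        wsd(gr$data[[v]], gr$w)
      }, numeric(1)) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, level = "",
        statistic = if (v == "crcl_le60") "%" else "mean (sd)",
        t(if (is.null(sds)) round(vals, digits) else round(vals, digits)),
        check.names = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
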