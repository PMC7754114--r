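#' Harmonized trial eligibility criteria
#'
#' The anchored comparison requires both cohorts to satisfy a common set of
#' inclusion/exclusion criteria mirroring the trial protocol: age >= 65 as a
#' transplant-ineligibility proxy, no transplant as part of first-line
#' therapy, ECOG performance status <= 2, creatinine clearance >= 30 mL/min,
#' at least one post-baseline response assessment, absence of selected
#' comorbidities, and (real-world only) restriction to regimens used by at
#' least 10% of the population for statistical power.
#'
#' @param min_age_years Minimum age at first-line therapy start.
#' @param max_ecog Maximum ECOG performance status.
#' @param min_crcl_ml_min Minimum creatinine clearance (mL/min).
#' @param require_response_assessment Require >= 1 disease-response
#'   assessment after first-line start.
#' @param exclude_transplant_lot1 Exclude patients transplanted during
#'   first-line therapy.
#' @param min_regimen_share Minimum share of (post-clinical-criteria)
#'   real-world patients a regimen must have to be retained, in `[0, 1]`.
#' @param lab_bounds Named list of `c(lower, upper)` bounds on lab
#'   covariates (bone-marrow / liver criteria); empty by default since the
#'   protocol thresholds are not restated here.
#' @param excluded_comorbidities Names of logical record columns whose
#'   `TRUE` values are excluded.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_age_years = 65,
                                 max_ecog = 2L,
                                 min_crcl_ml_min = 30,
                                 require_response_assessment = TRUE,
                                 exclude_transplant_lot1 = TRUE,
                                 min_regimen_share = 0.10,
                                 lab_bounds = list(),
                                 excluded_comorbidities = c("severe_cardiac",
                                                            "other_malignancy")) {
  if (min_regimen_share < 0 || min_regimen_share > 1)
    stop("min_regimen_share must lie in [0, 1]")
  for (b in lab_bounds)
    if (length(b) != 2 || b[1] > b[2]) stop("lab bounds must be (lower <= upper)")
  structure(list(min_age_years = min_age_years, max_ecog = max_ecog,
                 min_crcl_ml_min = min_crcl_ml_min,
                 require_response_assessment = require_response_assessment,
                 exclude_transplant_lot1 = exclude_transplant_lot1,
                 min_regimen_share = min_regimen_share,
                 lab_bounds = lab_bounds,
                 excluded_comorbidities = excluded_comorbidities),
            class = "eligibility_criteria")
}

# each criterion returns TRUE = fails (excluded); NA covariate values never
# exclude (eligibility precedes imputation)
criterion_failures <- function(records, criteria) {
  fails <- list()
  ok <- function(x) !is.na(x) & x        # NA-safe "fails" indicator
  if (!is.null(criteria$min_age_years) && "age" %in% names(records))
    fails[["age"]] <- ok(records$age < criteria$min_age_years)
  if (isTRUE(criteria$exclude_transplant_lot1)) {
    if (!"transplant_lot1" %in% names(records))
      stop("criterion references absent column: transplant_lot1")
    fails[["transplant_lot1"]] <- ok(records$transplant_lot1)
  }
  if (!is.null(criteria$max_ecog) && "ecog" %in% names(records))
    fails[["ecog"]] <- ok(as.numeric(as.character(records$ecog)) > criteria$max_ecog)
  if (!is.null(criteria$min_crcl_ml_min) && "crcl" %in% names(records))
    fails[["crcl"]] <- ok(records$crcl < criteria$min_crcl_ml_min)
  for (lab in names(criteria$lab_bounds)) {
    if (!lab %in% names(records))
      stop("criterion references absent column: ", lab)
    b <- criteria$lab_bounds[[lab]]
    fails[[lab]] <- ok(records[[lab]] < b[1] | records[[lab]] > b[2])
  }
  for (com in criteria$excluded_comorbidities) {
    if (!com %in% names(records))
      stop("criterion references absent column: ", com)
    fails[[com]] <- ok(records[[com]])
  }
  if (isTRUE(criteria$require_response_assessment)) {
    if (!"response_assessed" %in% names(records))
      stop("criterion references absent column: response_assessed")
    fails[["response_assessment"]] <- ok(!records$response_assessed)
  }
  fails
}

#' Apply eligibility criteria with attrition accounting
#'
#' Criteria are evaluated in a fixed order (age, transplant during first
#' line, ECOG, creatinine clearance, lab bounds, comorbidities, response
#' assessment, then the real-world regimen-share restriction); each excluded
#' record is counted once, at the first criterion it fails.  A missing value
#' on a criterion covariate never excludes a record — eligibility precedes
#' imputation, matching a pipeline in which clinical covariates of included
#' patients are multiply imputed afterwards.  The regimen-share restriction
#' applies to real-world records only and its shares are computed on the
#' post-clinical-criteria real-world population.
#'
#' @param records Patient data frame.
#' @param criteria An [eligibility_criteria()] object.
#' @return A list with `records` (the eligible subset) and `attrition`, a
#'   data frame with per-criterion exclusion counts by source and the final
#'   remaining counts.
#' @examples
#' cfg <- simulation_config(n_trial_per_arm = 100, seed = 3)
#' el <- apply_eligibility(simulate_cohorts(cfg), eligibility_criteria())
#' el$attrition
#' @export
apply_eligibility <- function(records, criteria) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  fails <- criterion_failures(records, criteria)
  excluded <- rep(FALSE, nrow(records))
  rows <- list()
  for (cr in names(fails)) {
    new <- fails[[cr]] & !excluded
    rows[[cr]] <- data.frame(criterion = cr,
                             excluded_trial = sum(new & records$source == "trial"),
                             excluded_rwd = sum(new & records$source == "rwd"))
    excluded <- excluded | new
  }
  kept <- records[!excluded, , drop = FALSE]

  # regimen-share restriction on the post-clinical-criteria real-world set
  if (!is.null(criteria$min_regimen_share) && criteria$min_regimen_share > 0 &&
      any(kept$source == "rwd")) {
    keep_regs <- regimen_share_filter(kept[kept$source == "rwd", , drop = FALSE],
                                      criteria$min_regimen_share)
    drop <- kept$source == "rwd" & !(kept$regimen %in% keep_regs)
    rows[["regimen_share"]] <- data.frame(criterion = "regimen_share",
                                          excluded_trial = 0L,
                                          excluded_rwd = sum(drop))
    kept <- kept[!drop, , drop = FALSE]
  }
  attrition <- do.call(rbind, rows)
  attrition <- rbind(attrition,
                     data.frame(criterion = "eligible",
                                excluded_trial = sum(kept$source == "trial"),
                                excluded_rwd = sum(kept$source == "rwd")))
  rownames(attrition) <- NULL
  list(records = kept, attrition = attrition)
}

#' Regimens meeting a minimum share of real-world use
#'
#' @param records Patient data frame (typically the real-world subset after
#'   clinical criteria).
#' @param min_share Minimum fraction of records, in `[0, 1]`.
#' @return Character vector of regimen labels whose share is `>= min_share`.
#' @examples
#' df <- data.frame(regimen = rep(c("A", "B", "C"), c(50, 45, 5)))
#' regimen_share_filter(df, 0.10)
#' @export
regimen_share_filter <- function(records, min_share) {
  if (nrow(records) == 0) stop("records must be non-empty")
  shares <- table(records$regimen) / nrow(records)
  names(shares)[shares >= min_share]
}
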