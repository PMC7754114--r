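#' Outcome derivation settings
#'
#' @param convention `"on_treatment"` (censor at treatment discontinuation
#'   for reasons other than progression or death — the primary convention,
#'   reducing heterogeneity in treatment persistence between trial and
#'   routine care) or `"itt"` (intent to treat: discontinuation ignored,
#'   follow-up runs to event, loss to follow-up or the administrative cap).
#' @param max_followup_months Administrative cap in months (48.5 for the
#'   progression-free survival analyses; 41.4 for the exploratory overall
#'   survival window).
#' @param endpoint `"pfs"` or `"os"` (label only; both are time-to-event).
#' @return Object of class `outcome_spec`.
#' @export
outcome_spec <- function(convention = c("on_treatment", "itt"),
                         max_followup_months = 48.5,
                         endpoint = c("pfs", "os")) {
  convention <- match.arg(convention)
  endpoint <- match.arg(endpoint)
  if (max_followup_months <= 0) stop("max_followup_months must be > 0")
  structure(list(convention = convention,
                 max_followup_months = max_followup_months,
                 endpoint = endpoint),
            class = "outcome_spec")
}

#' Derive the analysis time/event pair under an outcome convention
#'
#' Maps patient records to the `(time, event)` pair the Cox model consumes.
#' Under `"on_treatment"` the recorded follow-up already censors at
#' treatment discontinuation (`censor_reason = "discontinued"`).  Under
#' `"itt"` the discontinuation-free columns (`itt_months`, `itt_event`) are
#' used; records whose follow-up was truncated at discontinuation must carry
#' them.  All times are then capped at `spec$max_followup_months`, with
#' events beyond the cap reset to censored.
#'
#' @param records Patient records (see [simulate_cohorts()] for the column
#'   contract).
#' @param spec An [outcome_spec()].
#' @return `records` with columns `time` and `event` appended (and capped),
#'   ready for [fit_cox()].
#' @export
derive_outcome <- function(records, spec = outcome_spec()) {
  stopifnot(inherits(spec, "outcome_spec"))
  if (any(records$followup_months <= 0, na.rm = TRUE))
    stop("non-positive follow-up time")
  if (spec$convention == "on_treatment") {
    records$time <- records$followup_months
    records$event <- as.integer(records$event)
  } else {
    if (!all(c("itt_months", "itt_event") %in% names(records))) {
      if (any(records$censor_reason == "discontinued"))
        stop("itt convention requires itt_months/itt_event columns when ",
             "records were censored at discontinuation")
      records$time <- records$followup_months
      records$event <- as.integer(records$event)
      records$time <- pmin(records$time, spec$max_followup_months)
      records$event[records$followup_months > spec$max_followup_months] <- 0L
      return(records)
    }
    records$time <- records$itt_months
    records$event <- as.integer(records$itt_event)
  }
  over <- records$time > spec$max_followup_months
  records$event[over] <- 0L
  records$time[over] <- spec$max_followup_months
  records
}

# shared entry guard: subset to the two regimens, build the treatment
# indicator, check events per arm
cox_table <- function(data, treatment, reference, weights) {
  keep <- data$regimen %in% c(treatment, reference)
  d <- data[keep, , drop = FALSE]
  if (!is.null(weights)) {
    if (length(weights) == nrow(data)) weights <- weights[keep]
    if (length(weights) != nrow(d)) stop("weights length mismatch")
    if (any(weights <= 0)) stop("weights must be positive")
  } else weights <- rep(1, nrow(d))
  d$.treat <- as.integer(d$regimen == treatment)
  if (length(unique(d$.treat)) < 2)
    stop("monotone likelihood: treatment indicator is constant")
  ev <- tapply(d$event, d$.treat, sum)
  if (length(ev) < 2 || any(ev == 0))
    stop("monotone likelihood: no events in one arm; no estimate emitted")
  d$.w <- weights
  d
}

#' Weighted Cox proportional-hazards hazard ratio
#'
#' Fits a Cox model of `Surv(time, event)` on a treatment indicator
#' (optionally plus adjustment covariates) with Breslow tie handling.
#' Weighted fits use a robust sandwich standard error with the weights
#' treated as fixed; unit-weight fits use the model-based variance.  An
#' empty covariate list gives the weighted (or unadjusted) model; a
#' non-empty list gives the doubly robust model combining weighting with
#' outcome-model adjustment.
#'
#' @param data Analysis table from [derive_outcome()] (columns `time`,
#'   `event`, `regimen`, covariates).
#' @param treatment,reference Regimen labels to compare.
#' @param weights Optional positive per-patient weights (length of `data`
#'   or of its two-regimen subset).
#' @param covariates Adjustment covariate names (expanded via
#'   [covariate_design()]); empty for no adjustment.
#' @return An [hr_estimate()] object.
#' @examples
#' toy <- data.frame(regimen = c("A", "A", "B", "B"),
#'                   time = c(1, 3, 2, 3), event = c(1, 0, 1, 0))
#' fit_cox(toy, "A", "B")   # log HR = log(sqrt(2))
#' @export
fit_cox <- function(data, treatment, reference, weights = NULL,
                    covariates = character(0)) {
  d <- cox_table(data, treatment, reference, weights)
  unit_w <- all(d$.w == 1)
  rhs <- ".treat"
  if (length(covariates)) {
    X <- covariate_design(d, covariates)
    keep <- apply(X, 2, stats::sd) > 0
    X <- X[, keep, drop = FALSE]
    d <- cbind(d, as.data.frame(X, check.names = FALSE))
    rhs <- paste(c(".treat", sprintf("`%s`", colnames(X))), collapse = " + ")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, weights = d$.w, ties = "breslow",
                    robust = !unit_w),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("monotone likelihood: coefficient diverging; no estimate emitted")
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[".treat"]
  se <- sqrt(diag(fit$var)[1])   # robust variance when weighted, else model-based
  hr_estimate(treatment, reference, log_hr = unname(beta), se = unname(se),
              source = if ("source" %in% names(d)) as.character(d$source[1])
                       else NA_character_,
              n = nrow(d), events = sum(d$event),
              model = if (length(covariates)) "doubly_robust"
                      else if (unit_w) "unadjusted" else "weighted")
}

#' Proportional-hazards check via a treatment-by-log(time) interaction
#'
#' Tests a time-varying treatment coefficient of the form
#' `beta(t) = beta + theta * log(t)` — the treatment-by-log(follow-up-time)
#' interaction — with the standard Schoenfeld-residual score test (log time
#' transform); small p-values indicate non-proportional hazards.
#' Report-only: no automatic action is taken.
#'
#' @inheritParams fit_cox
#' @return List with `p` (interaction p-value), `table` (the test table)
#'   and the underlying Cox fit.
#' @export
ph_check <- function(data, treatment, reference, weights = NULL) {
  d <- cox_table(data, treatment, reference, weights)
  if (sum(d$event) < 2)
    stop("too few events to test proportional hazards")
  unit_w <- all(d$.w == 1)
  fit <- survival::coxph(survival::Surv(time, event) ~ .treat, data = d,
                         weights = d$.w, ties = "breslow", robust = !unit_w)
  zph <- survival::cox.zph(fit, transform = "log")
  list(p = unname(zph$table[".treat", "p"]), table = zph$table, fit = fit)
}

#' Treatment-by-subgroup interaction analysis
#'
#' Fits a single Cox model with treatment, a binary subgroup indicator and
#' their interaction (plus optional adjustment covariates, as used for the
#' age >= 75 subgroup where within-stratum balance is imperfect), and
#' returns stratum-specific hazard-ratio estimates from the interaction
#' parameterization together with the Wald p-value of the interaction.
#'
#' @inheritParams fit_cox
#' @param subgroup Logical/0-1 vector aligned with `data`, or the name of a
#'   logical column of `data`.
#' @return List with `strata` (named list of [hr_estimate()]s for the
#'   subgroup-`FALSE` and subgroup-`TRUE` strata), and `interaction_p`.
#' @export
subgroup_interaction <- function(data, treatment, reference, subgroup,
                                 weights = NULL, covariates = character(0)) {
  if (is.character(subgroup) && length(subgroup) == 1)
    subgroup <- data[[subgroup]]
  subgroup <- as.integer(subgroup)
  if (length(subgroup) != nrow(data)) stop("subgroup length mismatch")
  data$.sub <- subgroup
  keep <- data$regimen %in% c(treatment, reference)
  for (s in 0:1) {
    ds <- data[keep & data$.sub == s, , drop = FALSE]
    if (nrow(ds) == 0) stop("empty stratum (subgroup = ", s, ")")
    ev <- tapply(ds$event, ds$regimen == treatment, sum)
    if (length(ev) < 2 || any(ev == 0))
      stop("stratum with zero events in one arm (subgroup = ", s, ")")
  }
  d <- cox_table(data, treatment, reference, weights)
  unit_w <- all(d$.w == 1)
  rhs <- ".treat * .sub"
  if (length(covariates)) {
    X <- covariate_design(d, covariates)
    X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
    d <- cbind(d, as.data.frame(X, check.names = FALSE))
    rhs <- paste(c(".treat * .sub", sprintf("`%s`", colnames(X))),
                 collapse = " + ")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = d, weights = d$.w, ties = "breslow",
                         robust = !unit_w)
  co <- stats::coef(fit)
  V <- fit$var
  i_t <- which(names(co) == ".treat")
  i_x <- which(names(co) == ".treat:.sub")
  b0 <- co[i_t]
  se0 <- sqrt(V[i_t, i_t])
  b1 <- co[i_t] + co[i_x]
  se1 <- sqrt(V[i_t, i_t] + V[i_x, i_x] + 2 * V[i_t, i_x])
  z_int <- co[i_x] / sqrt(V[i_x, i_x])
  mk <- function(b, se, s) hr_estimate(
    treatment, reference, log_hr = unname(b), se = unname(se),
    source = if ("source" %in% names(d)) as.character(d$source[1]) else NA,
    n = sum(d$.sub == s), events = sum(d$event[d$.sub == s]),
    model = if (length(covariates)) "doubly_robust"
            else if (unit_w) "unadjusted" else "weighted")
  list(strata = list(subgroup_false = mk(b0, se0, 0),
                     subgroup_true = mk(b1, se1, 1)),
       interaction_p = unname(2 * stats::pnorm(-abs(z_int))))
}
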