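#' Back out the standard error of a log hazard ratio from its 95% CI
#'
#' Published hazard ratios are usually reported as `HR (lower, upper)` with a
#' normal-approximation 95% confidence interval on the log scale.  The
#' standard error of the log hazard ratio is then
#' `(log(upper) - log(lower)) / (2 * 1.96)`, which is what anchored indirect
#' comparisons need to combine estimates from different sources.
#'
#' @param hr Hazard ratio point estimate (must lie inside the interval).
#' @param ci_lower,ci_upper Bounds of the 95% confidence interval.
#' @return Standard error of `log(hr)` (a single number).
#' @examples
#' se_from_ci(0.54, 0.42, 0.71)
#' @export
se_from_ci <- function(hr, ci_lower, ci_upper) {
  if (!is.numeric(hr) || !is.numeric(ci_lower) || !is.numeric(ci_upper))
    stop("hr and CI bounds must be numeric")
  if (any(c(hr, ci_lower, ci_upper) <= 0))
    stop("hazard ratios and CI bounds must be strictly positive")
  if (ci_lower > hr || hr > ci_upper)
    stop("point estimate must lie within [ci_lower, ci_upper]")
  (log(ci_upper) - log(ci_lower)) / (2 * stats::qnorm(0.975))
}

#' Construct a direct hazard-ratio estimate
#'
#' Container for one fitted (or published) direct comparison of two regimens
#' within a single data source.  Either supply `log_hr` and `se`, or supply
#' `hr` with its 95% confidence interval, in which case the standard error is
#' backed out with [se_from_ci()].
#'
#' @param treatment,reference Regimen labels of the comparison
#'   (`treatment` vs `reference`).
#' @param log_hr Log hazard ratio.  Mutually exclusive with `hr`/`ci`.
#' @param se Standard error of the log hazard ratio.
#' @param hr Hazard ratio point estimate.
#' @param ci Length-2 numeric, the 95% confidence interval of `hr`.
#' @param source Data-source label, e.g. `"trial"` or `"rwd"`.
#' @param n,events Optional sample size and event count.
#' @param model Estimation flavour: `"weighted"`, `"doubly_robust"` or
#'   `"unadjusted"`.
#' @return An object of class `hr_estimate` with elements `comparison`,
#'   `source`, `log_hr`, `se`, `hr`, `ci95`, `p`, `n`, `events`, `model`.
#' @examples
#' hr_estimate("DRd", "Rd", hr = 0.54, ci = c(0.42, 0.71), source = "trial")
#' @export
hr_estimate <- function(treatment, reference,
                        log_hr = NULL, se = NULL,
                        hr = NULL, ci = NULL,
                        source = NA_character_,
                        n = NA_integer_, events = NA_integer_,
                        model = c("weighted", "doubly_robust", "unadjusted")) {
  model <- match.arg(model)
  if (is.null(log_hr)) {
    if (is.null(hr) || is.null(ci) || length(ci) != 2L)
      stop("supply either log_hr + se, or hr + ci (length 2)")
    se <- se_from_ci(hr, ci[1], ci[2])
    log_hr <- log(hr)
  }
  if (is.null(se) || se < 0) stop("se must be a non-negative number")
  z <- stats::qnorm(0.975)
  out <- structure(list(
    comparison = c(treatment = treatment, reference = reference),
    source     = source,
    log_hr     = as.numeric(log_hr),
    se         = as.numeric(se),
    hr         = exp(as.numeric(log_hr)),
    ci95       = exp(log_hr + c(-1, 1) * z * se),
    p          = if (se > 0) 2 * stats::pnorm(-abs(log_hr / se)) else
                   as.numeric(log_hr == 0),
    n          = n,
    events     = events,
    model      = model
  ), class = "hr_estimate")
  out
}

#' @export
print.hr_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Direct comparison: %s vs %s (%s, %s)\n",
              x$comparison[["treatment"]], x$comparison[["reference"]],
              x$source, x$model))
  cat(sprintf("  HR %.*f (95%% CI %.*f, %.*f), p = %s\n",
              digits, x$hr, digits, x$ci95[1], digits, x$ci95[2],
              format.pval(x$p, digits = 2)))
  if (!is.na(x$n)) cat(sprintf("  n = %d, events = %d\n", x$n, x$events))
  invisible(x)
}

#' Anchored indirect comparison of two direct hazard-ratio estimates
#'
#' Combines two direct comparisons that share a common anchor regimen into an
#' indirect comparison on the log hazard-ratio scale: if A vs anchor and
#' B vs anchor are the direct estimates, the indirect A vs B estimate is
#' `log HR(A vs anchor) - log HR(B vs anchor)` with variance equal to the sum
#' of the two variances (the two sources are independent; within-source
#' correlation through the shared anchor arm is ignored, the standard
#' anchored-comparison approximation).  Because only relative effects cross
#' sources, absolute differences in outcome ascertainment or baseline risk
#' between the sources cancel.
#'
#' @param a,b Objects of class [hr_estimate()] sharing the same reference
#'   (anchor) regimen.  The result compares `a`'s treatment with `b`'s.
#' @return An object of class `itc_result` with the combined `log_hr`, `se`,
#'   `hr`, `ci95`, two-sided Wald `p`, the `anchor` label and both `inputs`.
#' @examples
#' a <- hr_estimate("DRd", "Rd", hr = 0.54, ci = c(0.42, 0.71), source = "trial")
#' b <- hr_estimate("VRd", "Rd", hr = 0.80, ci = c(0.62, 1.02), source = "rwd")
#' bucher_combine(a, b)
#' @export
bucher_combine <- function(a, b) {
  stopifnot(inherits(a, "hr_estimate"), inherits(b, "hr_estimate"))
  anchor_a <- a$comparison[["reference"]]
  anchor_b <- b$comparison[["reference"]]
  if (!identical(anchor_a, anchor_b))
    stop(sprintf("anchor mismatch: '%s' vs '%s'", anchor_a, anchor_b))
  log_hr <- a$log_hr - b$log_hr
  se <- sqrt(a$se^2 + b$se^2)
  z <- stats::qnorm(0.975)
  structure(list(
    comparison = c(treatment = a$comparison[["treatment"]],
                   reference = b$comparison[["treatment"]]),
    anchor = anchor_a,
    log_hr = log_hr,
    se = se,
    hr = exp(log_hr),
    ci95 = exp(log_hr + c(-1, 1) * z * se),
    p = if (se > 0) 2 * stats::pnorm(-abs(log_hr / se)) else
      as.numeric(log_hr == 0),
    inputs = list(a = a, b = b)
  ), class = "itc_result")
}

#' @export
print.itc_result <- function(x, digits = 2, ...) {
  cat(sprintf("Anchored indirect comparison: %s vs %s (anchor %s)\n",
              x$comparison[["treatment"]], x$comparison[["reference"]],
              x$anchor))
  cat(sprintf("  HR %.*f (95%% CI %.*f, %.*f), p = %s\n",
              digits, x$hr, digits, x$ci95[1], digits, x$ci95[2],
              format.pval(x$p, digits = 2)))
  invisible(x)
}

#' Percent risk reduction implied by a hazard ratio
#'
#' `100 * (1 - HR)`, rounded to a whole percent for reporting ("a 32% reduced
#' risk of progression or death").  Negative values indicate increased risk.
#'
#' @param x An `itc_result`, `hr_estimate`, or a bare hazard ratio.
#' @return Integer-rounded percentage.
#' @examples
#' percent_risk_reduction(0.675)
#' @export
percent_risk_reduction <- function(x) {
  hr <- if (inherits(x, c("itc_result", "hr_estimate"))) x$hr else x
  stopifnot(is.numeric(hr), hr > 0)
  round(100 * (1 - hr))
}
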