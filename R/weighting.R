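#' Fit a trial-membership propensity model for one real-world group
#'
#' Pools the trial cohort (both randomized arms) with one real-world
#' treatment group and fits a logistic regression of trial membership on the
#' baseline covariates.  The fitted trial-membership probabilities are the
#' propensity scores from which odds weights are formed so the real-world
#' group resembles the trial population.  The model is refit per imputed
#' dataset and per real-world group.
#'
#' @param trial Trial patient records (complete covariates, post-imputation).
#' @param group Records of a single real-world treatment group.
#' @param covariates Covariate names (factors are expanded to indicators);
#'   see [covariate_design()].
#' @return Object of class `membership_model`: the fitted `glm`, the
#'   trial-membership probability for every `group` patient (`prob_group`),
#'   the group label and covariate set.
#' @export
fit_membership_model <- function(trial, group,
                                 covariates = weighting_covariates("full")) {
  if (nrow(trial) == 0 || nrow(group) == 0)
    stop("both the trial sample and the group must be non-empty")
  pooled <- rbind(trial[, intersect(names(trial), names(group)), drop = FALSE],
                  group[, intersect(names(trial), names(group)), drop = FALSE])
  X <- covariate_design(pooled, covariates)
  if (anyNA(X))
    stop("membership model requires complete covariates (impute first)")
  y <- rep(c(1L, 0L), c(nrow(trial), nrow(group)))
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  co <- stats::coef(fit)[-1]
  if (!fit$converged || any(is.na(co)) || any(abs(co) > 15)) {
    worst <- names(co)[which.max(abs(ifelse(is.na(co), Inf, co)))]
    stop("separation (or collinearity) in membership model; offending covariate: ",
         worst)
  }
  p <- stats::fitted(fit)
  structure(list(model = fit,
                 prob_group = p[y == 0L],
                 prob_trial = p[y == 1L],
                 group = if ("regimen" %in% names(group))
                   as.character(group$regimen[1]) else NA_character_,
                 covariates = covariates),
            class = "membership_model")
}

#' Standard covariate sets for the membership model
#'
#' `"full"` uses every baseline-table covariate (age, sex, race, ISS stage,
#' cytogenetic risk, ECOG, the creatinine-clearance <= 60 mL/min indicator
#' and months from diagnosis to first-line therapy); `"demographics_only"`
#' restricts to age, sex and race — the sensitivity configuration that
#' omits clinical covariates with high missingness.
#'
#' @param set `"full"` or `"demographics_only"`.
#' @return Character vector of covariate names.
#' @export
weighting_covariates <- function(set = c("full", "demographics_only")) {
  switch(match.arg(set),
         full = c("age", "sex", "race", "iss", "cyto_risk", "ecog",
                  "crcl_le60", "dx_to_lot1"),
         demographics_only = c("age", "sex", "race"))
}

#' Odds weights targeting the trial population
#'
#' Converts trial-membership probabilities `p` into weights
#' `w = p / (1 - p)` (the weighting-to-target-population form: a weighted
#' real-world group has the covariate distribution of the trial population),
#' normalized to sum to the group's unweighted size, with the effective
#' sample size `ESS = (sum w)^2 / sum(w^2)`.
#'
#' @param p Trial-membership probabilities in (0, 1), or a
#'   [fit_membership_model()] result.
#' @param group Optional regimen label for reporting.
#' @return Object of class `weight_set`: `group`, `weights` (normalized),
#'   `normalized = TRUE`, `ess`, `n`.
#' @examples
#' odds_weights(c(0.5, 0.8))   # raw odds 1, 4 -> normalized 0.4, 1.6
#' @export
odds_weights <- function(p, group = NULL) {
  if (inherits(p, "membership_model")) {
    group <- group %||% p$group
    p <- p$prob_group
  }
  if (any(p <= 0) || any(p >= 1))
    stop("membership probabilities must lie strictly in (0, 1)")
  w_raw <- p / (1 - p)
  n <- length(w_raw)
  w <- w_raw * n / sum(w_raw)
  structure(list(group = group %||% NA_character_, weights = w,
                 normalized = TRUE, ess = sum(w)^2 / sum(w^2), n = n),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Weight set%s: n = %d, ESS = %.1f (%.0f%% of n)\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$n, x$ess, 100 * x$ess / x$n))
  invisible(x)
}

#' Standardized difference between a target sample and a (weighted) group
#'
#' For a continuous covariate:
#' `(mean_target - mean_group) / sqrt((var_target + var_group) / 2)`;
#' for a binary indicator the variances are `p (1 - p)`.  Group moments use
#' the supplied weights; the sign convention is target minus group.
#'
#' @param x_target,x_group Numeric vectors (binary indicators coded 0/1).
#' @param w_target,w_group Optional non-negative weights.
#' @param binary Treat the covariate as a binary indicator.
#' @return The standardized difference (a single number).
#' @examples
#' standardized_difference(rnorm(100, 1), rnorm(100, 0))  # ~1
#' @export
standardized_difference <- function(x_target, x_group,
                                    w_target = NULL, w_group = NULL,
                                    binary = FALSE) {
  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) {
    mu <- wmean(x, w)
    sum(w * (x - mu)^2) / (sum(w) - 1)
  }
  w_target <- w_target %||% rep(1, length(x_target))
  w_group <- w_group %||% rep(1, length(x_group))
  m_t <- wmean(x_target, w_target)
  m_g <- wmean(x_group, w_group)
  if (binary) {
    v_t <- m_t * (1 - m_t)
    v_g <- m_g * (1 - m_g)
  } else {
    v_t <- wvar(x_target, w_target)
    v_g <- wvar(x_group, w_group)
  }
  pooled <- (v_t + v_g) / 2
  if (pooled <= 0) stop("zero pooled variance; standardized difference undefined")
  (m_t - m_g) / sqrt(pooled)
}

#' Covariate-balance report for weighted real-world groups
#'
#' Computes before/after-weighting standardized differences of every
#' covariate indicator between the trial population (the target) and each
#' real-world treatment group, and flags covariates whose absolute weighted
#' standardized difference exceeds the threshold (0.1 by default, the
#' conventional cut-off for meaningful imbalance).  Groups with any flagged
#' covariate are marked as requiring doubly robust estimation downstream.
#'
#' @param trial Trial records (complete covariates).
#' @param rwd Real-world records.
#' @param weight_sets Named list of [odds_weights()] results, one per
#'   real-world regimen.
#' @param covariates Covariate names (expanded to indicators).
#' @param threshold Flagging threshold on the absolute weighted SMD.
#' @return Object of class `balance_report`: `table` (one row per group x
#'   indicator with unweighted/weighted SMD), `flagged` (subset over
#'   threshold), `groups_flagged`, `threshold`.
#' @export
balance_report <- function(trial, rwd, weight_sets,
                           covariates = weighting_covariates("full"),
                           threshold = 0.1) {
  X_t <- covariate_design(trial, covariates)
  rows <- list()
  for (g in names(weight_sets)) {
    grp <- rwd[rwd$regimen == g, , drop = FALSE]
    ws <- weight_sets[[g]]
    if (nrow(grp) != ws$n)
      stop("weight set for group '", g, "' does not match its record count")
    X_g <- covariate_design(grp, covariates)
    for (j in colnames(X_t)) {
      bin <- all(X_t[, j] %in% c(0, 1)) && all(X_g[, j] %in% c(0, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, covariate = j,
        smd_unweighted = standardized_difference(X_t[, j], X_g[, j],
                                                 binary = bin),
        smd_weighted = standardized_difference(X_t[, j], X_g[, j],
                                               w_group = ws$weights,
                                               binary = bin))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  flagged <- tab[abs(tab$smd_weighted) > threshold, , drop = FALSE]
  structure(list(table = tab, flagged = flagged,
                 groups_flagged = unique(flagged$group),
                 threshold = threshold),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Balance report (|weighted SMD| > %.2f flagged)\n", x$threshold))
  mx <- stats::aggregate(abs(smd_weighted) ~ group, data = x$table, FUN = max)
  names(mx) <- c("group", "max_abs_weighted_smd")
  print(mx, row.names = FALSE)
  if (nrow(x$flagged)) {
    cat("Flagged:\n")
    print(x$flagged, row.names = FALSE, digits = 3)
  } else cat("No covariate flagged.\n")
  invisible(x)
}
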