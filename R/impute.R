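#' Multiple imputation of baseline covariates by chained equations
#'
#' Fills missing baseline-covariate cells by iterated conditional modelling:
#' each incomplete covariate is regressed on all other baseline covariates
#' plus, when present, the event indicator, log follow-up time and the data
#' source (standard practice for imputation in survival analyses), and its
#' missing cells are re-drawn from the fitted conditional model; the sweep
#' over covariates is cycled `n_cycles` times and the whole chain is repeated
#' `m` times to produce `m` complete datasets.
#'
#' Continuous covariates use predictive-mean matching (k = 5 donors, with a
#' Bayesian draw of the regression coefficients), so imputed values are
#' always observed donor values — robust to non-normal lab distributions.
#' Binary covariates are drawn from a logistic model with a normal
#' approximation draw of its coefficients; covariates with more than two
#' levels are drawn from fitted multinomial probabilities.
#'
#' @param records Data frame of patient records (or a bare covariate table).
#' @param m Number of completed datasets (default 10).
#' @param n_cycles Chained-equation sweeps per dataset (default 10).
#' @param seed Integer seed; the result is deterministic given it.
#' @param covariates Columns eligible for imputation/prediction; defaults to
#'   the intersection of the standard baseline set with `names(records)`.
#' @param pmm_k Number of predictive-mean-matching donors.
#' @return Object of class `imputed_datasets`: list with `m`, `datasets` (a
#'   list of completed copies of `records`), `covariates`, `n_cycles`,
#'   `seed`.  Originally observed cells are identical across datasets.
#' @examples
#' cfg <- simulation_config(n_trial_per_arm = 60,
#'                          n_rwd_per_regimen = c(VRd = 60, Rd = 60), seed = 2)
#' imp <- impute_chained(simulate_cohorts(cfg), m = 2, n_cycles = 3, seed = 9)
#' sapply(imp$datasets, function(d) sum(is.na(d$iss)))
#' @export
impute_chained <- function(records, m = 10, n_cycles = 10, seed = 1L,
                           covariates = intersect(names(default_covariate_spec()),
                                                  names(records)),
                           pmm_k = 5L) {
  stopifnot(m >= 1, n_cycles >= 1)
  covs <- covariates
  miss_frac <- vapply(covs, function(v) mean(is.na(records[[v]])), numeric(1))
  if (any(miss_frac == 1))
    stop("covariate(s) 100% missing: ",
         paste(covs[miss_frac == 1], collapse = ", "))
  for (v in covs)
    if (is.factor(records[[v]]) &&
        length(unique(stats::na.omit(records[[v]]))) < 2)
      stop("degenerate single-level categorical: ", v)
  if (!any(miss_frac == 0))
    stop("at least one fully observed covariate is required")
  targets <- covs[miss_frac > 0]
  targets <- targets[order(miss_frac[targets])]     # impute least-missing first

  aux <- character(0)
  if (all(c("followup_months", "event") %in% names(records)))
    aux <- c("event", "log_fu")
  if ("source" %in% names(records) &&
      length(unique(records$source)) > 1) aux <- c(aux, "src")

  set.seed(seed)
  if (length(targets) == 0)
    return(structure(list(m = m, datasets = rep(list(records), m),
                          covariates = covs, n_cycles = n_cycles, seed = seed),
                     class = "imputed_datasets"))

  predictor_matrix <- function(dat, exclude) {
    use <- setdiff(covs, exclude)
    X <- covariate_design(dat, use)
    if ("log_fu" %in% aux)
      X <- cbind(X, event = dat$event, log_fu = log(dat$followup_months))
    if ("src" %in% aux)
      X <- cbind(X, src = as.numeric(dat$source == dat$source[1]))
    # drop constant columns (can arise in small strata)
    X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  }

  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    dat <- records
    for (v in targets) {                       # initialize from observed margins
      na <- is.na(dat[[v]])
      dat[[v]][na] <- sample(dat[[v]][!na], sum(na), replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (v in targets) {
        na <- is.na(records[[v]])
        X <- predictor_matrix(dat, v)
        dat[[v]][na] <- draw_conditional(records[[v]], dat[[v]], X, na, pmm_k)
      }
    }
    datasets[[k]] <- dat
  }
  structure(list(m = m, datasets = datasets, covariates = covs,
                 n_cycles = n_cycles, seed = seed),
            class = "imputed_datasets")
}

#' @export
print.imputed_datasets <- function(x, ...) {
  cat(sprintf("%d imputed dataset(s), %d chained-equation cycles, seed %d\n",
              x$m, x$n_cycles, x$seed))
  invisible(x)
}

# one conditional-model draw for the missing cells of a single covariate;
# y_orig holds the original (with NA) values, y_cur the current completion
draw_conditional <- function(y_orig, y_cur, X, na, pmm_k) {
  obs <- !na
  if (is.factor(y_orig)) {
    lv <- levels(droplevels(y_orig[obs]))
    if (length(lv) == 2) {
      yb <- as.numeric(y_cur[obs] == lv[2])
      fit <- suppressWarnings(stats::glm.fit(cbind(1, X[obs, , drop = FALSE]),
                                             yb, family = stats::binomial()))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      eta <- as.numeric(cbind(1, X[na, , drop = FALSE]) %*% beta)
      drawn <- lv[1 + (stats::runif(sum(na)) < stats::plogis(eta))]
    } else {
      df <- data.frame(y = factor(y_cur[obs], levels = lv), X[obs, , drop = FALSE])
      cap <- utils::capture.output(
        fit <- nnet::multinom(y ~ ., data = df, maxit = 200, trace = FALSE))
      pr <- stats::predict(fit,
                           newdata = data.frame(X[na, , drop = FALSE]),
                           type = "probs")
      pr <- matrix(pr, nrow = sum(na), ncol = length(lv))
      drawn <- lv[apply(pr, 1, function(p)
        sample.int(length(p), 1, prob = pmax(p, 1e-12)))]
    }
    return(drawn)   # character values within the factor's levels
  }
  ## continuous: predictive-mean matching with a Bayesian coefficient draw
  Xo <- cbind(1, X[obs, , drop = FALSE])
  yo <- y_cur[obs]
  qrX <- qr(Xo)
  betahat <- qr.coef(qrX, yo)
  betahat[is.na(betahat)] <- 0
  res <- yo - as.numeric(Xo %*% betahat)
  df_res <- max(length(yo) - qrX$rank, 1)
  sigma2 <- sum(res^2) / df_res
  sigma2_star <- sigma2 * df_res / stats::rchisq(1, df_res)
  R <- qr.R(qrX)[, order(qrX$pivot), drop = FALSE]
  XtX <- crossprod(R)
  V <- tryCatch(chol2inv(chol(XtX + diag(1e-8, ncol(XtX)))),
                error = function(e) diag(1e-6, ncol(XtX)))
  beta_star <- betahat + as.numeric(t(chol(sigma2_star * V +
                                             diag(1e-12, ncol(V)))) %*%
                                      stats::rnorm(length(betahat)))
  pred_obs <- as.numeric(Xo %*% betahat)
  pred_mis <- as.numeric(cbind(1, X[na, , drop = FALSE]) %*% beta_star)
  pmm_match(pred_obs, yo, pred_mis, pmm_k)
}

# nearest-predicted-value donor matching: for each missing prediction pick
# one of the k nearest observed predictions and return that donor's value
pmm_match <- function(pred_obs, y_obs, pred_mis, k) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  n <- length(po)
  k <- min(k, n)
  pos <- findInterval(pred_mis, po)
  vapply(seq_along(pred_mis), function(i) {
    lo <- max(1, pos[i] - k)
    hi <- min(n, pos[i] + k)
    idx <- lo:hi
    d <- abs(po[idx] - pred_mis[i])
    donors <- idx[order(d)][seq_len(min(k, length(idx)))]
    yo[sample(donors, 1)]
  }, numeric(1))
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Combines per-dataset point estimates and their variances into a single
#' estimate: the pooled point is the mean; the total variance is the
#' within-imputation mean variance plus `(1 + 1/m)` times the
#' between-imputation variance; degrees of freedom follow Rubin's
#' small-sample formula `(m - 1) * (1 + W / ((1 + 1/m) B))^2`, and the CI and
#' two-sided p-value use the t distribution on those df (normal when the
#' between-imputation variance is zero).  Estimates are pooled on the scale
#' supplied — the log hazard-ratio scale in this pipeline.
#'
#' @param estimates Numeric vector of per-dataset estimates (length m >= 2).
#' @param variances Numeric vector of their squared standard errors.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `pooled_estimate`: `point`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `ci`, `p`, `m`.
#' @examples
#' pool_rubin(c(0, 2), c(1, 1))   # point 1, total variance 4
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  if (length(estimates) != length(variances))
    stop("estimates and variances must have equal length")
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules require m >= 2 estimates")
  if (any(variances <= 0)) stop("variances must be > 0")
  point <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between > 0) (m - 1) * (1 + within / ((1 + 1 / m) * between))^2 else Inf
  se <- sqrt(total)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(point = point, within_var = within, between_var = between,
                 total_var = total, se = se, df = df,
                 ci = point + c(-1, 1) * q * se,
                 p = 2 * stats::pt(-abs(point / se), df),
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled over %d imputations: %.*f (SE %.*f, 95%% CI %.*f, %.*f), p = %s\n",
              x$m, digits, x$point, digits, x$se, digits, x$ci[1],
              digits, x$ci[2], format.pval(x$p, digits = 2)))
  cat(sprintf("  within-var %.4g, between-var %.4g, df %.3g\n",
              x$within_var, x$between_var, x$df))
  invisible(x)
}
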