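# shared fixtures and independent oracles

# small, fast simulation config for smoke/property tests
small_config <- function(seed = 1, n_trial = 150, n_rwd = 150, ...) {
  simulation_config(n_trial_per_arm = n_trial,
                    n_rwd_per_regimen = c(VRd = n_rwd, Rd = n_rwd, Vd = n_rwd),
                    seed = seed, ...)
}

# Breslow weighted Cox partial log-likelihood for a single binary covariate,
# written from the definition (independent oracle for fit_cox)
breslow_loglik <- function(beta, time, event, x, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (beta * x[i] - log(sum(w[risk] * exp(beta * x[risk]))))
  }
  ll
}

# grid-search maximizer of the partial likelihood over beta in [-5, 5]
grid_cox <- function(time, event, x, w = rep(1, length(time)),
                     step = 1e-4) {
  grid <- seq(-5, 5, by = step)
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = time, event = event, x = x, w = w)
  grid[which.max(ll)]
}

# four-subject dataset whose partial-likelihood maximum is exp(beta) = sqrt(2)
toy_sqrt2 <- function() {
  data.frame(regimen = c("A", "A", "B", "B"),
             time = c(1, 3, 2, 3),
             event = c(1L, 0L, 1L, 0L))
}

# published direct estimates (hr, lower, upper) used as worked-example inputs
published_direct <- function() {
  list(
    primary = list(trial = c(0.54, 0.42, 0.71),
                   VRd = c(0.80, 0.62, 1.02), Vd = c(1.14, 0.87, 1.48)),
    demographics = list(trial = c(0.54, 0.42, 0.71),
                        VRd = c(0.82, 0.64, 1.05), Vd = c(1.24, 0.97, 1.57)),
    doubly_robust = list(trial = c(0.54, 0.42, 0.71),
                         VRd = c(0.79, 0.61, 1.01), Vd = c(1.11, 0.84, 1.48)),
    clinics_ge12 = list(trial = c(0.54, 0.42, 0.71),
                        VRd = c(0.81, 0.51, 1.28), Vd = c(1.22, 0.66, 2.27)),
    patients_ge12 = list(trial = c(0.50, 0.35, 0.71),
                         VRd = c(0.73, 0.49, 1.10), Vd = c(1.23, 0.71, 2.12)),
    itt = list(trial = c(0.53, 0.42, 0.67),
               VRd = c(1.02, 0.84, 1.25), Vd = c(1.35, 1.09, 1.68)),
    age_ge_75 = list(trial = c(0.55, 0.40, 0.79),
                     VRd = c(0.69, 0.49, 0.97), Vd = c(1.08, 0.79, 1.47)),
    age_lt_75 = list(trial = c(0.55, 0.39, 0.78),
                     VRd = c(0.94, 0.67, 1.32), Vd = c(1.18, 0.81, 1.72)))
}

# published anchored ITC results, same rows: list(VRd = c(hr, lo, hi), Vd = ...)
published_itc <- function() {
  list(
    primary = list(VRd = c(0.68, 0.48, 0.98), Vd = c(0.48, 0.33, 0.69)),
    demographics = list(VRd = c(0.66, 0.46, 0.95), Vd = c(0.44, 0.31, 0.63)),
    doubly_robust = list(VRd = c(0.69, 0.48, 0.99), Vd = c(0.49, 0.33, 0.71)),
    clinics_ge12 = list(VRd = c(0.67, 0.23, 0.85), Vd = c(0.45, 0.23, 0.85)),
    patients_ge12 = list(VRd = c(0.69, 0.40, 1.17), Vd = c(0.41, 0.22, 0.78)),
    itt = list(VRd = c(0.52, 0.38, 0.70), Vd = c(0.39, 0.28, 0.54)),
    age_ge_75 = list(VRd = c(0.80, 0.51, 1.26), Vd = c(0.51, 0.33, 0.79)),
    age_lt_75 = list(VRd = c(0.58, 0.37, 0.91), Vd = c(0.46, 0.28, 0.76)))
}
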