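# Shared fixtures and independent oracles used across the suite.

default_cfg <- experiment_config()

two_element_truth <- tibble::tibble(E_kpa = c(1.2, 0.6), tau_s = c(0.5, 20))

make_curve <- function(elements, E_inf_kpa = 0, noise_sigma = 0, seed = 1,
                       config = default_cfg, collapse_time_s = NULL) {
  gel <- gel_spec(elements, E_inf_kpa = E_inf_kpa, noise_sigma = noise_sigma,
                  collapse_time_s = collapse_time_s, seed = seed)
  simulate_relaxation_curve(gel, config)
}

# Closed-form OLS via the normal equations, independent of lm().
ols_slope_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  list(slope = slope, intercept = yb - slope * xb)
}

# Exhaustive single-element grid search over a log-spaced (E, tau) grid.
# chi2(E, tau) = sum((y - E exp(-t/tau))^2) evaluated at every grid node.
grid_search_one_element <- function(curve, E_range, tau_range, n_grid = 400) {
  E_grid <- exp(seq(log(E_range[1]), log(E_range[2]), length.out = n_grid))
  tau_grid <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))
  X <- exp(-outer(curve$t_s, tau_grid, `/`))
  Sxy <- colSums(X * curve$Et_kpa)
  Sxx <- colSums(X^2)
  Syy <- sum(curve$Et_kpa^2)
  chi2 <- Syy - 2 * outer(E_grid, Sxy) + outer(E_grid^2, Sxx)
  k <- arrayInd(which.min(chi2), dim(chi2))
  list(E = E_grid[k[1]], tau = tau_grid[k[2]],
       log_step_E = log(E_grid[2] / E_grid[1]),
       log_step_tau = log(tau_grid[2] / tau_grid[1]))
}

# Independent pooled-variance one-tailed t computation via the t CDF.
t_oracle <- function(a, b, direction) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- if (direction == "greater") pt(tt, df, lower.tail = FALSE)
       else pt(tt, df)
  list(statistic = tt, df = df, p = p)
}
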