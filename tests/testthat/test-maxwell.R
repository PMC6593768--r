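test_that("prony_predict matches closed forms", {
  el <- tibble::tibble(E_kpa = 2, tau_s = 5)
  # t = 0: exponentials are all 1
  expect_identical(prony_predict(0, el, E_inf_kpa = 0.3), 2.3)
  expect_equal(prony_predict(5, el), 2 * exp(-1), tolerance = 1e-12)
  # far beyond the slowest element only the equilibrium term remains
  expect_equal(prony_predict(1000, tibble::tibble(E_kpa = c(1, 2),
                                                  tau_s = c(1, 10)),
                             E_inf_kpa = 0.3),
               0.3, tolerance = 1e-12)
  expect_error(prony_predict(1, tibble::tibble(E_kpa = 1, tau_s = 0)),
               class = "gelrelax_validation_error")
})

test_that("prony_predict is monotone non-increasing for non-negative elements", {
  t <- seq(0, 100, by = 0.5)
  for (seed in 1:10) {
    el <- withr::with_seed(seed, {
      k <- sample(1:3, 1)
      tibble::tibble(E_kpa = runif(k, 0, 3), tau_s = 10^runif(k, -1, 2))
    })
    expect_true(all(diff(prony_predict(t, el, E_inf_kpa = 0.1)) <= 1e-12))
  }
})

test_that("chi_squared is the sum of squared residuals", {
  cv <- make_curve(two_element_truth, noise_sigma = 0)
  perfect <- list(elements = two_element_truth, E_inf_kpa = 0)
  expect_equal(chi_squared(perfect, cv), 0, tolerance = 1e-20)
  # constant residual r at n points -> n r^2
  shifted <- list(elements = two_element_truth, E_inf_kpa = 0.25)
  expect_equal(chi_squared(shifted, cv), nrow(cv) * 0.25^2, tolerance = 1e-9)
  # brute-force loop oracle against the zero model
  noisy <- make_curve(two_element_truth, noise_sigma = 0.05, seed = 7)
  zero <- list(elements = tibble::tibble(E_kpa = double(), tau_s = double()),
               E_inf_kpa = 0)
  acc <- 0
  for (k in seq_len(nrow(noisy))) acc <- acc + noisy$Et_kpa[k]^2
  expect_equal(chi_squared(zero, noisy), acc, tolerance = 1e-12)
  # weights hook
  w <- rep(2, nrow(cv))
  expect_equal(chi_squared(shifted, cv, weights = w),
               2 * chi_squared(shifted, cv), tolerance = 1e-12)
})

test_that("fixed-order fits recover noiseless generator parameters", {
  one <- tibble::tibble(E_kpa = 1.81, tau_s = 5)
  f1 <- fit_fixed_order(make_curve(one, noise_sigma = 0), 1, seed = 1)
  expect_true(f1$converged)
  expect_equal(f1$elements$E_kpa, 1.81, tolerance = 1e-6)
  expect_equal(f1$elements$tau_s, 5, tolerance = 1e-6)

  f2 <- fit_fixed_order(make_curve(two_element_truth, noise_sigma = 0), 2,
                        seed = 1)
  expect_equal(f2$elements$E_kpa, two_element_truth$E_kpa, tolerance = 1e-4)
  expect_equal(f2$elements$tau_s, two_element_truth$tau_s, tolerance = 1e-4)
  # elements come back sorted by ascending tau
  expect_true(!is.unsorted(f2$elements$tau_s))
})

test_that("an equilibrium spring is recovered when present", {
  el <- tibble::tibble(E_kpa = 1.5, tau_s = 8)
  cv <- make_curve(el, E_inf_kpa = 0.4, noise_sigma = 0.005, seed = 11)
  f <- fit_fixed_order(cv, 1, e_inf = "free", seed = 2)
  expect_equal(f$E_inf_kpa, 0.4, tolerance = 0.05)
  expect_equal(f$elements$E_kpa, 1.5, tolerance = 0.05)
})

test_that("single-element fits agree with an exhaustive log-grid search", {
  for (seed in 1:3) {
    truth <- withr::with_seed(seed, {
      tibble::tibble(E_kpa = runif(1, 0.5, 3), tau_s = 10^runif(1, -0.5, 1.5))
    })
    cv <- make_curve(truth, noise_sigma = 0.01, seed = 100 + seed)
    fit <- fit_fixed_order(cv, 1, e_inf = "zero", seed = seed)
    grid <- grid_search_one_element(cv, E_range = c(0.1, 10),
                                    tau_range = c(0.05, 500))
    expect_lte(abs(log(fit$elements$E_kpa) - log(grid$E)), grid$log_step_E)
    expect_lte(abs(log(fit$elements$tau_s) - log(grid$tau)), grid$log_step_tau)
  }
})

test_that("fits are bit-identical given identical curve, seed and options", {
  cv <- make_curve(two_element_truth, noise_sigma = 0.01, seed = 5)
  expect_identical(fit_fixed_order(cv, 2, seed = 42),
                   fit_fixed_order(cv, 2, seed = 42))
  expect_identical(select_order(cv, seed = 42), select_order(cv, seed = 42))
})

test_that("order selection stops when chi-squared improvement is insignificant", {
  # noiseless one-element curve: one element suffices
  cv1 <- make_curve(tibble::tibble(E_kpa = 2, tau_s = 5), noise_sigma = 0)
  s1 <- select_order(cv1, seed = 1)
  expect_equal(s1$n_elements, 1L)
  # noiseless decade-separated two-element curve: exactly two are kept
  cv2 <- make_curve(two_element_truth, noise_sigma = 0)
  s2 <- select_order(cv2, seed = 1)
  expect_equal(s2$n_elements, 2L)
  expect_true(all(diff(s2$selection_trace$chi2) <= 1e-12))
  # the selection trace records every order fitted
  expect_equal(s2$selection_trace$n, seq_len(nrow(s2$selection_trace)))
})

test_that("chi-squared is non-increasing along the selection trace", {
  for (seed in 1:5) {
    truth <- withr::with_seed(seed, {
      k <- sample(2:3, 1)
      tibble::tibble(E_kpa = runif(k, 0.3, 2), tau_s = sort(10^runif(k, -1, 2)))
    })
    cv <- make_curve(truth, noise_sigma = 0.02, seed = 200 + seed)
    s <- select_order(cv, max_n = 4, epsilon = 0, seed = seed)
    expect_true(all(diff(s$selection_trace$chi2) <= 1e-8 * s$selection_trace$chi2[1]))
  }
})

test_that("relative importance normalizes element stiffnesses to percent", {
  fake <- function(E) list(elements = tibble::tibble(E_kpa = E,
                                                     tau_s = seq_along(E)))
  expect_equal(relative_importance(fake(c(3, 1))), c(75, 25))
  expect_equal(relative_importance(fake(5)), 100)
  expect_equal(relative_importance(fake(c(1, 1, 2))), c(25, 25, 50))
  expect_error(relative_importance(fake(c(0, 0))), class = "gelrelax_ri_error")
  # sums to 100 within 1e-9 for fitted models
  for (seed in 1:5) {
    cv <- make_curve(two_element_truth, noise_sigma = 0.01, seed = seed)
    f <- fit_fixed_order(cv, 2, seed = seed)
    expect_equal(sum(f$relative_importance), 100, tolerance = 1e-9)
  }
})

test_that("elements classify into the tau taxonomy with left-closed bins", {
  fake <- list(elements = tibble::tibble(E_kpa = rep(1, 5),
                                         tau_s = c(0.4, 1, 5, 100, 150)))
  got <- classify_elements(fake)
  expect_equal(as.character(got$label),
               c("sub_second_fluid", "ecm_1_10s", "ecm_1_10s",
                 "slow_10_100s", "out_of_range"))
  # tau = 10 falls in the slow bin (left-closed convention)
  fake10 <- list(elements = tibble::tibble(E_kpa = 1, tau_s = 10))
  expect_equal(as.character(classify_elements(fake10)$label), "slow_10_100s")
})

test_that("collapse QC flags failed measurements and passes clean ones", {
  cfg <- experiment_config()
  # simulated collapse at t = 3 s is flagged
  collapsed <- make_curve(two_element_truth, noise_sigma = 0.01,
                          collapse_time_s = 3, seed = 21)
  expect_true(qc_flag_collapse(collapsed)$collapsed)
  # clean two-element simulation is not
  clean <- make_curve(two_element_truth, noise_sigma = 0.01, seed = 22)
  expect_false(qc_flag_collapse(clean)$collapsed)
  # an all-zero curve is degenerate and flagged
  t <- seq(0, 100, by = 0.1)
  expect_true(qc_flag_collapse(relaxation_curve(t, 0 * t, 0.2))$collapsed)
  # a non-converged fit flags the measurement
  fakefit <- list(converged = FALSE)
  expect_true(qc_flag_collapse(clean, fakefit)$collapsed)
  expect_match(qc_flag_collapse(clean, fakefit)$reason, "converge")
})

test_that("tidy, glance and augment expose the fit as tables", {
  cv <- make_curve(two_element_truth, noise_sigma = 0.01, seed = 3)
  f <- select_order(cv, seed = 3)
  td <- tidy(f)
  expect_named(td, c("element", "E_kpa", "tau_s", "relative_importance",
                     "class"))
  expect_equal(nrow(td), f$n_elements)
  gl <- glance(f)
  expect_equal(gl$E0_kpa, f$E_inf_kpa + sum(f$elements$E_kpa))
  au <- augment(f)
  expect_equal(au$.resid, au$Et_kpa - au$.fitted)
  expect_equal(sum(au$.resid^2), f$chi2, tolerance = 1e-10)
})
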