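test_that("summaries report mean, sample SD and SEM", {
  got <- summarize_metric(data.frame(x = c(1, 2, 3)), x)
  expect_equal(got$mean, 2)
  expect_equal(got$sd, 1)
  expect_equal(got$sem, 1 / sqrt(3))
  expect_true(got$dispersion_defined)

  # single observation: dispersion undefined and flagged
  one <- summarize_metric(data.frame(x = 5), x)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd) && is.na(one$sem))
  expect_false(one$dispersion_defined)

  # SEM * sqrt(n) = SD on grouped summaries
  d <- data.frame(g = rep(c("a", "b"), c(4, 6)), x = c(1:4, 2:7))
  s <- summarize_metric(d, x, by = g)
  expect_equal(s$sem * sqrt(s$n), s$sd)

  expect_error(summarize_metric(data.frame(x = double()), x),
               class = "gelrelax_empty_group_error")
})

test_that("the sample mean of seeded normal draws lands within 3 SEM", {
  d <- withr::with_seed(1234, data.frame(x = rnorm(1000, 1.81, 0.1)))
  s <- summarize_metric(d, x)
  expect_lt(abs(s$mean - 1.81), 3 * s$sem)
})

test_that("one-tailed t test matches the independent t-CDF oracle", {
  for (seed in 1:10) {
    d <- withr::with_seed(seed, list(a = rnorm(8, 1, 0.5),
                                     b = rnorm(11, 1.3, 0.7)))
    for (dir in c("greater", "less")) {
      got <- t_test_one_tailed(d$a, d$b, direction = dir)
      want <- t_oracle(d$a, d$b, dir)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$df, want$df)
      expect_equal(got$p_value, want$p, tolerance = 1e-10)
    }
  }
})

test_that("one-tailed t test has the textbook symmetries", {
  a <- c(1, 2, 3)
  b <- a + 10
  # strongly separated groups in the tested direction
  expect_lt(t_test_one_tailed(a, b, "less")$p_value, 0.001)
  # identical groups: t = 0, p = 0.5 by symmetry (degenerate, flagged)
  same <- t_test_one_tailed(c(1, 1, 1), c(1, 1, 1), "greater")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  expect_true(same$degenerate)
  # one-tailed p is half the two-tailed p when t is in the tested direction
  d <- withr::with_seed(77, list(a = rnorm(10, 2), b = rnorm(10, 1)))
  one <- t_test_one_tailed(d$a, d$b, "greater")
  two <- stats::t.test(d$a, d$b, var.equal = TRUE)$p.value
  expect_equal(one$p_value, two / 2, tolerance = 1e-12)
  # antisymmetry: p(greater) + p(less) = 1 for continuous data
  expect_equal(t_test_one_tailed(d$a, d$b, "greater")$p_value +
                 t_test_one_tailed(d$a, d$b, "less")$p_value, 1,
               tolerance = 1e-12)
  # Welch variant is selectable
  w <- t_test_one_tailed(d$a, d$b, "greater", var_equal = FALSE)
  expect_equal(w$p_value,
               stats::t.test(d$a, d$b, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("cohort reports count, summarise and exclude correctly", {
  cfg <- experiment_config()
  spec <- cohort_spec(group = "NAM", n_donors = 2, n_pregels = 2,
                      n_replicates = 2, p_third_element = 0, seed = 8)
  traces <- simulate_cohort(spec, cfg)
  res <- analyze_cohort(traces, cfg, seed = 8)
  expect_equal(nrow(res), 8)
  rep <- build_report(res, by = group)
  expect_equal(nrow(rep$samples), 8)
  expect_equal(nrow(rep$excluded), sum(res$collapsed))
  # exclusion bookkeeping: included + excluded = total
  expect_equal(sum(!rep$samples$collapsed) + nrow(rep$excluded),
               nrow(rep$samples))
  # one summary row per metric for the single group
  expect_equal(sum(rep$summary$metric == "E_kpa"), 1)
  expect_equal(rep$summary$n[rep$summary$metric == "E_kpa"],
               sum(!res$collapsed))
  # SEM consistency on emitted summaries
  ok <- rep$summary$dispersion_defined
  expect_equal(rep$summary$sem[ok] * sqrt(rep$summary$n[ok]),
               rep$summary$sd[ok])
  # elements table aligns with selected orders
  expect_equal(nrow(rep$elements),
               sum(res$n_elements, na.rm = TRUE))
})

test_that("an all-collapsed cohort yields an empty summary, not an error", {
  cfg <- experiment_config()
  spec <- cohort_spec(group = "DAM", n_donors = 1, n_pregels = 2,
                      n_replicates = 1, seed = 3)
  res <- analyze_cohort(simulate_cohort(spec, cfg), cfg, seed = 3)
  expect_true(all(res$collapsed))
  rep <- build_report(res, by = group)
  expect_equal(nrow(rep$summary), 0)
  expect_equal(nrow(rep$excluded), nrow(res))
})

test_that("plot builders return ggplot objects", {
  cv <- make_curve(two_element_truth, noise_sigma = 0.01, seed = 2)
  f <- select_order(cv, seed = 2)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(plot_ri_spectrum(tidy(f)), "ggplot")
})
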