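#' Evaluate a Prony series (generalized Maxwell model)
#'
#' The generalized Maxwell model describes stress relaxation as a parallel
#' combination of spring-dashpot (Maxwell) elements, optionally with an
#' equilibrium spring:
#' \deqn{E(t) = E_\infty + \sum_i E_i \exp(-t/\tau_i)}
#' where each element has stiffness \eqn{E_i} (kPa) and relaxation time
#' constant \eqn{\tau_i} (s).
#'
#' @param t Times in seconds (>= 0).
#' @param elements Data frame with columns `E_kpa` and `tau_s`.
#' @param E_inf_kpa Equilibrium stiffness in kPa (default 0).
#' @return Numeric vector of E(t) in kPa.
#' @examples
#' prony_predict(c(0, 5), tibble::tibble(E_kpa = 2, tau_s = 5)) # 2, 2/e
#' @export
prony_predict <- function(t, elements, E_inf_kpa = 0) {
  elements <- as_tibble(elements)
  if (nrow(elements) > 0 && any(elements$tau_s <= 0)) {
    abort("All relaxation time constants must be > 0.",
          class = "gelrelax_validation_error")
  }
  if (nrow(elements) == 0) {
    return(rep(E_inf_kpa, length(t)))
  }
  E_inf_kpa + as.vector(exp(-outer(t, elements$tau_s, `/`)) %*% elements$E_kpa)
}

#' Chi-squared error function of a Maxwell fit
#'
#' The unweighted sum of squared residuals between the measured relaxing
#' stiffness and the model prediction,
#' \eqn{\chi^2 = \sum_k (E(t_k) - \hat E(t_k))^2}.  An optional weight vector
#' turns it into a weighted sum (off by default; no measurement variances are
#' assumed).
#'
#' @param fit A [maxwell_fit][fit_fixed_order], or a list with `elements` and
#'   `E_inf_kpa`.
#' @param curve A [relaxation_curve()].
#' @param weights Optional non-negative weights, one per sample.
#' @return The chi-squared value (kPa^2).
#' @export
chi_squared <- function(fit, curve, weights = NULL) {
  pred <- prony_predict(curve$t_s, fit$elements, fit$E_inf_kpa %||% 0)
  r <- curve$Et_kpa - pred
  w <- weights %||% rep(1, length(r))
  sum(w * r^2)
}

# Default tau initializations: log-spaced over the observed decade range.
tau_init_grid <- function(n, tau_init_range) {
  lo <- log(tau_init_range[[1]])
  hi <- log(tau_init_range[[2]])
  if (n == 1) exp((lo + hi) / 2) else exp(seq(lo, hi, length.out = n))
}

#' Fit a generalized Maxwell model with a fixed number of elements
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) minimizing [chi_squared()] subject to
#' \eqn{E_i \ge 0}, \eqn{\tau_i \in} `tau_bounds`, and \eqn{E_\infty \ge 0}
#' (or fixed to 0 with `e_inf = "zero"`).  The optimizer is multi-started
#' from log-spaced time-constant initializations with seeded jitter, so the
#' result is deterministic given `seed`.  Elements are returned sorted by
#' ascending time constant, so the "first" element is the fastest.
#'
#' @param curve A [relaxation_curve()] with more than `3 n + 1` samples.
#' @param n Number of Maxwell elements (>= 1).
#' @param e_inf `"free"` (equilibrium stiffness fitted, bounded at 0) or
#'   `"zero"` (no equilibrium term).
#' @param n_starts Number of multi-start initializations.
#' @param seed Integer seed for the start jitter.
#' @param tau_bounds Lower/upper bounds on time constants, seconds.
#' @param tau_init_range Range over which starting time constants are
#'   log-spaced, seconds.
#' @param weights Optional per-sample weights for the error function.
#' @param extra_starts Optional list of additional full start vectors
#'   (`c(E_1..E_n, tau_1..tau_n, [E_inf])`), used internally by
#'   [select_order()] to warm-start from the previous order.
#' @return An object of class `maxwell_fit`: a list with `elements` (tibble
#'   `E_kpa`, `tau_s`, ascending tau), `E_inf_kpa`, `chi2`, `n_elements`,
#'   `relative_importance` (percent, summing to 100), `converged`,
#'   `selection_trace` (`NULL` unless produced by [select_order()]), `seed`,
#'   and the fitted `curve`.
#' @export
fit_fixed_order <- function(curve, n, e_inf = c("free", "zero"),
                            n_starts = 10, seed = 1L,
                            tau_bounds = c(1e-3, 1e4),
                            tau_init_range = c(0.1, 100),
                            weights = NULL, extra_starts = NULL) {
  e_inf <- match.arg(e_inf)
  n <- as.integer(n)
  if (n < 1) abort("`n` must be >= 1.", class = "gelrelax_validation_error")
  t <- curve$t_s
  y <- curve$Et_kpa
  if (length(t) <= 3 * n + 1) {
    abort(sprintf("Need more than %d samples to fit %d elements.", 3 * n + 1, n),
          class = "gelrelax_validation_error")
  }
  free_einf <- e_inf == "free"
  sw <- sqrt(weights %||% rep(1, length(y)))
  lower <- c(rep(0, n), rep(tau_bounds[[1]], n), if (free_einf) 0)
  upper <- c(rep(Inf, n), rep(tau_bounds[[2]], n), if (free_einf) Inf)
  resid_fn <- function(p) {
    pred <- as.vector(exp(-outer(t, p[n + seq_len(n)], `/`)) %*% p[seq_len(n)])
    if (free_einf) pred <- pred + p[[2 * n + 1]]
    sw * (y - pred)
  }

  E0 <- max(y[[1]], 1e-8)
  tau0 <- tau_init_grid(n, tau_init_range)
  einf0 <- if (free_einf) max(min(y), 0)
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1) {
        c(rep(E0 / n, n), tau0, einf0)
      } else {
        c(rep(E0 / n, n) * exp(rnorm(n, 0, 0.3)),
          pmin(pmax(tau0 * exp(rnorm(n, 0, 0.5)), tau_bounds[[1]]),
               tau_bounds[[2]]),
          einf0)
      }
    })
  })
  starts <- c(starts, extra_starts)

  runs <- lapply(starts, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
  })
  chi2s <- map_dbl(runs, function(r) if (is.null(r)) Inf else sum(r$fvec^2))
  convs <- map_lgl(runs, function(r) !is.null(r) && r$info %in% 1:4)
  best <- if (any(convs)) {
    which(convs)[which.min(chi2s[convs])]
  } else {
    which.min(chi2s)
  }
  p <- runs[[best]]$par
  ord <- order(p[n + seq_len(n)])
  elements <- tibble(E_kpa = p[seq_len(n)][ord], tau_s = p[n + seq_len(n)][ord])
  fit <- structure(
    list(
      elements = elements,
      E_inf_kpa = if (free_einf) p[[2 * n + 1]] else 0,
      chi2 = chi2s[[best]],
      n_elements = n,
      relative_importance = NULL,
      converged = any(convs),
      selection_trace = NULL,
      seed = as.integer(seed),
      curve = curve,
      options = list(e_inf = e_inf, n_starts = n_starts,
                     tau_bounds = tau_bounds, tau_init_range = tau_init_range,
                     weighted = !is.null(weights))
    ),
    class = "maxwell_fit"
  )
  fit$relative_importance <- if (sum(elements$E_kpa) > 0) {
    relative_importance(fit)
  } else {
    rep(NA_real_, n)
  }
  fit
}

#' Select the number of Maxwell elements by chi-squared improvement
#'
#' Fits models with 1, 2, ... elements sequentially and stops when adding an
#' element no longer gives a meaningful decrease of the chi-squared error
#' function.  With `criterion = "relative"` (default) the search stops at the
#' first order n where \eqn{(\chi^2_n - \chi^2_{n+1}) / \chi^2_n <}
#' `epsilon`; with `criterion = "ftest"` it stops when the extra-sum-of-
#' squares F test for the added element is not significant at `alpha`.  Each
#' higher-order fit is warm-started from the previous solution plus a
#' zero-stiffness element, so the recorded chi-squared sequence is
#' non-increasing.  A numerically perfect fit stops the search immediately.
#'
#' @inheritParams fit_fixed_order
#' @param max_n Maximum number of elements to consider.
#' @param epsilon Relative chi-squared improvement below which an added
#'   element is judged insignificant.
#' @param criterion `"relative"` or `"ftest"`.
#' @param alpha Significance level for the F-test criterion.
#' @return The [maxwell_fit][fit_fixed_order] at the selected order, with
#'   `selection_trace` (tibble of `n`, `chi2` for every order fitted).
#' @export
select_order <- function(curve, max_n = 4, epsilon = 0.05,
                         criterion = c("relative", "ftest"), alpha = 0.05,
                         e_inf = c("free", "zero"), n_starts = 10, seed = 1L,
                         tau_bounds = c(1e-3, 1e4),
                         tau_init_range = c(0.1, 100), weights = NULL) {
  criterion <- match.arg(criterion)
  e_inf <- match.arg(e_inf)
  if (max_n < 1) abort("`max_n` must be >= 1.",
                       class = "gelrelax_validation_error")
  fit_n <- function(n, extra_starts = NULL) {
    fit_fixed_order(curve, n, e_inf = e_inf, n_starts = n_starts,
                    seed = seed + n, tau_bounds = tau_bounds,
                    tau_init_range = tau_init_range, weights = weights,
                    extra_starts = extra_starts)
  }
  # Chi-squared at machine level relative to the signal counts as perfect.
  perfect <- 1e-16 * sum(curve$Et_kpa^2)
  free_einf <- e_inf == "free"

  fits <- list(fit_n(1L))
  trace <- tibble(n = 1L, chi2 = fits[[1]]$chi2)
  chosen <- 1L
  n <- 1L
  while (n < max_n) {
    cur <- fits[[n]]
    if (cur$chi2 <= perfect) break
    warm <- c(cur$elements$E_kpa, 0,
              cur$elements$tau_s, tau_init_grid(1, tau_init_range),
              if (free_einf) cur$E_inf_kpa)
    nxt <- fit_n(n + 1L, extra_starts = list(warm))
    trace <- bind_rows(trace, tibble(n = n + 1L, chi2 = nxt$chi2))
    fits[[n + 1L]] <- nxt
    stop_here <- if (criterion == "relative") {
      (cur$chi2 - nxt$chi2) / cur$chi2 < epsilon
    } else {
      npar <- 2 * (n + 1) + as.integer(free_einf)
      df2 <- length(curve$t_s) - npar
      f <- ((cur$chi2 - nxt$chi2) / 2) / (nxt$chi2 / df2)
      p <- pf(f, 2, df2, lower.tail = FALSE)
      is.na(p) || p > alpha
    }
    if (stop_here) {
      chosen <- n
      break
    }
    chosen <- n + 1L
    n <- n + 1L
  }
  out <- fits[[chosen]]
  out$selection_trace <- trace
  out
}

#' Relative importance of Maxwell elements
#'
#' The percentage contribution of each element's stiffness to the summed
#' element stiffnesses, \eqn{RI_i = 100 E_i / (E_1 + E_2 \dots E_n)}.  The
#' equilibrium term is excluded from the denominator.
#'
#' @param fit A [maxwell_fit][fit_fixed_order] (or list with an `elements`
#'   data frame).
#' @return Numeric vector of percentages, aligned with `fit$elements` and
#'   summing to 100.
#' @examples
#' relative_importance(list(elements = data.frame(E_kpa = c(3, 1),
#'                                                tau_s = c(1, 10))))
#' @export
relative_importance <- function(fit) {
  E <- fit$elements$E_kpa
  total <- sum(E)
  if (length(E) == 0 || total <= 0) {
    abort("All element stiffnesses are zero; relative importance undefined.",
          class = "gelrelax_ri_error")
  }
  100 * E / total
}

#' Classify Maxwell elements by relaxation time constant
#'
#' Elements are binned by their time constant into the taxonomy observed for
#' ECM-derived hydrogels: sub-second elements (interstitial fluid pushed out
#' of the gel), 1-10 s elements (the ECM network itself), 10-100 s elements
#' (a slow mode seen in the stiffest gels), and anything slower.  Bins are
#' left-closed: (0, 1), \[1, 10), \[10, 100\], (100, Inf).
#'
#' @param fit A [maxwell_fit][fit_fixed_order] (or list with `elements`).
#' @return Tibble with `element`, `tau_s`, and `label` (factor with levels
#'   `sub_second_fluid`, `ecm_1_10s`, `slow_10_100s`, `out_of_range`).
#' @export
classify_elements <- function(fit) {
  tau <- fit$elements$tau_s
  label <- dplyr::case_when(
    tau < 1 ~ "sub_second_fluid",
    tau < 10 ~ "ecm_1_10s",
    tau <= 100 ~ "slow_10_100s",
    TRUE ~ "out_of_range"
  )
  tibble(
    element = seq_along(tau),
    tau_s = tau,
    label = factor(label, levels = c("sub_second_fluid", "ecm_1_10s",
                                     "slow_10_100s", "out_of_range"))
  )
}

#' Flag collapsed gel measurements
#'
#' Some gels cannot sustain the constant-strain hold and collapse, yielding
#' no usable relaxation data; such measurements must be excluded from cohort
#' summaries.  A measurement is flagged as collapsed when any of:
#'
#' * the relaxing stiffness becomes non-positive before `early_fraction` of
#'   the hold has elapsed;
#' * the stiffness drops by more than `drop_fraction` between adjacent
#'   samples while still above `drop_floor` of its initial value (the floor
#'   keeps noise fluctuations in a fully relaxed tail from triggering);
#' * the Maxwell fit failed to converge at every order tried.
#'
#' @param curve A [relaxation_curve()].
#' @param fit Optional [maxwell_fit][fit_fixed_order] for the same curve.
#' @param early_fraction Fraction of the hold defining "early" (default 0.1).
#' @param drop_fraction Adjacent-sample fractional drop that counts as abrupt
#'   (default 0.5).
#' @param drop_floor Fraction of E(0) below which drops are ignored
#'   (default 0.1).
#' @return A one-row tibble: `collapsed` (logical) and `reason` (string, `NA`
#'   if clean).
#' @export
qc_flag_collapse <- function(curve, fit = NULL, early_fraction = 0.1,
                             drop_fraction = 0.5, drop_floor = 0.1) {
  Et <- curve$Et_kpa
  t <- curve$t_s
  t_end <- max(t)
  reasons <- character()
  if (any(Et[t <= early_fraction * t_end] <= 0)) {
    reasons <- c(reasons, sprintf(
      "non-positive stiffness before %.0f%% of the hold", 100 * early_fraction))
  }
  Et0 <- Et[[1]]
  if (length(Et) >= 2 && Et0 > 0) {
    head_Et <- Et[-length(Et)]
    drop <- (head_Et - Et[-1]) / head_Et
    if (any(head_Et >= drop_floor * Et0 & drop > drop_fraction)) {
      reasons <- c(reasons, sprintf(
        "abrupt >%.0f%% drop between adjacent samples", 100 * drop_fraction))
    }
  }
  if (!is.null(fit) && !isTRUE(fit$converged)) {
    reasons <- c(reasons, "Maxwell fit did not converge at any order")
  }
  tibble(
    collapsed = length(reasons) > 0,
    reason = if (length(reasons) > 0) paste(reasons, collapse = "; ")
             else NA_character_
  )
}

#' @export
print.maxwell_fit <- function(x, ...) {
  cat(sprintf("<maxwell_fit> %d element(s)%s, chi2 = %.4g%s\n",
              x$n_elements,
              if (x$options$e_inf == "free") " + equilibrium term" else "",
              x$chi2,
              if (x$converged) "" else " (NOT converged)"))
  df <- as.data.frame(x$elements)
  df$RI_pct <- x$relative_importance
  print(df, digits = 4)
  cat(sprintf("E_inf = %.4g kPa\n", x$E_inf_kpa))
  if (!is.null(x$selection_trace)) {
    cat("selection trace (n : chi2): ",
        paste(sprintf("%d : %.4g", x$selection_trace$n,
                      x$selection_trace$chi2), collapse = ", "), "\n")
  }
  invisible(x)
}
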