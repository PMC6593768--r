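#' Instantaneous stiffness from the compression ramp
#'
#' The stiffness E is the ordinary least-squares slope of stress against
#' strain over the ramp phase.  An intercept is fitted (and reported) so the
#' slope is insensitive to a touch-load offset at contact; set
#' `intercept = FALSE` to force the line through the origin.
#'
#' @param ss A [segment_phases()] result (or any data frame with `stress_pa`,
#'   `strain`, `phase` columns).
#' @param intercept Fit an intercept? Default `TRUE`.
#' @return A one-row tibble of class `stiffness_result`: `E_kpa` (slope, kPa),
#'   `intercept_kpa`, `r2`, `n_points`.
#' @export
fit_stiffness <- function(ss, intercept = TRUE) {
  d <- ss[ss$phase == "ramp", , drop = FALSE]
  if (nrow(d) < 2 || length(unique(d$strain)) < 2) {
    abort("Ramp has fewer than 2 distinct strain values; cannot fit a slope.",
          class = "gelrelax_degenerate_ramp_error")
  }
  stress_kpa <- d$stress_pa / 1000
  fit <- if (intercept) lm(stress_kpa ~ d$strain) else lm(stress_kpa ~ d$strain + 0)
  slope <- unname(coef(fit)[[if (intercept) 2 else 1]])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- tibble(
    E_kpa = slope,
    intercept_kpa = if (intercept) unname(coef(fit)[[1]]) else 0,
    r2 = if (is.finite(r2)) r2 else NA_real_,
    n_points = nrow(d)
  )
  class(out) <- c("stiffness_result", class(out))
  out
}

#' Construct a relaxation curve
#'
#' A relaxation curve is the relaxing stiffness E(t) over the constant-strain
#' hold, with time zeroed at the start of the hold.
#'
#' @param t_s Sample times in seconds (rebased so the first sample is 0).
#' @param Et_kpa Relaxing stiffness in kPa.
#' @param strain0 Constant strain of the hold (> 0).
#' @return A tibble of class `relaxation_curve` with columns `t_s`, `Et_kpa`
#'   and attribute `strain0`.
#' @export
relaxation_curve <- function(t_s, Et_kpa, strain0) {
  if (length(t_s) == 0 || length(t_s) != length(Et_kpa)) {
    abort("`t_s` and `Et_kpa` must be non-empty and of equal length.",
          class = "gelrelax_validation_error")
  }
  if (!is.finite(strain0) || strain0 <= 0) {
    abort("`strain0` must be a positive number.",
          class = "gelrelax_validation_error")
  }
  if (!all(is.finite(Et_kpa))) {
    abort("`Et_kpa` must be finite.", class = "gelrelax_validation_error")
  }
  out <- tibble(t_s = as.double(t_s - t_s[[1]]), Et_kpa = as.double(Et_kpa))
  attr(out, "strain0") <- strain0
  class(out) <- c("relaxation_curve", class(out))
  out
}

#' Relaxing stiffness over the hold phase
#'
#' Divides the hold-phase relaxing stress by the constant hold strain to give
#' the relaxing stiffness E(t), and rebases time to the start of the hold.
#'
#' @param ss A [segment_phases()] result.
#' @return A [relaxation_curve()] in kPa.
#' @export
relaxing_stiffness <- function(ss) {
  d <- ss[ss$phase == "hold", , drop = FALSE]
  if (nrow(d) == 0) {
    abort("Trace has no hold phase.", class = "gelrelax_validation_error")
  }
  strain0 <- d$strain[[1]]
  if (!is.finite(strain0) || strain0 <= 0) {
    abort("Hold strain is zero; relaxing stiffness undefined.",
          class = "gelrelax_division_error")
  }
  relaxation_curve(d$time_s, d$stress_pa / strain0 / 1000, strain0)
}

#' Total relaxation over the hold
#'
#' The percentage drop of the relaxing stiffness from the start of the hold
#' to its end: \eqn{TR = 100 (E(0) - E(t_{end})) / E(0)}, with E(0) taken as
#' the first hold sample.
#'
#' @param curve A [relaxation_curve()].
#' @return Total relaxation in percent.
#' @examples
#' # a tau = 20 s element relaxes by 100 (1 - exp(-5)) ~ 99.33% over 100 s
#' t <- seq(0, 100, by = 0.1)
#' total_relaxation(relaxation_curve(t, 2 * exp(-t / 20), 0.2))
#' @export
total_relaxation <- function(curve) {
  Et0 <- curve$Et_kpa[[1]]
  if (!is.finite(Et0) || Et0 <= 0) {
    abort("E(0) <= 0: total relaxation undefined.",
          class = "gelrelax_relaxation_error")
  }
  100 * (Et0 - curve$Et_kpa[[nrow(curve)]]) / Et0
}
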