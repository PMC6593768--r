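#' Tidy a Maxwell fit into its elements
#'
#' @param x A [maxwell_fit][fit_fixed_order].
#' @param ... Unused.
#' @return A tibble with one row per Maxwell element: `element`, `E_kpa`,
#'   `tau_s`, `relative_importance` (percent), `class` (time-constant bin
#'   from [classify_elements()]).
#' @export
tidy.maxwell_fit <- function(x, ...) {
  cls <- classify_elements(x)
  tibble(
    element = cls$element,
    E_kpa = x$elements$E_kpa,
    tau_s = x$elements$tau_s,
    relative_importance = x$relative_importance,
    class = cls$label
  )
}

#' One-row summary of a Maxwell fit
#'
#' @param x A [maxwell_fit][fit_fixed_order].
#' @param ... Unused.
#' @return A one-row tibble: `n_elements`, `chi2`, `E_inf_kpa`, `E0_kpa`
#'   (instantaneous stiffness `E_inf + sum(E_i)`), `converged`.
#' @export
glance.maxwell_fit <- function(x, ...) {
  tibble(
    n_elements = x$n_elements,
    chi2 = x$chi2,
    E_inf_kpa = x$E_inf_kpa,
    E0_kpa = x$E_inf_kpa + sum(x$elements$E_kpa),
    converged = x$converged
  )
}

#' Augment the fitted curve with predictions and residuals
#'
#' @param x A [maxwell_fit][fit_fixed_order].
#' @param ... Unused.
#' @return The fitted relaxation curve with `.fitted` and `.resid` columns.
#' @export
augment.maxwell_fit <- function(x, ...) {
  pred <- prony_predict(x$curve$t_s, x$elements, x$E_inf_kpa)
  tibble(t_s = x$curve$t_s, Et_kpa = x$curve$Et_kpa,
         .fitted = pred, .resid = x$curve$Et_kpa - pred)
}
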