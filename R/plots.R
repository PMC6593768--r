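#' Plot a relaxation curve
#'
#' @param object A [relaxation_curve()].
#' @param ... Unused.
#' @return A ggplot of relaxing stiffness against hold time.
#' @export
autoplot.relaxation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s, y = .data$Et_kpa)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::labs(x = "Time in hold (s)", y = "Relaxing stiffness E(t) (kPa)") +
    ggplot2::theme_minimal()
}

#' Plot a Maxwell fit over its data
#'
#' Shows the measured relaxing stiffness, the fitted Prony series, and each
#' element's individual decay.
#'
#' @param object A [maxwell_fit][fit_fixed_order].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maxwell_fit <- function(object, ...) {
  aug <- augment(object)
  comp <- tidy(object) |>
    mutate(curve = purrr::map2(.data$E_kpa, .data$tau_s, function(E, tau) {
      tibble(t_s = aug$t_s, Et_kpa = E * exp(-aug$t_s / tau))
    })) |>
    select("element", "curve") |>
    tidyr::unnest("curve") |>
    mutate(element = factor(.data$element))
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$Et_kpa),
                        size = 0.4, alpha = 0.3) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$Et_kpa, colour = .data$element),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "black") +
    ggplot2::labs(x = "Time in hold (s)", y = "Relaxing stiffness (kPa)",
                  colour = "Element") +
    ggplot2::theme_minimal()
}

#' Relative-importance spectrum of fitted Maxwell elements
#'
#' Scatter of each element's relative importance against its relaxation time
#' constant (log scale) across a set of fits — the standard way to survey
#' which relaxation modes dominate a cohort.
#'
#' @param elements A tibble of tidied elements (e.g. the `elements` table of
#'   a [build_report()] result), with columns `tau_s`,
#'   `relative_importance`, and optionally `sample_id`.
#' @return A ggplot.
#' @export
plot_ri_spectrum <- function(elements) {
  mapping <- if ("sample_id" %in% names(elements)) {
    ggplot2::aes(x = .data$tau_s, y = .data$relative_importance,
                 colour = .data$sample_id)
  } else {
    ggplot2::aes(x = .data$tau_s, y = .data$relative_importance)
  }
  ggplot2::ggplot(elements, mapping) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Relaxation time constant tau (s)",
                  y = "Relative importance (%)", colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Per-group stiffness plot
#'
#' Jittered per-sample stiffness with group means, excluding collapsed
#' measurements.
#'
#' @param results An [analyze_cohort()] tibble with a `group` column.
#' @return A ggplot.
#' @export
plot_group_stiffness <- function(results) {
  d <- results |> filter(!.data$collapsed)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$E_kpa)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Stiffness E (kPa)") +
    ggplot2::theme_minimal()
}
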