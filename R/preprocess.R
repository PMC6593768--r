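#' Detect plunger-gel contact and compute gel thickness
#'
#' Contact is declared at the first sample where the force stays at or above
#' the touch load for `config$debounce_n` consecutive samples (a debounce
#' against force noise).  Gel thickness is the difference between the position
#' of the top of the glass slide (a calibration input, typically measured from
#' a blank run) and the plunger position at contact.
#'
#' @param trace A [raw_trace()] with force in newtons.
#' @param config An [experiment_config()]; `touch_load_mg` sets the threshold.
#' @param slide_position_um Position of the top of the glass slide, in um.
#' @return An object of class `contact_event`: a list with `index`,
#'   `touch_time_s`, `touch_position_um`, `slide_position_um`, `thickness_um`.
#' @export
detect_contact <- function(trace, config, slide_position_um) {
  stopifnot(inherits(config, "experiment_config"))
  threshold <- touch_load_n(config)
  above <- trace$force_n >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= config$debounce_n)
  if (length(hit) == 0) {
    abort(sprintf(
      "No sustained touch-load crossing (threshold %.3g N for %d samples).",
      threshold, config$debounce_n
    ), class = "gelrelax_contact_error")
  }
  index <- ends[hit[[1]]] - runs$lengths[hit[[1]]] + 1L
  touch_position <- trace$position_um[index]
  thickness <- slide_position_um - touch_position
  if (thickness < 0) {
    abort(sprintf(
      "Negative thickness (%.3g um): contact detected past the slide position.",
      thickness
    ), class = "gelrelax_geometry_error")
  }
  structure(
    list(
      index = index,
      touch_time_s = trace$time_s[index],
      touch_position_um = touch_position,
      slide_position_um = slide_position_um,
      thickness_um = thickness,
      threshold_n = threshold
    ),
    class = "contact_event"
  )
}

#' @export
print.contact_event <- function(x, ...) {
  cat("<contact_event>\n")
  cat(sprintf("  contact at sample %d (t = %.3g s, position %.4g um)\n",
              x$index, x$touch_time_s, x$touch_position_um))
  cat(sprintf("  thickness %.4g um (slide at %.4g um)\n",
              x$thickness_um, x$slide_position_um))
  invisible(x)
}

#' Segment a trace into phases and convert to stress and strain
#'
#' Splits a trace into approach (before contact), ramp (compression up to the
#' target deformation), hold (the constant-strain relaxation window of
#' `hold_duration_s` seconds) and post (anything after).  Force is converted
#' to stress by dividing by the plunger cross-section; deformation is
#' converted to engineering strain relative to the detected thickness.  The
#' hold-phase strain is taken as exactly `deformation_fraction` (the
#' idealized constant strain of the protocol).
#'
#' If the trace ends before the hold completes, the partial result is
#' returned with attribute `truncated = TRUE` and a warning of class
#' `gelrelax_truncated_warning`.
#'
#' @param trace A [raw_trace()].
#' @param contact A [detect_contact()] result.
#' @param config An [experiment_config()].
#' @return A tibble of class `stress_strain_trace` with columns `time_s`,
#'   `stress_pa`, `strain`, `phase` (factor: approach, ramp, hold, post) and
#'   attributes `contact`, `config`, `strain0`, `truncated`.
#' @export
segment_phases <- function(trace, contact, config) {
  stopifnot(inherits(contact, "contact_event"),
            inherits(config, "experiment_config"))
  idx <- contact$index
  travel <- trace$position_um - contact$touch_position_um
  target <- config$deformation_fraction * contact$thickness_um
  # Contact detection can land a few samples late under force noise, which
  # inflates the target relative to the plunger's actual travel plateau.
  # Accept the plateau as the hold start when it comes within 5% of the
  # target; a plunger that genuinely stopped short is still an error.
  plateau <- max(travel[seq_along(travel) >= idx])
  if (plateau < 0.95 * target) {
    abort("Trace never reaches the target deformation.",
          class = "gelrelax_validation_error")
  }
  target_eff <- min(target, plateau)
  reached <- which(seq_along(travel) >= idx & travel >= target_eff - 1e-9)
  j <- reached[[1]]
  hold_end <- trace$time_s[j] + config$hold_duration_s

  i <- seq_len(nrow(trace))
  phase <- dplyr::case_when(
    i < idx ~ "approach",
    i < j ~ "ramp",
    trace$time_s <= hold_end + 1e-9 ~ "hold",
    TRUE ~ "post"
  )
  strain <- dplyr::case_when(
    phase == "approach" ~ 0,
    phase == "ramp" ~ pmin(pmax(travel, 0) / contact$thickness_um,
                           config$deformation_fraction),
    TRUE ~ config$deformation_fraction
  )
  out <- tibble(
    time_s = trace$time_s,
    stress_pa = to_stress(trace$force_n, config),
    strain = strain,
    phase = factor(phase, levels = c("approach", "ramp", "hold", "post"))
  )
  truncated <- max(trace$time_s) < hold_end - 1e-9
  if (truncated) {
    warn(sprintf("Trace ends %.3g s before the hold completes; partial hold.",
                 hold_end - max(trace$time_s)),
         class = "gelrelax_truncated_warning")
  }
  attr(out, "contact") <- contact
  attr(out, "config") <- config
  attr(out, "strain0") <- config$deformation_fraction
  attr(out, "truncated") <- truncated
  class(out) <- c("stress_strain_trace", class(out))
  out
}

#' Convert force to stress
#'
#' Stress is force divided by the plunger cross-section
#' \eqn{A = \pi (d/2)^2} with the diameter in metres.
#'
#' @param force_n Force in newtons.
#' @param config An [experiment_config()] providing the plunger diameter.
#' @return Stress in pascals.
#' @examples
#' cfg <- experiment_config()
#' to_stress(4.908739e-6, cfg) # ~1 Pa for a 0.25-cm plunger
#' @export
to_stress <- function(force_n, config) {
  force_n / plunger_area_m2(config)
}

#' Convert percent deformation to engineering strain
#'
#' @param deformation_percent Deformation in percent, in \[0, 100\].
#' @return Dimensionless strain (deformation / 100).
#' @examples
#' to_strain(20) # 0.2
#' @export
to_strain <- function(deformation_percent) {
  if (any(!is.finite(deformation_percent)) ||
      any(deformation_percent < 0) || any(deformation_percent > 100)) {
    abort("`deformation_percent` must lie in [0, 100].",
          class = "gelrelax_validation_error")
  }
  deformation_percent / 100
}
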