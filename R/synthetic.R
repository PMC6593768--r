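#' Ground-truth specification of a synthetic gel
#'
#' Defines the material (Prony-series parameters), geometry, noise and
#' failure mode of a simulated stress-relaxation measurement, so that every
#' pipeline stage can be tested by parameter recovery against known truth.
#'
#' @param elements Data frame with columns `E_kpa`, `tau_s`: the ground-truth
#'   Maxwell elements.
#' @param E_inf_kpa Equilibrium stiffness in kPa.
#' @param thickness_um Gel thickness in um (the casting-ring height; default
#'   800, i.e. a 0.8-mm ring).
#' @param noise_sigma Additive Gaussian stress noise, expressed as a fraction
#'   of the instantaneous stiffness `E(0)` (on the stiffness scale; the
#'   stress-noise standard deviation is `noise_sigma * E(0) * strain`).
#' @param collapse_time_s Seconds into the hold at which the gel collapses
#'   (force decays abruptly to baseline), or `NULL` for a gel that survives.
#' @param seed Integer seed making the simulated measurement reproducible.
#' @return An object of class `gel_spec`.
#' @export
gel_spec <- function(elements, E_inf_kpa = 0, thickness_um = 800,
                     noise_sigma = 0.01, collapse_time_s = NULL, seed = 1L) {
  elements <- as_tibble(elements)
  stopifnot(all(c("E_kpa", "tau_s") %in% names(elements)))
  if (any(elements$E_kpa < 0) || any(elements$tau_s <= 0)) {
    abort("Element stiffnesses must be >= 0 and time constants > 0.",
          class = "gelrelax_validation_error")
  }
  if (thickness_um <= 0 || noise_sigma < 0 || E_inf_kpa < 0) {
    abort("`thickness_um` must be > 0, `noise_sigma` and `E_inf_kpa` >= 0.",
          class = "gelrelax_validation_error")
  }
  if (!is.null(collapse_time_s) && collapse_time_s <= 0) {
    abort("`collapse_time_s` must be positive (seconds into the hold).",
          class = "gelrelax_validation_error")
  }
  structure(
    list(elements = elements, E_inf_kpa = E_inf_kpa,
         thickness_um = thickness_um, noise_sigma = noise_sigma,
         collapse_time_s = collapse_time_s, seed = as.integer(seed)),
    class = "gel_spec"
  )
}

# Instantaneous stiffness E(0) of a gel spec, kPa.
gel_E0 <- function(gel) gel$E_inf_kpa + sum(gel$elements$E_kpa)

# Hold-phase relaxing-stiffness signal with optional collapse, kPa.
hold_signal_kpa <- function(gel, t_hold) {
  sig <- prony_predict(t_hold, gel$elements, gel$E_inf_kpa)
  if (!is.null(gel$collapse_time_s)) {
    tc <- gel$collapse_time_s
    at_tc <- prony_predict(tc, gel$elements, gel$E_inf_kpa)
    late <- t_hold > tc
    sig[late] <- at_tc * exp(-(t_hold[late] - tc) / 0.2)
  }
  sig
}

#' Simulate a relaxation curve directly
#'
#' Generates the hold-phase relaxing-stiffness curve of a synthetic gel
#' without the approach/ramp preamble: the Prony-series decay of the spec,
#' the collapse transient if one is set, plus additive Gaussian noise with
#' standard deviation `noise_sigma * E(0)`.
#'
#' @param gel A [gel_spec()].
#' @param config An [experiment_config()] supplying the hold duration and
#'   sampling rate (100 s at 10 Hz by default: 1001 samples).
#' @return A [relaxation_curve()] in kPa.
#' @export
simulate_relaxation_curve <- function(gel, config = experiment_config()) {
  stopifnot(inherits(gel, "gel_spec"))
  t <- seq(0, config$hold_duration_s, by = 1 / config$sampling_rate_hz)
  sig <- hold_signal_kpa(gel, t)
  Et <- withr::with_seed(gel$seed, {
    sig + rnorm(length(t), 0, gel$noise_sigma * gel_E0(gel))
  })
  relaxation_curve(t, Et, config$deformation_fraction)
}

#' Simulate a full instrument trace
#'
#' Forward-simulates the low-load compression protocol: the plunger
#' approaches at `approach_speed_um_s` recording baseline force noise,
#' contacts the gel at `slide position - thickness`, compresses at the ramp
#' speed to `deformation_fraction * thickness`, then holds for
#' `hold_duration_s`.  The material response is idealized as a step strain at
#' hold start: hold-phase force is exactly
#' `area * strain0 * E(t)` for the spec's Prony series.  During the ramp the
#' force is the touch load plus a quasi-static elastic term
#' (`area * strain(t) * E(0)`); the step to the touch load at the contact
#' sample idealizes the instrument's contact detection so the detected
#' thickness matches the ring height to within one position step.  If
#' `collapse_time_s` is set, the hold force decays exponentially (0.2-s time
#' constant) to baseline after the collapse — a minimal failure waveform for
#' exercising QC, not a physical model of gel failure.
#'
#' @param gel A [gel_spec()].
#' @param config An [experiment_config()].
#' @param approach_gap_um Plunger travel before contact, in um.
#' @param sample_id,meta Passed to [raw_trace()].
#' @return A [raw_trace()] with attributes `truth` (the gel spec) and
#'   `slide_position_um`.
#' @export
simulate_trace <- function(gel, config = experiment_config(),
                           approach_gap_um = 50, sample_id = "SIM",
                           meta = list()) {
  stopifnot(inherits(gel, "gel_spec"), inherits(config, "experiment_config"))
  if (!is.null(gel$collapse_time_s) &&
      gel$collapse_time_s > config$hold_duration_s) {
    abort("`collapse_time_s` lies beyond the hold duration.",
          class = "gelrelax_validation_error")
  }
  dt <- 1 / config$sampling_rate_hz
  contact_pos <- approach_gap_um
  slide_pos <- approach_gap_um + gel$thickness_um
  target <- config$deformation_fraction * gel$thickness_um
  t_contact <- contact_pos / config$approach_speed_um_s
  t_reach <- t_contact + target / config$ramp_speed_um_s
  t_total <- t_reach + config$hold_duration_s + 1
  time <- seq(0, t_total, by = dt)

  pos <- ifelse(time <= t_contact,
                config$approach_speed_um_s * time,
                pmin(contact_pos + config$ramp_speed_um_s * (time - t_contact),
                     contact_pos + target))
  in_contact <- pos >= contact_pos - 1e-9
  at_hold <- pos >= contact_pos + target - 1e-9
  t_hold0 <- time[which(at_hold)[1]]
  strain_t <- pmin(pmax(pos - contact_pos, 0) / gel$thickness_um,
                   config$deformation_fraction)

  area <- plunger_area_m2(config)
  # Contact step overshoots the touch load by 5% so that detection of the
  # contact sample is not razor-edge against measurement noise.
  touch_stress <- 1.05 * touch_load_n(config) / area
  stress <- numeric(length(time))
  ramp_idx <- in_contact & !at_hold
  stress[ramp_idx] <- touch_stress + 1000 * gel_E0(gel) * strain_t[ramp_idx]
  stress[at_hold] <- 1000 * config$deformation_fraction *
    hold_signal_kpa(gel, time[at_hold] - t_hold0)

  noise_sd <- gel$noise_sigma * 1000 * gel_E0(gel) * config$deformation_fraction
  stress <- withr::with_seed(gel$seed, {
    stress + rnorm(length(time), 0, noise_sd)
  })
  out <- raw_trace(time, pos, stress * area, sample_id = sample_id,
                   meta = meta)
  attr(out, "truth") <- gel
  attr(out, "slide_position_um") <- slide_pos
  out
}

#' Specification of a synthetic measurement cohort
#'
#' Describes a hierarchical cohort mimicking the replicate structure of
#' donor-derived ECM hydrogels: several donors, several independent pregel
#' solutions per donor, cast in duplicate.  Material parameters are sampled
#' hierarchically — donor-level means, pregel-level multiplicative
#' deviations — with log-normal time constants and normal (truncated at
#' zero) stiffnesses.  A `"DAM"`-like group assigns a collapse time to every
#' trace, emulating gels that cannot sustain the hold; `"NAM"`-like gels
#' survive.  Defaults place a dominant sub-second element and an ECM element
#' in the 1-10 s decade, with an occasional slower third element.
#'
#' @param n_donors,n_pregels,n_replicates Cohort dimensions (default 3
#'   donors x 3 pregel solutions x 2 replicates).
#' @param group `"NAM"` (survives) or `"DAM"` (collapses).
#' @param mean_E_kpa,sd_E_kpa Donor-level means/SDs of element stiffnesses,
#'   one per element (kPa).
#' @param tau_median_s,tau_logsd Donor-level medians and log-SDs of the
#'   element time constants (log-normal).
#' @param p_third_element Probability that a pregel solution exhibits a slow
#'   third element.
#' @param third_E_kpa `c(mean, sd)` of the third element's stiffness.
#' @param third_tau `c(median, logsd)` of the third element's time constant.
#' @param pregel_cv Log-scale SD of pregel-level multiplicative deviations.
#' @param noise_sigma,thickness_um Passed to each [gel_spec()].
#' @param collapse Logical: force every trace to collapse (defaults to
#'   `group == "DAM"`).
#' @param collapse_window_s Range (s into the hold) from which collapse times
#'   are drawn uniformly.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 3, n_pregels = 3, n_replicates = 2,
                        group = c("NAM", "DAM"),
                        mean_E_kpa = c(1.2, 0.6), sd_E_kpa = c(0.25, 0.15),
                        tau_median_s = c(0.5, 5), tau_logsd = c(0.3, 0.3),
                        p_third_element = 0.3,
                        third_E_kpa = c(0.3, 0.1), third_tau = c(30, 0.3),
                        pregel_cv = 0.2,
                        noise_sigma = 0.01, thickness_um = 800,
                        collapse = NULL, collapse_window_s = c(2, 8),
                        seed = 1L) {
  group <- match.arg(group)
  if (any(c(n_donors, n_pregels, n_replicates) < 1)) {
    abort("Cohort counts must be >= 1.", class = "gelrelax_validation_error")
  }
  if (length(mean_E_kpa) != length(tau_median_s) ||
      length(sd_E_kpa) != length(mean_E_kpa) ||
      length(tau_logsd) != length(tau_median_s)) {
    abort("Element parameter vectors must have equal lengths.",
          class = "gelrelax_validation_error")
  }
  structure(
    list(n_donors = n_donors, n_pregels = n_pregels,
         n_replicates = n_replicates, group = group,
         mean_E_kpa = mean_E_kpa, sd_E_kpa = sd_E_kpa,
         tau_median_s = tau_median_s, tau_logsd = tau_logsd,
         p_third_element = p_third_element, third_E_kpa = third_E_kpa,
         third_tau = third_tau, pregel_cv = pregel_cv,
         noise_sigma = noise_sigma, thickness_um = thickness_um,
         collapse = collapse %||% (group == "DAM"),
         collapse_window_s = collapse_window_s, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Normal draw truncated just above zero (stiffnesses cannot be negative).
rnorm_pos <- function(n, mean, sd, floor = 0.01) {
  pmax(rnorm(n, mean, sd), floor)
}

#' Simulate a cohort of stress-relaxation measurements
#'
#' Samples ground-truth gels hierarchically per [cohort_spec()] and simulates
#' one trace per replicate.  Sample ids follow the donor/pregel nomenclature
#' `<group><donor><pregel letter>-<replicate>` (e.g. `"NAM2B-1"`).
#'
#' @param cohort A [cohort_spec()].
#' @param config An [experiment_config()].
#' @return A tibble with one row per trace: `sample_id`, `group`, `donor`,
#'   `pregel`, `replicate`, `collapse_time_s`, and list-columns `trace`
#'   ([raw_trace()]) and `truth` ([gel_spec()]).
#' @export
simulate_cohort <- function(cohort, config = experiment_config()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  withr::with_seed(cohort$seed, {
    rows <- list()
    for (d in seq_len(cohort$n_donors)) {
      k <- length(cohort$mean_E_kpa)
      donor_E <- rnorm_pos(k, cohort$mean_E_kpa, cohort$sd_E_kpa)
      donor_tau <- rlnorm(k, log(cohort$tau_median_s), cohort$tau_logsd)
      donor_E3 <- rnorm_pos(1, cohort$third_E_kpa[[1]], cohort$third_E_kpa[[2]])
      donor_tau3 <- rlnorm(1, log(cohort$third_tau[[1]]), cohort$third_tau[[2]])
      for (p in seq_len(cohort$n_pregels)) {
        has_third <- runif(1) < cohort$p_third_element
        E <- donor_E * exp(rnorm(k, 0, cohort$pregel_cv))
        tau <- donor_tau * exp(rnorm(k, 0, cohort$pregel_cv))
        if (has_third) {
          E <- c(E, donor_E3 * exp(rnorm(1, 0, cohort$pregel_cv)))
          tau <- c(tau, donor_tau3 * exp(rnorm(1, 0, cohort$pregel_cv)))
        }
        for (r in seq_len(cohort$n_replicates)) {
          collapse_time <- if (cohort$collapse) {
            runif(1, cohort$collapse_window_s[[1]], cohort$collapse_window_s[[2]])
          }
          gel <- gel_spec(
            elements = tibble(E_kpa = E, tau_s = tau),
            thickness_um = cohort$thickness_um,
            noise_sigma = cohort$noise_sigma,
            collapse_time_s = collapse_time,
            seed = sample.int(.Machine$integer.max - 1L, 1)
          )
          id <- sprintf("%s%d%s-%d", cohort$group, d, LETTERS[[p]], r)
          rows[[length(rows) + 1L]] <- tibble(
            sample_id = id, group = cohort$group, donor = d,
            pregel = LETTERS[[p]], replicate = r,
            collapse_time_s = collapse_time %||% NA_real_,
            trace = list(simulate_trace(gel, config, sample_id = id,
                                        meta = list(donor = d,
                                                    pregel = LETTERS[[p]],
                                                    replicate = r))),
            truth = list(gel)
          )
        }
      }
    }
    bind_rows(rows)
  })
}
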