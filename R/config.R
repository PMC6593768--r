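#' Experiment configuration for a low-load compression relaxation test
#'
#' Bundles the instrument and protocol parameters of a constant-strain
#' stress-relaxation experiment on a soft hydrogel: a plunger is lowered onto
#' the gel until a small touch load registers contact, the gel is compressed
#' to a fixed fraction of its thickness, and the force response is monitored
#' while the strain is held constant.  Defaults follow a common protocol for
#' decellularized-ECM gels cast in 0.8-mm rings: a 0.25-cm plunger approaching
#' at 5 um/s, a 10 mg-load contact threshold, 20% deformation held for 100 s.
#'
#' All internal physics is in SI units (s, m, N, Pa); configuration fields are
#' expressed in the instrument's native units (um, mg, cm) and converted on
#' use.
#'
#' @param plunger_diameter_cm Plunger diameter in cm.
#' @param approach_speed_um_s Plunger approach speed in um/s.
#' @param touch_load_mg Contact threshold in mg-load.
#' @param deformation_fraction Compression as a fraction of gel thickness,
#'   in (0, 1).
#' @param hold_duration_s Constant-strain hold duration in seconds.
#' @param force_unit Unit of the force column in trace files: `"mg"`
#'   (mg-load), `"mN"`, or `"N"`.
#' @param ring_height_um Casting-ring height in um (nominal gel thickness,
#'   used by the simulator).
#' @param sampling_rate_hz Instrument sampling rate in Hz.
#' @param ramp_speed_um_s Compression (ramp) speed in um/s; defaults to the
#'   approach speed.
#' @param debounce_n Number of consecutive samples the force must stay at or
#'   above the touch load before contact is declared.
#' @param gravity_m_s2 Standard gravity used for the mg-load to newton
#'   conversion.
#'
#' @return An object of class `experiment_config` (a validated named list).
#' @examples
#' cfg <- experiment_config()
#' cfg$deformation_fraction
#' @export
experiment_config <- function(plunger_diameter_cm = 0.25,
                              approach_speed_um_s = 5,
                              touch_load_mg = 10,
                              deformation_fraction = 0.20,
                              hold_duration_s = 100,
                              force_unit = c("mg", "mN", "N"),
                              ring_height_um = 800,
                              sampling_rate_hz = 10,
                              ramp_speed_um_s = NULL,
                              debounce_n = 5L,
                              gravity_m_s2 = 9.80665) {
  force_unit <- match.arg(force_unit)
  cfg <- structure(
    list(
      plunger_diameter_cm = plunger_diameter_cm,
      approach_speed_um_s = approach_speed_um_s,
      touch_load_mg = touch_load_mg,
      deformation_fraction = deformation_fraction,
      hold_duration_s = hold_duration_s,
      force_unit = force_unit,
      ring_height_um = ring_height_um,
      sampling_rate_hz = sampling_rate_hz,
      ramp_speed_um_s = ramp_speed_um_s %||% approach_speed_um_s,
      debounce_n = as.integer(debounce_n),
      gravity_m_s2 = gravity_m_s2
    ),
    class = "experiment_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  positive <- c(
    "plunger_diameter_cm", "approach_speed_um_s", "touch_load_mg",
    "hold_duration_s", "ring_height_um", "sampling_rate_hz",
    "ramp_speed_um_s", "gravity_m_s2"
  )
  for (f in positive) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(sprintf("`%s` must be a single positive number.", f),
            class = "gelrelax_config_error")
    }
  }
  if (!is.numeric(cfg$deformation_fraction) ||
      cfg$deformation_fraction <= 0 || cfg$deformation_fraction >= 1) {
    abort("`deformation_fraction` must lie in (0, 1).",
          class = "gelrelax_config_error")
  }
  if (cfg$debounce_n < 1L) {
    abort("`debounce_n` must be >= 1.", class = "gelrelax_config_error")
  }
  if (!cfg$force_unit %in% c("mg", "mN", "N")) {
    abort("`force_unit` must be one of 'mg', 'mN', 'N'.",
          class = "gelrelax_config_error")
  }
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  plunger diameter : %.3g cm\n", x$plunger_diameter_cm))
  cat(sprintf("  approach speed   : %.3g um/s (ramp %.3g um/s)\n",
              x$approach_speed_um_s, x$ramp_speed_um_s))
  cat(sprintf("  touch load       : %.3g mg (debounce %d samples)\n",
              x$touch_load_mg, x$debounce_n))
  cat(sprintf("  deformation      : %.0f%% held for %.3g s\n",
              100 * x$deformation_fraction, x$hold_duration_s))
  cat(sprintf("  sampling         : %.3g Hz; force unit '%s'\n",
              x$sampling_rate_hz, x$force_unit))
  invisible(x)
}

#' Convert force values between instrument units
#'
#' Forces recorded as mg-load are converted to newtons as F = m g with the
#' mass in kg and g standard gravity (9.80665 m/s^2); millinewtons scale by
#' 1e-3.  Conversions are exact scalings and therefore involutive.
#'
#' @param x Numeric vector of force values.
#' @param from,to Units among `"mg"`, `"mN"`, `"N"`.
#' @param gravity Standard gravity in m/s^2.
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_force(10, "mg", "N") # 9.80665e-05
#' @export
convert_force <- function(x, from = c("mg", "mN", "N"), to = c("N", "mg", "mN"),
                          gravity = 9.80665) {
  from <- match.arg(from)
  to <- match.arg(to)
  to_newton <- c(mg = 1e-6 * gravity, mN = 1e-3, N = 1)
  x * to_newton[[from]] / to_newton[[to]]
}

# Plunger cross-section in m^2; diameter is stored in cm.
plunger_area_m2 <- function(config) {
  r_m <- config$plunger_diameter_cm / 100 / 2
  pi * r_m^2
}

touch_load_n <- function(config) {
  convert_force(config$touch_load_mg, "mg", "N", gravity = config$gravity_m_s2)
}

#' Read or write an experiment configuration as JSON
#'
#' @param path File path.
#' @return `read_config()` returns an [experiment_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "gelrelax_config_error")
  }
  do.call(experiment_config, raw)
}

#' @rdname read_config
#' @param config An [experiment_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
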