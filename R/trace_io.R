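#' Construct a raw instrument trace
#'
#' A raw trace is the sampled record of a low-load compression tester: time,
#' plunger position (increasing toward the slide), and force.  Internally the
#' force is always stored in newtons.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param position_um Plunger position in um.
#' @param force_n Force in newtons.
#' @param sample_id Opaque sample label (e.g. `"NAM1A"`).
#' @param meta Named list of annotations (donor, pregel solution, replicate).
#' @return A tibble of class `raw_trace` with columns `time_s`, `position_um`,
#'   `force_n` and attributes `sample_id` and `meta`.
#' @export
raw_trace <- function(time_s, position_um, force_n, sample_id = NULL,
                      meta = list()) {
  if (length(time_s) < 2) {
    abort("A trace needs at least 2 samples.",
          class = "gelrelax_validation_error")
  }
  if (any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.",
          class = "gelrelax_validation_error")
  }
  if (!all(is.finite(position_um)) || !all(is.finite(force_n))) {
    abort("Position and force must be finite.",
          class = "gelrelax_validation_error")
  }
  out <- tibble(time_s = as.double(time_s),
                position_um = as.double(position_um),
                force_n = as.double(force_n))
  attr(out, "sample_id") <- sample_id
  attr(out, "meta") <- meta
  class(out) <- c("raw_trace", class(out))
  out
}

default_column_aliases <- function() {
  list(
    time = c("time_s", "time", "t", "time_sec", "time_seconds"),
    position = c("position_um", "position", "pos_um", "pos",
                 "displacement_um", "z_um"),
    force = c("force", "force_mg", "force_mn", "force_n", "load", "load_mg")
  )
}

# Sniff the delimiter from the header line: tab, comma or semicolon.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
}

#' Read an instrument trace from delimited text
#'
#' Reads a CSV/TSV export of a compression tester (delimiter sniffed from the
#' header), matches the time / position / force columns case-insensitively
#' against configurable aliases, converts the force to newtons according to
#' `config$force_unit`, and validates the result.
#'
#' @param path Path to a delimited text file with a header.
#' @param config An [experiment_config()]; `force_unit` declares the unit of
#'   the force column.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @param meta Named list of annotations attached to the trace.
#' @param aliases Optional named list with elements `time`, `position`,
#'   `force`, each a character vector of acceptable (case-insensitive) column
#'   names, replacing the defaults.
#' @return A [raw_trace()] with force in newtons.
#' @export
read_trace <- function(path, config, sample_id = NULL, meta = list(),
                       aliases = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  aliases <- aliases %||% default_column_aliases()
  df <- readr::read_delim(path, delim = sniff_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  pick <- function(role) {
    hit <- intersect(tolower(aliases[[role]]), names(df))
    if (length(hit) == 0) {
      abort(sprintf("No %s column found in '%s' (tried: %s).", role, path,
                    paste(aliases[[role]], collapse = ", ")),
            class = "gelrelax_format_error")
    }
    df[[hit[[1]]]]
  }
  force_raw <- pick("force")
  raw_trace(
    time_s = pick("time"),
    position_um = pick("position"),
    force_n = convert_force(force_raw, from = config$force_unit, to = "N",
                            gravity = config$gravity_m_s2),
    sample_id = sample_id %||% sub("\\.[^.]+$", "", basename(path)),
    meta = meta
  )
}

# Generic pre-serialization hook: turn package objects into plain lists /
# data frames that jsonlite can round-trip.
serialize_result <- function(x) UseMethod("serialize_result")

#' @export
serialize_result.default <- function(x) x

#' @export
serialize_result.list <- function(x) lapply(x, serialize_result)

#' @export
serialize_result.data.frame <- function(x) as.data.frame(x)

#' @export
serialize_result.maxwell_fit <- function(x) {
  list(
    elements = as.data.frame(x$elements),
    E_inf_kpa = x$E_inf_kpa,
    chi2 = x$chi2,
    n_elements = x$n_elements,
    relative_importance = x$relative_importance,
    converged = x$converged,
    selection_trace = if (!is.null(x$selection_trace))
      as.data.frame(x$selection_trace),
    seed = x$seed
  )
}

#' @export
serialize_result.cohort_report <- function(x) {
  list(
    samples = as.data.frame(x$samples),
    elements = as.data.frame(x$elements),
    summary = as.data.frame(x$summary),
    excluded = as.data.frame(x$excluded)
  )
}

#' Write and re-read pipeline results
#'
#' `write_results()` serializes any pipeline output (fits, summaries,
#' reports, plain data frames) to JSON or CSV; `read_results()` reads it
#' back.  The round trip is lossless for integers and strings and accurate to
#' better than 1e-12 relative for reals (JSON numbers are written at full
#' precision).  CSV is only available for tabular results.
#'
#' @param results A data frame, list, [maxwell_fit][fit_fixed_order], or
#'   [cohort_report][build_report].
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `write_results()` returns `path` invisibly; `read_results()` the
#'   parsed object (tibbles for tabular data).
#' @export
write_results <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  results <- serialize_result(results)
  if (format == "csv") {
    if (!is.data.frame(results)) {
      abort("CSV output requires a tabular (data frame) result.",
            class = "gelrelax_format_error")
    }
    readr::write_csv(as_tibble(results), path, progress = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(out)) as_tibble(out) else out
  }
}
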