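#' Group summaries: mean, SD, SEM
#'
#' Summarises a metric into per-group mean, sample standard deviation
#' (n - 1 denominator) and standard error of the mean (SD / sqrt(n)).
#' Groups with a single value report `sd`/`sem` as `NA` and are flagged via
#' `dispersion_defined = FALSE`.
#'
#' @param data A data frame.
#' @param value Column to summarise (unquoted).
#' @param by Optional grouping columns (unquoted, tidyselect).
#' @param na_rm Drop `NA` values before summarising.
#' @return A tibble with columns `by...`, `n`, `mean`, `sd`, `sem`,
#'   `dispersion_defined`.
#' @examples
#' summarize_metric(data.frame(x = c(1, 2, 3)), x)
#' @export
summarize_metric <- function(data, value, by = NULL, na_rm = TRUE) {
  if (nrow(data) == 0) {
    abort("Cannot summarise an empty group.",
          class = "gelrelax_empty_group_error")
  }
  out <- data |>
    group_by(across({{ by }})) |>
    summarise(
      n = sum(!is.na({{ value }})),
      mean = mean({{ value }}, na.rm = na_rm),
      sd = sd({{ value }}, na.rm = na_rm),
      .groups = "drop"
    ) |>
    mutate(
      sem = .data$sd / sqrt(.data$n),
      dispersion_defined = .data$n >= 2
    )
  if (any(out$n == 0)) {
    abort("Cannot summarise an empty group.",
          class = "gelrelax_empty_group_error")
  }
  out
}

#' One-tailed two-sample t test
#'
#' Student's two-sample t test (pooled variance by default, Welch with
#' `var_equal = FALSE`), one-tailed in an explicitly stated direction:
#' `direction = "greater"` tests the alternative mean(a) > mean(b).
#' When both groups have zero variance and equal means the statistic is
#' degenerate; by convention `p = 0.5` is returned with
#' `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param direction `"greater"` or `"less"`: the alternative hypothesis for
#'   mean(a) relative to mean(b).  There is no default hypothesis — the
#'   direction is the analyst's choice.
#' @param var_equal Pooled-variance Student t (`TRUE`, default) or Welch.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `direction`,
#'   `method`, `degenerate`.
#' @export
t_test_one_tailed <- function(a, b, direction = c("greater", "less"),
                              var_equal = TRUE) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 observations.",
          class = "gelrelax_validation_error")
  }
  method <- if (var_equal) "Student (pooled variance)" else "Welch"
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                    p_value = 0.5, direction = direction, method = method,
                    degenerate = TRUE))
    }
    in_direction <- (mean(a) > mean(b)) == (direction == "greater")
    return(tibble(statistic = if (in_direction) Inf else -Inf,
                  df = length(a) + length(b) - 2,
                  p_value = if (in_direction) 0 else 1,
                  direction = direction, method = method, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, alternative = direction, var.equal = var_equal)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, direction = direction, method = method,
         degenerate = FALSE)
}

#' Analyse a single stress-relaxation trace
#'
#' Runs the full pipeline on one raw trace: contact detection, phase
#' segmentation, stiffness regression, relaxing-stiffness extraction,
#' Maxwell-model fitting with order selection, total relaxation, and
#' collapse QC.  Stages downstream of a failure (e.g. total relaxation of a
#' collapsed gel) report `NA` rather than aborting, so cohorts with failed
#' measurements can still be aggregated.
#'
#' @param trace A [raw_trace()].
#' @param config An [experiment_config()].
#' @param slide_position_um Slide position in um; defaults to the trace's
#'   `slide_position_um` attribute (set by [simulate_trace()]).
#' @param max_n,epsilon,e_inf,seed Passed to [select_order()].
#' @param ... Further arguments to [select_order()].
#' @return A one-row tibble with `sample_id`, `thickness_um`, `E_kpa`,
#'   `stiffness_r2`, `total_relaxation_pct`, `n_elements`, `chi2`,
#'   `converged`, `collapsed`, `qc_reason`, and list-columns `fit`, `curve`.
#' @export
analyze_trace <- function(trace, config, slide_position_um = NULL,
                          max_n = 4, epsilon = 0.05, e_inf = "free",
                          seed = 1L, ...) {
  slide_position_um <- slide_position_um %||% attr(trace, "slide_position_um")
  if (is.null(slide_position_um)) {
    abort("`slide_position_um` is required (calibration input).",
          class = "gelrelax_config_error")
  }
  contact <- detect_contact(trace, config, slide_position_um)
  ss <- segment_phases(trace, contact, config)
  stiff <- tryCatch(fit_stiffness(ss), error = function(e) NULL)
  curve <- relaxing_stiffness(ss)
  fit <- tryCatch(
    select_order(curve, max_n = max_n, epsilon = epsilon, e_inf = e_inf,
                 seed = seed, ...),
    error = function(e) NULL
  )
  qc <- qc_flag_collapse(curve, fit)
  tr <- tryCatch(total_relaxation(curve), error = function(e) NA_real_)
  tibble(
    sample_id = attr(trace, "sample_id") %||% NA_character_,
    thickness_um = contact$thickness_um,
    E_kpa = if (is.null(stiff)) NA_real_ else stiff$E_kpa,
    stiffness_r2 = if (is.null(stiff)) NA_real_ else stiff$r2,
    total_relaxation_pct = tr,
    n_elements = if (is.null(fit)) NA_integer_ else fit$n_elements,
    chi2 = if (is.null(fit)) NA_real_ else fit$chi2,
    converged = if (is.null(fit)) FALSE else fit$converged,
    collapsed = qc$collapsed,
    qc_reason = qc$reason,
    fit = list(fit),
    curve = list(curve)
  )
}

#' Analyse every trace of a cohort
#'
#' @param traces A [simulate_cohort()] tibble (or any tibble with a `trace`
#'   list-column; id columns are carried through).
#' @param config An [experiment_config()].
#' @param ... Passed to [analyze_trace()].
#' @return A tibble with one row per trace: the id columns of `traces`
#'   followed by the [analyze_trace()] results.
#' @export
analyze_cohort <- function(traces, config, ...) {
  stopifnot(is.data.frame(traces), "trace" %in% names(traces))
  ids <- traces[setdiff(names(traces), c("trace", "truth"))]
  res <- map(traces$trace, analyze_trace, config = config, ...) |> list_rbind()
  res$sample_id <- NULL
  dplyr::bind_cols(ids, res)
}

#' Build a cohort report
#'
#' Aggregates per-trace pipeline results into a report bundle: the
#' per-sample table, the fitted Maxwell elements with relative importances
#' and time-constant classes, per-group summaries (mean, SD, SEM) of the
#' viscoelastic metrics for non-collapsed measurements, and the exclusion
#' list.  Collapsed measurements never enter the summaries.
#'
#' @param results An [analyze_cohort()] (or row-bound [analyze_trace()])
#'   tibble.
#' @param by Grouping columns for the summaries (unquoted tidyselect;
#'   e.g. `group` or `c(group, donor)`).
#' @param metrics Character vector of result columns to summarise.
#' @return An object of class `cohort_report`: a list of tibbles `samples`,
#'   `elements`, `summary`, `excluded`.
#' @export
build_report <- function(results, by = NULL,
                         metrics = c("E_kpa", "total_relaxation_pct",
                                     "n_elements")) {
  samples <- results |> select(-any_of(c("fit", "curve")))
  elements <- purrr::map2(results$fit, seq_len(nrow(results)), function(f, i) {
    if (is.null(f)) return(NULL)
    td <- tidy(f)
    td$sample_id <- if ("sample_id" %in% names(results))
      results$sample_id[[i]] else as.character(i)
    td
  }) |> list_rbind()
  included <- samples |> filter(!.data$collapsed)
  summary <- if (nrow(included) == 0) {
    tibble(metric = character(), n = integer(), mean = double(),
           sd = double(), sem = double(), dispersion_defined = logical())
  } else {
    map(metrics, function(m) {
      summarize_metric(included, .data[[m]], by = {{ by }}) |>
        mutate(metric = m, .before = 1)
    }) |> list_rbind()
  }
  excluded <- samples |>
    filter(.data$collapsed) |>
    select(any_of(c("sample_id", "qc_reason")))
  structure(
    list(samples = samples, elements = as_tibble(elements),
         summary = summary, excluded = excluded),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d sample(s), %d excluded by QC\n",
              nrow(x$samples), nrow(x$excluded)))
  if (nrow(x$summary) > 0) {
    cat("summary:\n")
    print(as.data.frame(x$summary), digits = 4)
  } else {
    cat("summary: empty (no measurable samples)\n")
  }
  if (nrow(x$excluded) > 0) {
    cat("excluded:", paste(x$excluded$sample_id, collapse = ", "), "\n")
  }
  invisible(x)
}
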