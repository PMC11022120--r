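#' Read a per-eye longitudinal OCT cohort
#'
#' Reads a long-format CSV of per-eye mGCIPL measurements and validates that
#' every eye is complete: both metrics (thickness in micrometres, volume in
#' cubic millimetres) at all three visits (baseline, 2 months, 6 months), all
#' values strictly positive, laterality exactly `"OD"` or `"OS"`.
#'
#' The expected dialect is comma-separated UTF-8 with header
#' `case_id,laterality,metric,timepoint,value`, where `metric` is one of
#' `mgcipl_thickness_um` / `mgcipl_volume_mm3` and `timepoint` one of
#' `baseline` / `m2` / `m6`. One eye is one `(case_id, laterality)` pair.
#'
#' @param source Path to a CSV file, or a connection, in the dialect above.
#' @return A tibble with columns `case_id` (character), `laterality`
#'   (`"OD"`/`"OS"`), `metric` (`"thickness"`/`"volume"`), `timepoint`
#'   (`"baseline"`/`"m2"`/`"m6"`) and `value` (double), six rows per eye.
#' @seealso [oct_cohort()] for the packaged pilot cohort, [summarize_metric()],
#'   [summarize_change()].
#' @examples
#' path <- system.file("extdata", "gcipl_cohort.csv", package = "octpower")
#' read_cohort(path)
#' @export
read_cohort <- function(source) {
  spec <- readr::cols(
    case_id = readr::col_character(),
    laterality = readr::col_character(),
    metric = readr::col_character(),
    timepoint = readr::col_character(),
    value = readr::col_double()
  )
  raw <- readr::read_csv(source, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(names(spec$cols), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort CSV is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- which(is.na(raw$value))
  if (length(bad) > 0) {
    abort(paste0(
      "non-numeric or missing value in cohort CSV at data row(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    warn("cohort CSV has a valid header but no records; returning empty cohort")
    return(tibble(
      case_id = character(), laterality = character(),
      metric = character(), timepoint = character(), value = double()
    ))
  }
  known <- raw$metric %in% .metric_codes
  if (!all(known)) {
    abort(paste0(
      "unknown metric code(s): ",
      paste(unique(raw$metric[!known]), collapse = ", ")
    ))
  }
  cohort <- raw |>
    dplyr::mutate(metric = names(.metric_codes)[match(.data$metric, .metric_codes)])
  validate_cohort(cohort)
}

#' The packaged AQP4-IgG seropositive optic neuritis pilot cohort
#'
#' Five affected eyes from four glucocorticoid-treated AQP4-IgG seropositive
#' optic neuritis patients, measured by spectral-domain OCT at symptom onset
#' and at the 2- and 6-month follow-ups. These per-eye mGCIPL thickness and
#' volume values are the pilot data from which all default sample-size
#' estimates in this package are derived. One patient contributed both eyes;
#' eyes are treated as independent units.
#'
#' @return A validated cohort tibble (see [read_cohort()] for the layout).
#' @examples
#' oct_cohort()
#' @export
oct_cohort <- function() {
  read_cohort(system.file("extdata", "gcipl_cohort.csv", package = "octpower"))
}

# Validate completeness/positivity of a cohort tibble; used by read_cohort()
# and by generate_cohort(). Returns the tibble invisibly unchanged on success.
validate_cohort <- function(cohort) {
  if (nrow(cohort) == 0) {
    return(cohort)
  }
  bad_lat <- !cohort$laterality %in% c("OD", "OS")
  if (any(bad_lat)) {
    abort(paste0(
      "laterality must be 'OD' or 'OS'; found: ",
      paste(unique(cohort$laterality[bad_lat]), collapse = ", ")
    ))
  }
  if (any(cohort$value <= 0)) {
    abort("all measurement values must be strictly positive")
  }
  dup <- cohort |>
    dplyr::count(.data$case_id, .data$laterality, .data$metric, .data$timepoint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicated measurement(s) for eye ", dup$case_id[1], "/", dup$laterality[1]
    ))
  }
  counts <- cohort |>
    dplyr::count(.data$case_id, .data$laterality)
  incomplete <- counts |>
    dplyr::filter(.data$n != length(.metrics) * length(.timepoints))
  if (nrow(incomplete) > 0) {
    abort(paste0(
      "incomplete eye(s), expected both metrics at all three timepoints: ",
      paste(incomplete$case_id, incomplete$laterality,
        sep = "/", collapse = ", "
      )
    ))
  }
  cohort
}

#' Summary statistics for one metric at one visit
#'
#' Computes n, mean, sample SD (n - 1 denominator), median, min and max of one
#' mGCIPL metric at one timepoint across all eyes of a cohort. Nothing is
#' rounded: downstream sample-size arithmetic consumes these values at full
#' double precision, and rounding is left to display.
#'
#' @param cohort A cohort tibble from [read_cohort()], [oct_cohort()] or
#'   [generate_cohort()].
#' @param metric `"thickness"` (micrometres) or `"volume"` (cubic millimetres).
#' @param timepoint `"baseline"`, `"m2"` or `"m6"`.
#' @return A one-row tibble: `metric`, `timepoint`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, in the metric's units.
#' @examples
#' oct_cohort() |> summarize_metric("thickness", "baseline")
#' @export
summarize_metric <- function(cohort, metric = c("thickness", "volume"),
                             timepoint = c("baseline", "m2", "m6")) {
  metric <- arg_match(metric)
  timepoint <- arg_match(timepoint)
  values <- cohort |>
    dplyr::filter(.data$metric == !!metric, .data$timepoint == !!timepoint) |>
    dplyr::pull(.data$value)
  summary_row(values, metric, timepoint)
}

#' Summary statistics of per-eye change from baseline
#'
#' For each eye, forms the difference baseline value minus follow-up value
#' (positive when tissue is lost) and summarizes the differences across eyes.
#' The mean of the paired differences equals the difference of the two visit
#' means; the SD of the differences is the dispersion a change-score
#' ("Method B") design uses.
#'
#' @inheritParams summarize_metric
#' @param followup Follow-up visit, `"m2"` or `"m6"`.
#' @return A one-row tibble as in [summarize_metric()], with `timepoint` set to
#'   e.g. `"baseline-m6"`.
#' @examples
#' oct_cohort() |> summarize_change("volume", "m6")
#' @export
summarize_change <- function(cohort, metric = c("thickness", "volume"),
                             followup = c("m2", "m6")) {
  metric <- arg_match(metric)
  followup <- arg_match(followup)
  diffs <- change_scores(cohort, metric, followup)
  summary_row(diffs, metric, paste0("baseline-", followup))
}

# per-eye baseline - follow-up differences, as a bare numeric vector
change_scores <- function(cohort, metric, followup) {
  wide <- cohort |>
    dplyr::filter(
      .data$metric == !!metric,
      .data$timepoint %in% c("baseline", followup)
    ) |>
    tidyr::pivot_wider(
      id_cols = c("case_id", "laterality"),
      names_from = "timepoint", values_from = "value"
    )
  if (!all(c("baseline", followup) %in% names(wide)) ||
    anyNA(wide[c("baseline", followup)])) {
    abort("every eye needs both a baseline and a follow-up value")
  }
  wide$baseline - wide[[followup]]
}

summary_row <- function(values, metric, timepoint) {
  if (length(values) < 2) {
    abort("at least 2 eyes are required to summarize (sample SD needs n >= 2)")
  }
  tibble(
    metric = metric,
    timepoint = timepoint,
    n = length(values),
    mean = mean(values),
    sd = sd(values),
    median = median(values),
    min = min(values),
    max = max(values)
  )
}
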