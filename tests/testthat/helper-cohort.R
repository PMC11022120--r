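# The pilot measurements, rebuilt in code independently of the packaged CSV:
# five affected eyes, mGCIPL volume (mm^3) and thickness (um) at onset and at
# the 2- and 6-month visits.
pilot_values <- function() {
  tibble::tribble(
    ~case_id, ~laterality, ~vol_b, ~vol_m2, ~vol_m6, ~th_b, ~th_m2, ~th_m6,
    "1", "OD", 0.62, 0.46, 0.37, 87.77, 64.11, 53.44,
    "2", "OD", 0.30, 0.25, 0.25, 41.66, 33.77, 32.55,
    "3", "OS", 0.58, 0.44, 0.44, 79.67, 60.00, 59.55,
    "4", "OD", 0.55, 0.31, 0.25, 75.22, 43.44, 35.01,
    "4", "OS", 0.62, 0.42, 0.37, 84.00, 56.56, 50.89
  )
}

# same data in the long cohort layout the package consumes
pilot_cohort <- function() {
  pilot_values() |>
    tidyr::pivot_longer(-c(case_id, laterality),
      names_to = c("metric", "timepoint"), names_sep = "_",
      values_to = "value"
    ) |>
    dplyr::mutate(
      metric = dplyr::recode(metric, vol = "volume", th = "thickness"),
      timepoint = dplyr::recode(timepoint, b = "baseline")
    )
}

# long-dialect CSV text for a cohort tibble, for exercising read_cohort()
cohort_csv <- function(cohort, path = withr::local_tempfile(fileext = ".csv",
                         .local_envir = parent.frame())) {
  codes <- c(thickness = "mgcipl_thickness_um", volume = "mgcipl_volume_mm3")
  out <- dplyr::mutate(cohort, metric = codes[metric])
  readr::write_csv(out, path)
  path
}
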