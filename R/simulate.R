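#' Specify a synthetic longitudinal OCT cohort
#'
#' Parameters for the generative model behind [generate_cohort()]: a normal
#' baseline, proportional mean loss at each follow-up visit, within-eye
#' correlated residual noise, and an optional protective treatment effect.
#' The eye's follow-up value is
#' `baseline * (1 - loss_fraction * (1 - treatment_effect)) + residual`,
#' with the two follow-up residuals sharing an eye-level component so that
#' their correlation is `within_eye_correlation`.
#'
#' Defaults emulate the packaged pilot cohort's mGCIPL volume: baseline
#' 0.534 mm³ (SD 0.134), about 30% of the baseline mean lost by 2 months and
#' 37% by 6 months. The correlation default (0.7) is a synthetic-data
#' convenience with no empirical basis in the pilot data; it does not enter
#' the two-sample design formulas.
#'
#' @param n_eyes Number of eyes (>= 2).
#' @param baseline_mean,baseline_sd Baseline distribution, metric units.
#' @param loss_fraction_m2,loss_fraction_m6 Fractions of the baseline mean
#'   lost by each visit in the untreated arm, in \[0, 1).
#' @param residual_sd_m2,residual_sd_m6 SDs of the visit-level residual noise,
#'   metric units.
#' @param within_eye_correlation Correlation of the two follow-up residuals,
#'   in \[0, 1).
#' @param treatment_effect Fraction of the loss prevented (0 = control arm).
#' @param metric Which metric the values represent (labelling only).
#' @return A list of class `cohort_model`.
#' @examples
#' cohort_model(n_eyes = 50, treatment_effect = 0.2)
#' @export
cohort_model <- function(n_eyes = 100,
                         baseline_mean = 0.534, baseline_sd = 0.134,
                         loss_fraction_m2 = 0.30, loss_fraction_m6 = 0.37,
                         residual_sd_m2 = 0.03, residual_sd_m6 = 0.03,
                         within_eye_correlation = 0.7,
                         treatment_effect = 0,
                         metric = c("volume", "thickness")) {
  metric <- arg_match(metric)
  if (n_eyes < 2) abort("n_eyes must be at least 2")
  if (baseline_sd < 0 || residual_sd_m2 < 0 || residual_sd_m6 < 0) {
    abort("standard deviations must be non-negative")
  }
  if (loss_fraction_m2 < 0 || loss_fraction_m2 >= 1 ||
    loss_fraction_m6 < 0 || loss_fraction_m6 >= 1) {
    abort("loss fractions must lie in [0, 1)")
  }
  if (within_eye_correlation < 0 || within_eye_correlation >= 1) {
    abort("within_eye_correlation must lie in [0, 1)")
  }
  if (treatment_effect < 0 || treatment_effect > 1) {
    abort("treatment_effect must lie in [0, 1]")
  }
  structure(
    list(
      n_eyes = as.integer(n_eyes),
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      loss_fraction_m2 = loss_fraction_m2, loss_fraction_m6 = loss_fraction_m6,
      residual_sd_m2 = residual_sd_m2, residual_sd_m6 = residual_sd_m6,
      within_eye_correlation = within_eye_correlation,
      treatment_effect = treatment_effect, metric = metric
    ),
    class = "cohort_model"
  )
}

#' Generate a synthetic per-eye cohort
#'
#' Draws a cohort from a [cohort_model()] in the same long layout as
#' [read_cohort()], so it can feed [summarize_metric()],
#' [estimate_sample_size()] and [sample_size_grid()] directly. Fully
#' reproducible from `seed`.
#'
#' OCT layer measurements are physically positive, so the generator redraws
#' the (rare, at the defaults) eye whose normal draw falls at or below zero —
#' a truncated-at-zero normal in effect.
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed controlling all randomness.
#' @return A validated cohort tibble, `3 * n_eyes` rows (one metric).
#' @examples
#' generate_cohort(cohort_model(n_eyes = 5), seed = 1)
#' @export
generate_cohort <- function(model, seed = 1L) {
  stopifnot(inherits(model, "cohort_model"))
  check_seed(seed)
  withr::local_seed(seed)
  n <- model$n_eyes
  rho <- model$within_eye_correlation
  retain_m2 <- 1 - model$loss_fraction_m2 * (1 - model$treatment_effect)
  retain_m6 <- 1 - model$loss_fraction_m6 * (1 - model$treatment_effect)
  draw_eyes <- function(k) {
    baseline <- rnorm(k, model$baseline_mean, model$baseline_sd)
    shared <- rnorm(k) # eye-level residual component, shared by both visits
    r2 <- model$residual_sd_m2 * (sqrt(rho) * shared + sqrt(1 - rho) * rnorm(k))
    r6 <- model$residual_sd_m6 * (sqrt(rho) * shared + sqrt(1 - rho) * rnorm(k))
    cbind(baseline, baseline * retain_m2 + r2, baseline * retain_m6 + r6)
  }
  # measurements are physically positive: redraw the rare eye whose normal
  # draw crosses zero (a truncated-at-zero model; negligible at the defaults)
  eyes <- draw_eyes(n)
  for (attempt in 1:100) {
    bad <- which(apply(eyes <= 0, 1, any))
    if (length(bad) == 0) break
    eyes[bad, ] <- draw_eyes(length(bad))
  }
  if (any(eyes <= 0)) {
    abort("model places too much mass below zero to generate positive cohorts")
  }
  ids <- sprintf("S%04d", seq_len(n))
  lat <- rep_len(c("OD", "OS"), n)
  cohort <- tibble(
    case_id = rep(ids, 3),
    laterality = rep(lat, 3),
    metric = model$metric,
    timepoint = rep(.timepoints, each = n),
    value = c(eyes[, 1], eyes[, 2], eyes[, 3])
  )
  # the other metric is appended as a constant so the cohort passes the
  # completeness check; analyses select their metric explicitly
  other <- setdiff(.metrics, model$metric)
  filler <- dplyr::mutate(cohort, metric = other, value = 1)
  validate_cohort(dplyr::bind_rows(cohort, filler))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("seed must be a single integer")
  }
  invisible(as.integer(seed))
}

#' Monte Carlo power of the two-sided two-sample comparison
#'
#' Repeatedly draws the two arms from normals with common `sigma`, applies the
#' two-sided test at level `alpha`, and counts rejections. The default test is
#' the z-test with `sigma` treated as known, matching the analytic power
#' formula; because that statistic depends on the data only through the two
#' arm means, the simulation draws the arm means directly from their exact
#' sampling distribution. A Welch t option (which simulates full samples and
#' estimates the variances) is available for sensitivity checks.
#'
#' @param n_test,n_gc Per-arm sizes.
#' @param gc_mean,test_mean Arm means under the alternative (follow-up values
#'   for a Method A design, mean change scores for Method B).
#' @param sigma Common SD (> 0).
#' @param alpha Two-sided level, default 0.05.
#' @param replicates Number of simulated trials (>= 100).
#' @param seed Integer seed.
#' @param test `"z"` (known sigma, default) or `"welch"`.
#' @return A one-row tibble: `replicates`, `seed`, `rejections`,
#'   `empirical_power`, `mc_se` (binomial standard error),
#'   `analytic_power` from [power_two_sample()], and `flagged` — `TRUE` when
#'   empirical and analytic power disagree by more than four Monte Carlo
#'   standard errors.
#' @examples
#' simulate_trial_power(103, 103,
#'   gc_mean = 0.198, test_mean = 0.1584,
#'   sigma = 0.1013, replicates = 10000, seed = 7
#' )
#' @export
simulate_trial_power <- function(n_test, n_gc, gc_mean, test_mean, sigma,
                                 alpha = 0.05, replicates = 10000, seed = 1L,
                                 test = c("z", "welch")) {
  test <- arg_match(test)
  if (sigma <= 0) abort("sigma must be positive")
  if (replicates < 100) abort("at least 100 replicates are required")
  check_seed(seed)
  withr::local_seed(seed)
  z_crit <- qnorm(1 - alpha / 2)
  if (test == "z") {
    mgc <- rnorm(replicates, gc_mean, sigma / sqrt(n_gc))
    mtest <- rnorm(replicates, test_mean, sigma / sqrt(n_test))
    z <- (mgc - mtest) / (sigma * sqrt(1 / n_gc + 1 / n_test))
    rejections <- sum(abs(z) > z_crit)
  } else {
    rejections <- 0L
    block <- max(1L, min(replicates, floor(2e6 / (n_test + n_gc))))
    done <- 0L
    while (done < replicates) {
      b <- min(block, replicates - done)
      xg <- matrix(rnorm(b * n_gc, gc_mean, sigma), nrow = n_gc)
      xt <- matrix(rnorm(b * n_test, test_mean, sigma), nrow = n_test)
      vg <- col_vars(xg)
      vt <- col_vars(xt)
      se <- sqrt(vg / n_gc + vt / n_test)
      tstat <- (colMeans(xg) - colMeans(xt)) / se
      df <- se^4 / ((vg / n_gc)^2 / (n_gc - 1) + (vt / n_test)^2 / (n_test - 1))
      rejections <- rejections + sum(abs(tstat) > stats::qt(1 - alpha / 2, df))
      done <- done + b
    }
  }
  emp <- rejections / replicates
  mc_se <- sqrt(emp * (1 - emp) / replicates)
  analytic <- power_two_sample(n_test, n_gc, gc_mean - test_mean, sigma, alpha)$power
  tibble(
    replicates = replicates, seed = as.integer(seed), rejections = rejections,
    empirical_power = emp, mc_se = mc_se, analytic_power = analytic,
    flagged = abs(emp - analytic) > 4 * mc_se
  )
}

# column variances without a matrixStats dependency
col_vars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Monte Carlo check of one estimated design
#'
#' Convenience wrapper: takes an `oct_design` from [estimate_sample_size()]
#' and simulates it at its own integer arm sizes, arm means and sigma.
#'
#' @param design An `oct_design`.
#' @inheritParams simulate_trial_power
#' @return The [simulate_trial_power()] report.
#' @examples
#' oct_cohort() |>
#'   estimate_sample_size("volume", "m6", method = "B") |>
#'   simulate_design(replicates = 5000, seed = 11)
#' @export
simulate_design <- function(design, replicates = 10000, seed = 1L,
                            test = c("z", "welch")) {
  stopifnot(inherits(design, "oct_design"))
  simulate_trial_power(
    n_test = design$n_test, n_gc = design$n_gc,
    gc_mean = design$gc_mean, test_mean = design$test_mean,
    sigma = design$sigma, alpha = design$alpha,
    replicates = replicates, seed = seed, test = test
  )
}

#' Pilot-to-power pipeline on synthetic data
#'
#' End-to-end validation loop: generates a control-arm pilot cohort from a
#' [cohort_model()], estimates the full sample-size grid from it, then
#' simulates every cell's design at its returned integer sizes and compares
#' empirical with analytic power.
#'
#' @param model A [cohort_model()] for the control-arm pilot (its
#'   `treatment_effect` should be 0).
#' @param seed Integer seed; the pilot draw and every cell's simulation derive
#'   their streams from it.
#' @param replicates Simulated trials per grid cell.
#' @inheritParams sample_size_grid
#' @return A tibble: the grid columns plus `empirical_power`, `mc_se` and
#'   `flagged` per cell.
#' @examples
#' end_to_end(cohort_model(n_eyes = 40), seed = 3,
#'   replicates = 1000, effect_sizes = 0.2, powers = 0.8)
#' @export
end_to_end <- function(model, seed = 1L, replicates = 10000,
                       effect_sizes = c(0.20, 0.30, 0.40, 0.50, 0.60),
                       powers = c(0.80, 0.90, 0.95),
                       methods = c("A", "B"),
                       metrics = model$metric,
                       followups = c("m2", "m6"),
                       alpha = 0.05, kappa = 1) {
  stopifnot(inherits(model, "cohort_model"))
  pilot <- generate_cohort(model, seed = seed)
  grid <- sample_size_grid(
    pilot,
    effect_sizes = effect_sizes, powers = powers, methods = methods,
    metrics = metrics, followups = followups, alpha = alpha, kappa = kappa
  )
  reports <- purrr::pmap(
    list(
      grid$n_test, grid$n_gc, grid$delta, grid$sigma, grid$alpha,
      seq_len(nrow(grid))
    ),
    function(n_test, n_gc, delta, sigma, a, i) {
      simulate_trial_power(
        n_test = n_test, n_gc = n_gc, gc_mean = delta, test_mean = 0,
        sigma = sigma, alpha = a, replicates = replicates,
        seed = as.integer(seed) + i
      ) |>
        dplyr::select("empirical_power", "mc_se", "flagged")
    }
  ) |>
    purrr::list_rbind()
  dplyr::bind_cols(tibble::as_tibble(grid), reports)
}
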