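#' Raw (unrounded) per-arm sample size
#'
#' The two-sample normal-approximation formula for the test-drug arm, with
#' matching ratio `kappa` (control n over test n):
#' \deqn{n_{test} = \left(1 + \frac{1}{\kappa}\right)
#'   \left(\frac{\sigma (z_{1-\alpha/2} + z_{1-\beta})}{\delta}\right)^2.}
#' Quantiles are taken at full double precision (z at 0.975 is 1.959964...,
#' not 1.96).
#'
#' @param delta Between-arm mean difference (non-zero), metric units.
#' @param sigma Common SD (> 0), metric units.
#' @param alpha Two-sided type-I error, default 0.05.
#' @param power Target power 1 - beta, default 0.80.
#' @param kappa Matching ratio n_control / n_test, default 1.
#' @return The positive real test-arm size before rounding.
#' @examples
#' n_per_arm_raw(delta = 0.0316, sigma = 0.09127)
#' @export
n_per_arm_raw <- function(delta, sigma, alpha = 0.05, power = 0.80, kappa = 1) {
  if (any(delta == 0)) abort("delta must be non-zero: a null difference needs infinite n")
  if (any(sigma <= 0)) abort("sigma must be positive")
  if (any(kappa <= 0)) abort("kappa must be positive")
  if (any(alpha <= 0) || any(alpha >= 1) || any(power <= 0) || any(power >= 1)) {
    abort("alpha and power must lie in (0, 1)")
  }
  (1 + 1 / kappa) * (sigma * (qnorm(1 - alpha / 2) + qnorm(power)) / delta)^2
}

#' Estimate the sample size of a two-arm OCT endpoint trial
#'
#' Turns a pilot cohort plus a design specification into per-arm and total
#' sample sizes. Method A compares the follow-up values themselves (sigma is
#' the SD of the control arm's follow-up measurements); Method B compares
#' baseline-minus-follow-up change scores (sigma is the SD of the paired
#' differences). Delta is the protective effect size times the control arm's
#' mean loss from baseline, identical under both methods. All pilot
#' statistics enter unrounded. Arm sizes are rounded up separately
#' (`n_test = ceiling(raw)`, `n_gc = ceiling(kappa * raw)`), so the achieved
#' analytic power never falls below the target.
#'
#' @param cohort A pilot cohort tibble ([oct_cohort()], [read_cohort()],
#'   [generate_cohort()]).
#' @param metric `"thickness"` or `"volume"`.
#' @param followup `"m2"` or `"m6"`.
#' @param method `"A"` (follow-up values) or `"B"` (change scores).
#' @param effect_size Fraction of the control-arm loss the drug prevents,
#'   in (0, 1].
#' @inheritParams n_per_arm_raw
#' @param inflate_for_dropout Optional anticipated dropout fraction in
#'   \[0, 1); when given, each arm is inflated post hoc to
#'   `ceiling(n / (1 - fraction))`. No dropout model is implied beyond this
#'   multiplier.
#' @return An object of class `oct_design`: a list with the design settings,
#'   the pilot statistics used (`delta`, `sigma`, `gc_mean`, `test_mean`),
#'   `n_test_raw`, integer `n_test`, `n_gc`, `n_total`, and the
#'   `achieved_power` from [power_two_sample()] at the integer sizes.
#'   [tidy()] and [glance()] methods return it as a tibble.
#' @examples
#' oct_cohort() |>
#'   estimate_sample_size("volume", "m6", method = "B", effect_size = 0.20)
#' @export
estimate_sample_size <- function(cohort, metric = c("thickness", "volume"),
                                 followup = c("m2", "m6"),
                                 method = c("A", "B"),
                                 effect_size = 0.20, alpha = 0.05,
                                 power = 0.80, kappa = 1,
                                 inflate_for_dropout = NULL) {
  metric <- arg_match(metric)
  followup <- arg_match(followup)
  method <- arg_match(method)

  base_stats <- summarize_metric(cohort, metric, "baseline")
  fup_stats <- summarize_metric(cohort, metric, followup)
  arms <- arm_means(effect_size, base_stats$mean, fup_stats$mean, method)
  sigma <- if (method == "A") {
    fup_stats$sd
  } else {
    summarize_change(cohort, metric, followup)$sd
  }

  raw <- n_per_arm_raw(arms$delta, sigma, alpha, power, kappa)
  n_test <- as.integer(ceiling(raw))
  n_gc <- as.integer(ceiling(kappa * raw))
  if (!is.null(inflate_for_dropout)) {
    if (inflate_for_dropout < 0 || inflate_for_dropout >= 1) {
      abort("inflate_for_dropout must lie in [0, 1)")
    }
    n_test <- as.integer(ceiling(n_test / (1 - inflate_for_dropout)))
    n_gc <- as.integer(ceiling(n_gc / (1 - inflate_for_dropout)))
  }

  structure(
    list(
      metric = metric, followup = followup, method = method,
      effect_size = effect_size, alpha = alpha, power_target = power,
      kappa = kappa,
      delta = arms$delta, sigma = sigma,
      gc_mean = arms$gc_mean, test_mean = arms$test_mean,
      n_test_raw = raw, n_test = n_test, n_gc = n_gc,
      n_total = n_test + n_gc,
      achieved_power = power_two_sample(n_test, n_gc, arms$delta, sigma, alpha)$power,
      n_pilot = base_stats$n,
      dropout = inflate_for_dropout %||% 0
    ),
    class = "oct_design"
  )
}

#' @export
print.oct_design <- function(x, ...) {
  unit <- if (x$metric == "thickness") "µm" else "mm³"
  cat(sprintf(
    "Two-arm sample size, mGCIPL %s at %s months (Method %s)\n",
    x$metric, sub("^m", "", x$followup), x$method
  ))
  cat(sprintf(
    "  pilot: n = %d eyes; delta = %.4g %s, sigma = %.4g %s\n",
    x$n_pilot, x$delta, unit, x$sigma, unit
  ))
  cat(sprintf(
    "  effect size %.0f%%, alpha %.3g (two-sided), power target %.0f%%, kappa %g\n",
    100 * x$effect_size, x$alpha, 100 * x$power_target, x$kappa
  ))
  cat(sprintf(
    "  n per test arm %d, per control arm %d, total %d (raw %.2f)\n",
    x$n_test, x$n_gc, x$n_total, x$n_test_raw
  ))
  cat(sprintf("  achieved analytic power %.4f\n", x$achieved_power))
  invisible(x)
}

#' @rdname estimate_sample_size
#' @param x An `oct_design` object.
#' @param ... Unused.
#' @method tidy oct_design
#' @export
tidy.oct_design <- function(x, ...) {
  tibble(
    metric = x$metric, followup = x$followup, method = x$method,
    effect_size = x$effect_size, alpha = x$alpha,
    power_target = x$power_target, kappa = x$kappa,
    delta = x$delta, sigma = x$sigma,
    n_test_raw = x$n_test_raw, n_test = x$n_test, n_gc = x$n_gc,
    n_total = x$n_total, achieved_power = x$achieved_power
  )
}

#' @rdname estimate_sample_size
#' @method glance oct_design
#' @export
glance.oct_design <- function(x, ...) {
  tibble(
    n_total = x$n_total, n_test = x$n_test, n_gc = x$n_gc,
    achieved_power = x$achieved_power, n_pilot = x$n_pilot
  )
}

#' Sample sizes over a full design grid
#'
#' [estimate_sample_size()] over the Cartesian product of effect sizes,
#' power targets, methods, metrics and follow-up visits — by default five
#' protective effect sizes (20–60%), three power targets (80/90/95%), both
#' methods and both metrics at both visits: 120 cells.
#'
#' @inheritParams estimate_sample_size
#' @param effect_sizes,powers,methods,metrics,followups Grid axes.
#' @return A tibble of class `oct_design_grid`, one row per cell, the columns
#'   of [tidy()] on each design.
#' @examples
#' grid <- oct_cohort() |> sample_size_grid()
#' dplyr::filter(grid, effect_size == 0.2, power_target == 0.8)
#' @export
sample_size_grid <- function(cohort,
                             effect_sizes = c(0.20, 0.30, 0.40, 0.50, 0.60),
                             powers = c(0.80, 0.90, 0.95),
                             methods = c("A", "B"),
                             metrics = c("thickness", "volume"),
                             followups = c("m2", "m6"),
                             alpha = 0.05, kappa = 1) {
  cells <- tidyr::expand_grid(
    followup = followups, effect_size = effect_sizes, power = powers,
    method = methods, metric = metrics
  )
  if (nrow(cells) == 0) abort("all grid axes must be non-empty")
  out <- purrr::pmap(cells, function(followup, effect_size, power, method, metric) {
    tidy(estimate_sample_size(
      cohort,
      metric = metric, followup = followup, method = method,
      effect_size = effect_size, alpha = alpha, power = power, kappa = kappa
    ))
  }) |>
    purrr::list_rbind()
  class(out) <- c("oct_design_grid", class(out))
  out
}

#' @describeIn sample_size_grid Heatmap-style plot of total N per cell,
#'   faceted by method and metric.
#' @param object An `oct_design_grid` tibble.
#' @param ... Unused.
#' @method autoplot oct_design_grid
#' @export
autoplot.oct_design_grid <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = factor(100 * .data$power_target),
      y = factor(100 * .data$effect_size), fill = .data$n_total,
      label = .data$n_total
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(colour = "white", size = 3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$followup),
      cols = ggplot2::vars(.data$method, .data$metric)
    ) +
    ggplot2::labs(
      x = "Power target (%)", y = "Protective effect size (%)",
      fill = "Total N"
    ) +
    ggplot2::theme_minimal()
}
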