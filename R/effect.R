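#' Mean loss from baseline in the control arm
#'
#' The deterioration the design is built around: the control (glucocorticoid)
#' arm's mean at baseline minus its mean at the follow-up visit, in the
#' metric's units. A negative loss (an improving endpoint) is allowed but
#' flagged with a warning.
#'
#' @param mean_baseline Control-arm mean at baseline.
#' @param mean_followup Control-arm mean at the follow-up visit.
#' @return `mean_baseline - mean_followup`, a double.
#' @examples
#' mean_loss(0.534, 0.376)
#' @export
mean_loss <- function(mean_baseline, mean_followup) {
  stopifnot(is.finite(mean_baseline), is.finite(mean_followup))
  loss <- mean_baseline - mean_followup
  if (any(loss < 0)) {
    warn("negative mean loss: the endpoint improves over follow-up")
  }
  loss
}

#' Treatment mean difference implied by a protective effect size
#'
#' A protective effect size of `e` means the test drug prevents a fraction `e`
#' of the control arm's mean loss from baseline. The implied between-arm mean
#' difference is therefore
#' \deqn{\delta = e \times (\mu_{baseline} - \mu_{followup}),}
#' and it is identical for the follow-up-value comparison (Method A) and the
#' change-score comparison (Method B), because the mean of paired differences
#' equals the difference of means.
#'
#' @param effect_size Fraction of the control-arm loss prevented, in (0, 1].
#' @param loss Control-arm mean loss from baseline ([mean_loss()]).
#' @return `effect_size * loss`, in the metric's units.
#' @examples
#' effect_delta(0.20, mean_loss(0.534, 0.376))
#' @export
effect_delta <- function(effect_size, loss) {
  if (any(effect_size <= 0) || any(effect_size > 1)) {
    abort("effect_size must lie in (0, 1]: a zero effect makes the required n infinite")
  }
  effect_size * loss
}

#' Arm means implied by an effect size, for both estimation methods
#'
#' Expands a protective effect size into the quantities each method compares:
#' under Method A the test-drug arm retains more tissue, so its follow-up mean
#' is the control follow-up mean plus delta; under Method B the test arm's
#' mean change from baseline is `(1 - effect_size)` times the control loss.
#' Either way the between-arm difference is the same delta.
#'
#' @inheritParams effect_delta
#' @param mean_baseline,mean_followup Control-arm means at baseline and at the
#'   follow-up visit.
#' @return A one-row tibble: `effect_size`, `loss`, `delta`, `gc_mean`,
#'   `test_mean` (the per-arm means that the chosen analysis compares),
#'   `method`.
#' @param method `"A"` (follow-up values) or `"B"` (change scores).
#' @examples
#' arm_means(0.20, 0.534, 0.376, method = "A")
#' arm_means(0.20, 0.534, 0.336, method = "B")
#' @export
arm_means <- function(effect_size, mean_baseline, mean_followup,
                      method = c("A", "B")) {
  method <- arg_match(method)
  loss <- mean_loss(mean_baseline, mean_followup)
  delta <- effect_delta(effect_size, loss)
  if (method == "A") {
    gc_mean <- mean_followup
    test_mean <- mean_followup + delta
  } else {
    gc_mean <- loss
    test_mean <- (1 - effect_size) * loss
  }
  tibble(
    effect_size = effect_size, loss = loss, delta = delta,
    gc_mean = gc_mean, test_mean = test_mean, method = method
  )
}
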