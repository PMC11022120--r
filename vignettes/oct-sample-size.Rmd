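---
title: "Designing neuroprotection trials on OCT mGCIPL endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing neuroprotection trials on OCT mGCIPL endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octpower)
library(dplyr)
```

## The design problem

AQP4-IgG seropositive optic neuritis destroys retinal ganglion cells, and the
damage is visible on OCT as thinning of the macular ganglion cell plus inner
plexiform layer (mGCIPL). A neuroprotective drug, given on top of standard
glucocorticoid (GC) treatment, would be expected to slow that thinning. This
package answers the planning question for a two-arm parallel trial of such a
drug: **how many patients per arm are needed to detect, with given power, a
drug that prevents a stated fraction of the mGCIPL loss seen under GC
treatment alone?**

The pilot information comes from a small longitudinal cohort — five affected
eyes of four seropositive patients, measured at symptom onset and at 2 and 6
months — shipped with the package (`oct_cohort()`). Two endpoint metrics are
available per eye: mGCIPL thickness (µm) and mGCIPL volume (mm³). Eyes are
treated as independent sampling units, exactly as in the pilot analysis; the
within-patient correlation of the one patient who contributed both eyes is
not modelled.

## The model

All machinery is the classical two-sample normal approximation. Writing
$\mu_{GC}$ and $\mu_{test}$ for the arm means of the analysed quantity,
$\sigma$ for their common SD, $\kappa = n_{GC}/n_{test}$ for the allocation
ratio, and $z_p$ for standard-normal quantiles, the test-arm size is

$$
n_{test} \;=\; \Bigl(1 + \tfrac{1}{\kappa}\Bigr)
\left( \frac{\sigma\,(z_{1-\alpha/2} + z_{1-\beta})}
            {\mu_{GC} - \mu_{test}} \right)^{\!2},
$$

and the power achieved at given integer arm sizes is the two-term expression

$$
1-\beta \;=\; \Phi(Z - z_{1-\alpha/2}) + \Phi(-Z - z_{1-\alpha/2}),
\qquad
Z = \frac{\mu_{GC}-\mu_{test}}{\sigma\sqrt{1/n_{GC}+1/n_{test}}}.
$$

Two choices of the analysed quantity are supported:

* **Method A** compares the *follow-up values* themselves. $\sigma$ is the SD
  of the control arm's follow-up measurements.
* **Method B** compares *change scores* (baseline minus follow-up, positive
  when tissue is lost), analysed as a two-sample comparison. $\sigma$ is the
  SD of the per-eye paired differences.

A change score removes the between-eye baseline spread, so Method B's
$\sigma$ — and hence its required $n$ — can be much smaller when baseline and
follow-up are strongly correlated, as they are for thickness. For the
volume endpoint at 6 months the paired differences happen to be *more*
variable than the follow-up values, and Method B demands the larger trial;
which method is efficient is an empirical property of the pilot data, not a
theorem.

### The protective effect size

The trials being planned have no observed treatment arm, so the alternative
hypothesis must be constructed. The package interprets a *protective effect
size* $e \in (0, 1]$ as: **the drug prevents a fraction $e$ of the control
arm's mean loss from baseline.** The between-arm difference is then

$$ \delta = e \times (\mu_{baseline} - \mu_{followup,GC}), $$

identical under both methods (the mean of paired differences is the
difference of means). The source analysis never wrote this formula down; we
fixed the interpretation by requiring it to reproduce the published worked
design (2-month volume, Method A, $e=0.2$, 131 per arm), which it does and
which the alternative readings ($e$ times the follow-up mean, or $e$ times
the baseline mean) do not. `effect_delta()` and `arm_means()` implement it;
the reverse-engineered status is worth remembering when comparing against
other software.

## Numerical choices

* **Unrounded pilot statistics.** Every $\delta$ and $\sigma$ enters at full
  double precision. This matters: the 6-month volume SD is 0.08355 — rounding
  it to the printed 0.084 changes the Method A total from 140 to 142.
  Summaries are rounded only for display.
* **Sample SD** uses the $n-1$ denominator; it is the convention that
  reproduces every published pilot SD.
* **Normal quantiles at full precision** ($z_{0.975} = 1.959964\ldots$, never
  1.96).
* **Ceiling, per arm.** `estimate_sample_size()` returns
  $n_{test} = \lceil n_{raw} \rceil$ and
  $n_{GC} = \lceil \kappa\, n_{raw} \rceil$: the conservative standard,
  guaranteeing the achieved analytic power meets the target. The published
  grid is not internally consistent on this point (a few cells match
  round-to-nearest instead, e.g. a 2-month volume cell printing 350 where the
  ceiling gives 352, or 160 versus 162); the package applies the ceiling
  globally rather than chase mixed conventions cell by cell.
* **Two-term power.** The far tail $\Phi(-Z-z_{1-\alpha/2})$ is kept even
  though the sample-size formula inverts only the first term. The
  discrepancy is below $10^{-6}$ at all design-relevant powers
  ($\ge 0.75$ or so), which is why "smallest $n$ whose power meets the
  target" and "ceiling of the closed form" agree there — a property the test
  suite checks by brute force. At very low targets (power near 0.5) the far
  tail can pull the crossing down by one patient; the package reports the
  closed-form inversion regardless.
* **Degenerate inputs.** $\delta = 0$ (no assumed effect) and $\sigma \le 0$
  are errors, not infinities; an improving endpoint (negative loss) is
  allowed with a warning. Median of an even-sized cohort is the midpoint of
  the central pair.

## Worked designs

```{r headline}
cohort <- oct_cohort()

# the published worked example: 2-month volume, follow-up comparison
estimate_sample_size(cohort, "volume", "m2", method = "A", effect_size = 0.20)

# the headline design: 6-month volume, change-score comparison
headline <- estimate_sample_size(cohort, "volume", "m6", method = "B",
                                 effect_size = 0.20)
headline
glance(headline)
```

The full grid over effect sizes 20–60%, powers 80/90/95%, both methods, both
metrics and both visits (120 designs):

```{r grid}
grid <- sample_size_grid(cohort)
grid |>
  filter(effect_size == 0.20, power_target == 0.80) |>
  select(metric, followup, method, n_test, n_gc, n_total, achieved_power)
```

```{r gridplot, fig.width = 7, fig.height = 4}
autoplot(grid)
```

## Monte Carlo validation

`simulate_trial_power()` draws the two arms from normals with the design's
common $\sigma$ and applies the two-sided z-test. Because that statistic
depends on the data only through the arm means, the simulator draws the
means directly from their exact sampling distributions — one normal draw per
arm per replicate — so even the full 120-cell sweep at 10,000 replicates per
cell runs in seconds. A Welch-t option (`test = "welch"`) simulates full
samples for sensitivity analysis; at the arm sizes these designs produce
($n \ge 16$) the z-versus-t difference is far below Monte Carlo resolution.

```{r sim}
simulate_design(headline, replicates = 100000, seed = 42)
```

## The synthetic cohort generator

`generate_cohort()` exists because the real pilot is five eyes: it lets the
whole pipeline be exercised, and its calibration checked, at any size. The
model is deliberately the simplest one consistent with the pilot's
structure:

* baseline $\sim N(\mu_0, \sigma_0)$, truncated at zero (layer measurements
  are physically positive; at the defaults the truncation is a $4\sigma$
  event and negligible);
* follow-up $= \text{baseline} \times (1 - \ell\,(1 - e)) + \varepsilon$,
  where $\ell$ is the visit's loss fraction and $e$ the treatment effect
  ($e = 0$ for a control arm);
* the two follow-up residuals share an eye-level component giving them
  correlation $\rho$.

Defaults emulate the pilot volume endpoint: $\mu_0 = 0.534$,
$\sigma_0 = 0.134$ mm³, losses of 30% by 2 months and 37% by 6 months, and
residual SD 0.03 mm³ (chosen as the scale of test–retest variation small
relative to the between-eye spread; the pilot cannot identify it
separately). The correlation default $\rho = 0.7$ has **no empirical basis**
in the pilot — it is a placeholder producing realistic-looking trajectories,
and nothing in the two-sample formulas consumes it.

What the generator does *not* emulate: within-patient correlation between
fellow eyes, measurement floor/ceiling effects, segmentation failures,
non-normal heavy tails, or dropout. Passing tests on synthetic cohorts
therefore validate the *arithmetic* of the pipeline (estimation inverts
power; simulation matches the formula; summaries recover generating
parameters), not the adequacy of the normal model for any particular real
population.

```{r endtoend}
end_to_end(cohort_model(n_eyes = 60), seed = 7, replicates = 5000,
           effect_sizes = 0.20, powers = 0.80) |>
  select(followup, method, n_total, achieved_power, empirical_power, flagged)
```

## Tunable parameters at a glance

| parameter | meaning | default | note |
|---|---|---|---|
| `alpha` | two-sided type-I error | 0.05 | always two-sided |
| `power` | target $1-\beta$ | 0.80 | grid also uses 0.90, 0.95 |
| `kappa` | $n_{GC}/n_{test}$ | 1 | total $N$ is minimized at 1 for equal $\sigma$ |
| `effect_size` | fraction of GC-arm loss prevented | 0.20 | grid 0.20–0.60 |
| `inflate_for_dropout` | post-hoc per-arm inflation $n/(1-f)$ | off | bookkeeping only, no dropout model |
| `test` (simulator) | `"z"` known-$\sigma$ or `"welch"` | `"z"` | matches the analytic formula |

## Limitations

The pilot is five eyes; its SDs are estimated with enormous uncertainty, and
everything downstream inherits that. The package propagates the pilot
numbers faithfully rather than pretending otherwise — treat the grid as a
reproducible translation of stated assumptions into patient counts, not as a
guarantee about future trials. Known limitations shared with the source
analysis: a fixed known-$\sigma$ normal approximation (no noncentral-t), no
unequal-variance formula, no modelling of the time course between visits,
and no within-patient correlation for bilateral cases. Sizes reported by the
test suite and in this vignette are computed at run time from the packaged
cohort; simulations here use 5,000–100,000 replicates, sizes chosen so the
Monte Carlo standard error is well below the differences being checked.
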