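---
title: "Generalizing cohort estimates with the continuum of resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizing cohort estimates with the continuum of resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contresist)
```

## The problem

Participants in epidemiological cohorts self-select: compared with the full
invited population they tend to be healthier, of higher socioeconomic
status, and more often native-born. Prevalences, incidence rates and
survival curves estimated from participants alone therefore need not
generalize to the population the cohort was meant to describe. The
continuum-of-resistance idea treats willingness to participate as a latent
ordering: the most reluctant observed participants should resemble the
unobserved non-participants more than keen participants do. In a cohort
with a baseline examination and a later re-examination, the baseline
participants who *declined* the re-examination are exactly such a
reluctant group, and this package exploits them in two ways.

Write a population statistic (a prevalence, outcome proportion, or mean
follow-up time) as its exact decomposition over participation groups,

$$\bar y \;=\; \omega_r \bar y_r \;+\; \omega_{b\setminus r}\,\bar
y_{b\setminus r} \;+\; (1-\omega_r-\omega_{b\setminus r})\,\bar y_n,$$

with $\omega_r$ and $\omega_{b\setminus r}$ the population shares of
re-examination and baseline-only participants, and $\bar y_r$,
$\bar y_{b\setminus r}$, $\bar y_n$ the group values
(`decompose_population()`).

* **Substitution** assumes $\bar y_n = \bar y_{b\setminus r}$, giving
  $\hat{\bar y} = \omega_r \bar y_r + (1-\omega_r)\bar y_{b\setminus r}$
  (`substitution_estimate()`). The estimate is a convex combination of
  observed values and cannot leave their range.
* **Extrapolation** assumes the statistic observed in growing participant
  subsets is *linear* in the included population share $x$:
  $\bar y = \alpha + \beta x$. The line is pinned by the two observable
  points $(x_r, \bar y_r)$ and $(x_b, \bar y_b)$ — the re-examination group
  and the pooled baseline participants — and read off at full participation
  $x = 1$ (`fit_extrapolation_line()`, `extrapolation_estimate()`). Its
  leverage $(1-x_b)/(x_b-x_r)$ is about 8.4 at the MDC shares, so it can
  (deliberately) land outside the observed range, and small input errors
  are amplified correspondingly.

Incidence rates (events per 10,000 person-years) are ratios, so the
substitution step is applied to outcome proportions and mean follow-up
times separately and the rate recomputed (`substitute_rate()`); this equals
the person-time-weighted mean of the group rates. Extrapolation of rates
operates directly on the rate scale, treating the group rate like any
other group statistic. Whether the published tables extrapolated rates on
the rate scale or via the proportion/follow-up decomposition is not stated;
the rate-scale choice reproduces the printed cells within rounding for all
rows, which is why it is the package's convention.

When the population value is itself observed (register linkage, or
simulation), the unobserved non-participant value follows algebraically,
$\bar y_n = (n\bar y - n_b \bar y_b)/(n - n_b)$
(`back_out_nonparticipants()`), and every candidate column can be scored by
its mean squared error against the population column
(`mse_vs_population()`, `summary()` on a fit). MSEs are kept separate per
scale (squared percentage points vs. squared rate units), never pooled.

## Conventions and numerical choices

* **Shares come from integer counts.** All $\omega$ and $x$ quantities are
  ratios of group counts (`group_shares()`), never re-derived from rounded
  percentages, because the extrapolation leverage turns half-a-digit input
  rounding into multi-digit output movement.
* **Pooled baseline from counts.** For extrapolation the pooled value
  $\bar y_b$ is by default recomputed as the count-weighted
  (person-time-weighted, for rates) mean of the re-examination and
  baseline-only cells rather than read from an independently rounded
  printed column; `pooled = "printed"` restores the alternative. On the
  published risk-factor table the counts choice keeps every recomputed
  extrapolation cell within about one printed digit, while the printed
  pooled column can be off by several (e.g. obesity, where rounding the
  pooled cell to 13 flattens the line entirely).
* **Scales are explicit.** Percentages live on 0–100 exactly as printed,
  proportions on 0–1; nothing converts implicitly.
* **Clipping.** Extrapolated values outside the statistic's valid range are
  clipped and flagged (`clipped`), with the raw value retained
  (`extrapolation_raw`). Substitution never needs clipping.
* **Report rounding** uses half-up (`round_half_up()`), matching how the
  published tables print; raw values are kept internally.
* **Rounding tolerances in the tests.** Printed inputs are rounded, so
  recomputed derived cells are compared with propagated-rounding bounds:
  one unit of the last printed digit for substitution (convex weights plus
  output rounding) and 1.5 units for extrapolation (leverage-amplified).
  The backing-out identity has leverage $(n + n_b)/n_n \approx 2.4$ at the
  MDC counts, so a half-digit input perturbation can move the backed-out
  value by up to about 1.2 digits; rows printed at mixed precisions can
  move further still in units of their finer digit. Published MSE scores
  were computed from unrounded register data; recomputation from rounded
  columns reproduces the prevalence MSEs within 0.5 squared percentage
  points and the rate MSEs within 10% relative, with the method ranking
  reproduced exactly.

## Survival curves

`km_fit()` computes the product-limit estimator (via the survival
package), with events preceding censorings at tied times. The two
population adjustments are authored here:

* `km_mixture()` averages group curves pointwise on the union of their
  jump times; the substitution curve mixes the re-examination and
  baseline-only curves with weights $(\omega_r, 1-\omega_r)$.
* `km_extrapolate()` applies the two-point line pointwise to
  $(x_r, S_r(t))$ and $(x_b, S_b(t))$ and evaluates at $x=1$. The
  transform is affine, so extrapolating survival and extrapolating
  cumulative incidence are the same operation (asserted in the tests).
  Raw pointwise values need not form a valid survival function; they are
  clipped into $[0,1]$ and made non-increasing by a running minimum, and a
  message reports whenever either repair changed anything. The repair
  policy is this package's documented choice — the original analyses do
  not state one.

## The synthetic cohort

Because the motivating register data are closed, `simulate_cohort()`
generates an invited population whose truth is known by construction,
against which every estimator is validated:

* a rank-uniform latent propensity $u \sim U(0,1)$ per invitee, making
  "share of the population participating" the literal abscissa of the
  extrapolation model;
* nested participation thresholds: baseline participation for the top
  `target_x_b` = 0.407 of propensity, re-examination for the top
  `target_x_r` = 0.336 (the MDC shares); `reexam_noise` (default 0.05)
  re-randomizes a baseline participant's re-examination status
  independently of propensity — preserving the marginal share while
  breaking the perfect continuum, so the harness can show failure modes,
  not just successes;
* binary covariates with prevalence linked to $u$ (`linear`, `logistic`,
  or `step`); the step link jumps at the re-examination threshold by
  default, which constructs a world where non-participants are distributed
  exactly like baseline-only participants — the substitution model's
  assumption made true, used to demonstrate its exactness;
* an exponential event time with hazard
  $\lambda_0 e^{s(u-0.5)}$, administratively censored at 15.33 years. The
  defaults $\lambda_0 = 0.028$/year, $s = -0.55$ reproduce the qualitative
  MDC pattern: a participant/population mortality-rate ratio of about
  0.84, with group mortality ordered non-participants > baseline-only >
  re-examination;
* pre-follow-up exclusions (death/emigration before follow-up start) drawn
  with probability 0.122 — the fraction the MDC exclusion step removed —
  independently of propensity, flagged in the records and dropped once at
  load time;
* a truth ledger computed from all non-excluded invitees *before* any
  participation subsetting: covariate prevalences, the all-cause rate,
  mean follow-up, survival at 5/10/15 years, and per-group means (whose
  recombination under `decompose_population()` reproduces the population
  truth to machine precision — a conservation law the tests assert).

Default sample size is the MDC's 65,068. One latent variable drives both
participation and hazard; there is no separate frailty, no emigration
process beyond censoring, and no calibration to the real covariate joint
distribution. Passing tests on this generator therefore show that the
estimators recover truths *under a propensity continuum of the assumed
form* — linearity for extrapolation, group-equivalence for substitution —
not that real cohorts satisfy those assumptions.

Under the noise-free linear link the extrapolation estimator is exactly
unbiased: the mean over the top-$x$ fraction of a linear function of a
uniform rank is itself linear in $x$, so the two-point line passes through
the population mean at $x=1$. `recovery_experiment()` confirms this
numerically (|bias| below 0.3 percentage points at $n = 50{,}000$ over 200
replicates in the acceptance tests) and, with the step link, the
substitution analogue. Problem sizes in the test suite — 200 replicates of
50,000 for linear recovery, 100 of 20,000 for substitution exactness,
20,000 for the mixture-curve oracle, 65,068 for the ordering check — were
chosen to keep Monte-Carlo error an order of magnitude below the asserted
bounds.

## Known limitations

* Both estimators are deterministic transforms of group summaries; no
  standard errors or confidence intervals are produced (the published
  analyses report none), and only two participation waves are supported —
  the line is a two-point fit, not a regression over many waves.
* Extrapolation requires a non-empty baseline-only group ($x_b > x_r$);
  with none, the slope is undefined and the fit raises rather than
  silently returning participant-only values.
* Printed-table reproduction is limited by input rounding; exact printed
  cells are only guaranteed where the published setup used the same
  rounded inputs (the risk-factor table's headline cells).
* The backing-out identity holds for count-weighted-linear statistics
  (means, proportions, prevalences); for rates it is applied to the
  proportion and follow-up components, not to the rate itself.
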