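---
title: "Timing strategies under risky gain functions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing strategies under risky gain functions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskytiming)
```

## The task and the decision problem

In a coincident timing task a participant presses a button some time after a
visual cue and earns points according to a *gain function* `G(t)` of the
executed response time `t` (ms). The target time is 2300 ms and the maximum
one-trial gain is 100 points. Four canonical payoff schedules are studied:

* **no risk** — a symmetric tent, `t/23` before the target, `-t/23 + 200`
  after it; every plausible response earns something;
* **step** — 100 points anywhere in the closed window `[1900, 2700]`, zero
  outside;
* **risk after** — `t/23` up to and including the target, zero afterwards:
  reward grows right up to a cliff;
* **risk before** — the mirror image, zero before the target.

Boundary membership follows the task's printed inequalities: at exactly
2300 ms both asymmetric schedules pay 100 points. Responses are modelled as
Gaussian around a planned time `T`: `t ~ N(T, sigma^2)`, where `sigma` is
the participant's motor variability. A risk-neutral planner maximises the
expected gain

$$EG(T) = \int_{-\infty}^{\infty} G(t)\,\phi\!\left(\frac{t-T}{\sigma}\right)\frac{dt}{\sigma},$$

whose maximiser `T*` sits at the target under the symmetric schedules but
moves *away* from the target — increasingly so as `sigma` grows — under the
asymmetric ones, because part of the density would otherwise spill over the
cliff.

## Closed-form expected gain and the optimiser

Because every `G` here is piecewise linear, the integral is a finite sum of
truncated-Gaussian moments: for a segment paying `m t + c` on `(a, b]`,
with `z = (bound - T)/sigma`,

$$E[(mt+c)\,1_{(a,b]}] = m\left(T(\Phi(z_b)-\Phi(z_a)) - \sigma(\phi(z_b)-\phi(z_a))\right) + c(\Phi(z_b)-\Phi(z_a)).$$

`expected_gain()` sums these terms exactly; numeric quadrature exists in
the test suite only, as an independent oracle. Exact integration decouples
integration error from optimisation error.

`optimal_plan()` locates `T*` by a 1-ms grid over
`target ± (6 sigma + 500)` — a bracket wide enough to provably contain the
optimum for all four canonical gains — followed by a root polish of the
analytic derivative `dEG/dT` (obtained segment-wise in closed form). When
the derivative carries no sign change, as on the flat plateau of the step
gain at small `sigma`, a golden-section refinement is used instead. Ties
within `1e-9` points are broken toward the target time, then toward the
smaller time, so symmetric schedules return exactly 2300.0. For the
asymmetric schedules the first-order condition reduces to
`Phi(z) = (2300/sigma) phi(z)` with `z = (2300 - T)/sigma`;
`stationarity_residual()` exposes it as an optimiser-independent check,
and `optimal_plan()` satisfies it to well below `1e-6`. `sigma = 0` is a
degenerate case returning the argmax of `G` with the same tie-break — the
bootstrap grid starts there.

```{r optima}
optimal_plan(gain_no_risk(), sigma = 120)
optimal_plan(gain_risk_after(), sigma = 150)
```

## Bootstrap confidence interval for the optimal time

`bootstrap_ci()` follows the plain percentile recipe: for each `sigma` on a
grid (default 0–400 ms in 1-ms steps, interpretable as the plausible range
of human response SDs in this task), compute `T*(sigma)`, simulate 3000
sessions of 100 Gaussian trials at `(T*, sigma)`, take each session's mean,
sort, and read the 2.5% and 97.5% order statistics. The half-width is
approximately `1.96 sigma / sqrt(100)` by the CLT, which the tests verify;
the interval has zero width at `sigma = 0`. No bias correction or
studentisation is applied — the percentile method is the procedure being
modelled. Replicate streams derive from the top-level seed by a counter, so
evaluating a sub-grid reproduces the full run's values.

`classify_strategy()` compares an observed mean time with the interval at
the participant's SD: inside is risk-neutral; beyond the bound facing the
target (later than optimal under risk-after, earlier under risk-before) is
risk-seeking; beyond the far bound is risk-averse. The participant's
`sigma` for the lookup is the SD of their non-outlier trials in the risk
condition itself, and the mean — not the median — summarises the
distribution, as the response distributions are treated as Gaussian.

## Empirical optimum by distribution shifting

Independently of the Gaussian model, `empirical_optimum()` translates the
*raw observed sample* (not a binned histogram) along the time axis over a
±1500-ms grid in 1-ms steps and picks the shift maximising the total gain
`sum_i G(t_i + s)`. Total gain is piecewise constant in `s` between sample
breakpoints, so a 1-ms grid resolves the optimum to ±0.5 ms; exact ties go
to the smallest `|s|`, then the negative shift. The optimal mean time is
the observed mean plus the optimal shift, and on samples generated from the
Gaussian model it agrees with `optimal_plan()` up to sampling error.

## Trial-level preprocessing and the compensation analysis

Trials more than 2.5 SD from their session mean are flagged once (a single
pass; no iterative re-flagging) and excluded from every time statistic. A
*miss* is a trial earning exactly zero points; under the no-risk schedule
no plausible response misses. Observed total gain is reported as the sum
over all trials — what the session actually earned — while means, SDs, the
empirical optimum and the compensation analysis use non-outlier trials.

The lag-1 analysis defines the compensation on trial `n` as
`RT[n+1] - RT[n]` and the response error as the deviation from the
session's post-exclusion mean (each condition centred on its own mean).
Errors are sorted into four bins with edges `{-2M, -M, 0, M, 2M}`, where
`M = |mean RT - 2300|` is the participant's distance from the target in
their risk condition; `M` scales the bins so participants at different
distances from the penalty boundary are comparable, and the same `M` is
applied to that participant's no-risk session for the cross-condition
contrast. Two printed edge conventions are supported (`exp1`:
left-open/right-closed, errors `<= -2M` or `> 2M` dropped; `exp2` the
mirror). Pairs spanning an outlier-flagged trial are dropped entirely —
the alternative of keeping them produces artefactual giant compensations.
With these definitions the bin of errors just beyond `M` contains exactly
the miss trials of the risk condition, which is what makes the
post-miss-overcompensation contrast well defined. `paired_stats()`
implements the paired t with the paired-sample effect size
`d = mean(diff)/sd(diff)` (the variant is not dictated by the procedure
being modelled; the paired formulation matches the paired test).
Repeated-measures ANOVA is deliberately not reimplemented: per-bin paired
contrasts with descriptive means carry the same information for this
pipeline and keep the package focused on its own computations.

`split_half_check()` guards against learning trends by comparing the first
and last half of each session (two-sample pooled t per participant, paired
t across participants); sessions that do not hold 100 trials are split
proportionally with a warning.

## The synthetic-participant generator

No raw behavioral data accompany the analysis, so the generator is a
first-class module that emulates the statistical structure the analysis
assumes:

* Gaussian motor noise with per-participant `sigma` drawn log-normally,
  median 130 ms and `sdlog = 0.3` (≈ 70–240 ms for 95% of agents) — the
  range human response SDs span in this task;
* sessions of 100 trials at a 2300-ms target, with foreperiods of
  800–1200 ms logged but inert, keeping the log format faithful to the
  task;
* planning policies formalising the candidate explanations of risk
  seeking: `optimal` (plans `T*(sigma)`), `fixed_offset` (plans `delta` ms
  toward the target — behavioral risk seeking as an offset), and
  `variance_misestimation` (plans `T*(alpha sigma)` — overconfidence about
  one's own noise when `alpha < 1`);
* lag-1 dynamics `RT[n+1] = plan - beta (RT[n] - plan) - s kappa 1(miss) + eps`,
  with `|beta| < 1` for stationarity and the post-miss correction `kappa`
  pushing away from the penalty region (`s = +1` under risk-after, `-1`
  under risk-before).

Simulated times are not clipped at zero: the analysis is
translation-based and the response model lives on the whole real line.
What the generator does **not** emulate: reaction-time process models
(accumulators, scalar timing), drifts or learning within a session,
non-Gaussian tails, or any perceptual calibration of the interval. Passing
recovery tests therefore show that the pipeline correctly inverts its own
generative assumptions — not that real data satisfy them.

```{r cohort}
cohort <- simulate_cohort(4, session_config("risk_after"),
                          policy = "fixed_offset", delta = 115, seed = 1)
head(attr(cohort, "manifest"))
```

## Numerical and design choices

* Optimiser: 1-ms coarse grid, derivative root polish (`uniroot`,
  tolerance `1e-10`), golden-section fallback to `1e-6` ms; results are
  stable to well under 0.1 ms.
* Percentile convention: sorted replicate means, indices
  `floor(0.025 B)` and `ceiling(0.975 B)`; with one replicate the interval
  degenerates to that replicate's mean.
* Sub-seeds for sigma-grid points, agents, and pipeline stages derive from
  the top-level seed through a fixed integer recurrence, so runs are
  reproducible and grid subsets are stream-stable.
* The bootstrap grid's printed range (0 to 0.4 in 0.001 steps) is read in
  seconds and implemented as 0–400 ms in 1-ms steps; participant SDs fall
  inside this range.
* Degenerate inputs fail loudly: negative `sigma`, empty samples, fewer
  than 3 trials for outlier flagging, `M <= 0`, zero-variance paired
  differences.
* Test and example problem sizes — e.g. 500-session recovery runs, 1000
  classification sessions, 3000-replicate intervals — were chosen as the
  smallest sizes at which the Monte-Carlo standard errors are a small
  fraction of the effects being recovered.

## Limitations

The pipeline treats `sigma` as stationary within a session and shared
between planning and execution; it cannot distinguish the `fixed_offset`
from the `variance_misestimation` account on observed means alone (both
produce means closer than optimal to the target), though the generator can
produce either for method validation. Classification inherits the
bootstrap interval's assumption that the participant's SD is estimated
without error; with 100 trials that estimate carries ~7% relative error,
which slightly widens the effective interval around the lookup.
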