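---
title: "The two-generation growth model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-generation growth model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`clonalfx` simulates provisioning-mediated parental environmental effects in
a clonal plant across one parent–offspring cycle. This vignette documents
the model, its assumptions, the numerical choices behind the implementation,
and what the synthetic-data machinery can and cannot validate.

## The model and its assumptions

A scenario is a parent grown in one nitrogen environment whose vegetative
propagules grow up in another. Four stages are chained:

1. **Parent growth.** Dry mass follows the three-parameter logistic curve
   $M(t) = M_0 K / (M_0 + (K - M_0)e^{-rt})$ with $M_0 = 22.38$ mg,
   $r = 0.103\,\mathrm{day}^{-1}$, for 75 days. The capacity is an affine
   function of the nitrogen concentration,
   $K = \gamma N + \delta$ with $\gamma = 219.642$ mg per (mg N/L) and
   $\delta = 1965.396$ mg, so nitrogen acts purely through the asymptote,
   not the rate.
2. **Allometry.** The parent's final total mass $TM$ sets the expected
   propagule number $0.253\,TM^{0.684}$ (rounded half-away-from-zero,
   floored at 1) and the mean propagule mass $MM = 2.727\,TM^{0.354}$.
3. **Size distribution.** Individual propagule masses are i.i.d. Weibull
   draws with $\mathrm{shape} = 0.015\,MM + 0.674$ and
   $\mathrm{scale} = 1.183\,MM - 5.083$. The Weibull parameters come from
   the *deterministic* mean mass of stage 2, not from an intermediate
   sampled mean; with that wiring the implied Weibull mean
   $\mathrm{scale}\cdot\Gamma(1 + 1/\mathrm{shape})$ stays within 5% of
   $MM$ over the whole realistic range (30–90 mg), which the test suite
   checks numerically. Because the scale link has a negative intercept,
   mean masses at or below $5.083/1.183 \approx 4.30$ mg would imply a
   non-positive scale and are rejected as infeasible; under the default
   parameters this cannot arise (the smallest design parent implies
   $MM \approx 50$ mg).
4. **Survival and offspring growth.** A fixed fraction $SR$ of the pool
   survives and each survivor grows logistically and independently with its
   own mass as $M_0$ and the capacity of the offspring nitrogen level.

Model assumptions, stated explicitly: both generations share one growth
law and one $r$; propagules are fully fragmented, physically independent,
and neither share resources nor compete; propagule sizes are exchangeable
(position along the stem carries no information); and survival is
size-independent. The independence assumptions are most defensible for
aquatic ramet populations, which is the setting the parameter set describes.

## Tunable parameters

| Parameter | Unit | Default | Role |
|---|---|---|---|
| `M0` | mg | 22.38 | initial fragment mass (measured propagule mass) |
| `r` | day⁻¹ | 0.103 | relative growth rate, both generations |
| `gamma`, `delta` | mg/(mg N/L), mg | 219.642, 1965.396 | capacity–nitrogen link |
| `alpha1`, `beta1` | –, – | 0.253, 0.684 | propagule-number power law |
| `alpha2`, `beta2` | –, – | 2.727, 0.354 | mean-mass power law |
| `alpha3`, `beta3` | –, – | 0.015, 0.674 | Weibull shape link |
| `alpha4`, `beta4` | –, – | 1.183, −5.083 | Weibull scale link |
| `survival_rate` | fraction | 0.25–1.00 grid | design variable |
| `offspring_time` | days | 30–300 grid | design variable |

The factorial design defaults — parental and offspring N at 10–60 mg/L in
steps of 10, survival rates 25/50/75/100%, offspring times 30, 45, 60, 75,
150, 300 days, five replicates (4320 runs), and the propagule-stage
subdesign (6 × 4 × 5 = 120 runs) — are the published experiment and are not
treated as free knobs.

## Numerical and design choices

**Count rounding.** The expected propagule number is real-valued; realised
counts round half-away-from-zero with a floor of one, so any positive
parent leaves at least one propagule. The survivor count uses the same
rounding on $n \cdot SR$, making $SR$ an exact design variable rather than
a binomial probability — a deliberate choice that keeps the survival factor
noiseless in the ANOVA.

**Survivor selection.** Survivors are a uniformly random subset. Since
draws are i.i.d., any selection rule that ignores the values is
statistically equivalent; the subset keeps the bookkeeping honest (the test
suite checks thinning is unbiased for the surviving mean).

**Seeding.** One master seed per factorial; each scenario receives a
substream seed drawn up-front by scenario index, so any subset of the table
is reproducible independent of execution order. Weibull sampling goes
through the inverse-CDF transform of uniform draws for cross-platform
stability.

**Nonlinear fitting.** Growth curves are fitted by Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`, `ftol = 1e-10`) restarted from a
deterministic grid of rate starts (0.02, 0.05, 0.1, 0.2) with capacity
starts taken from a linear regression of per-level maximum mass on N;
the best converged restart wins. $M_0$ is fixed at the measured propagule
mass, not estimated — the three free parameters of the capacity-bearing
families are $r$, $\gamma$, $\delta$. The closed forms of the six families
are documented in `growth_curve()`; the power family uses $M_0(t+1)^b$ so
the curve is finite at $t = 0$. Power laws are fitted on the original scale
(matching the original nonlinear fits) with the log–log OLS solution as the
start, so exact log-log-linear data reproduce the OLS answer.

**Model selection.** Growth families are ranked by the least-squares
information criterion $n\log(\mathrm{rss}/n) + 2k$ (additive constant
dropped — only rankings are meaningful). Ties break toward fewer
parameters, then the fixed family order. Size distributions are ranked per
plant by the Cramér–von Mises statistic with AIC as the tie-break; the
statistic follows the standard order-statistic form
$1/(12n) + \sum_i (F(x_{(i)}) - (2i-1)/(2n))^2$, implemented directly and
cross-checked against `fitdistrplus::gofstat` in the tests. Distribution
parameterizations: normal (mean, sd), lognormal (meanlog, sdlog), gamma
(shape, rate), weibull (shape, scale).

**Sequential ANOVA.** The design variables enter as raw numeric covariates,
so every term has one degree of freedom and, with all interactions, the
full-factorial table has denominator df $4320 - 16 = 4304$ and the
propagule table $120 - 4 = 116$. Raw numeric interactions are not mutually
orthogonal, so Type-I (sequential) sums of squares depend on the term
order; the order used is the canonical product-expansion order of
`PN*ON*SR*T` (mains; PN:ON, PN:SR, ON:SR, PN:T, ON:T, SR:T; the
three-ways; the four-way), which is both R's default and the printed-table
order. The implementation is base `lm()` + `anova()`; the test suite
verifies it against an independent nested-model QR-projection oracle at
1e-8 relative. Degenerate inputs are handled explicitly: a constant
response reports $F = 0$ everywhere, a numerically exact fit reports
$F = \infty$ for signal-bearing terms and 0 for the rest, and
rank-deficient designs error with the collinear term named. p-values come
from the $F(1, \mathrm{df_{den}})$ distribution with no multiple-testing
correction.

## The synthetic-data generator

The generator emulates the two greenhouse experiments that the fitting
stages were designed for, so the whole stack is testable without any
external data.

* **Trajectory experiment**: 4 N levels (10, 20, 40, 60 mg/L) × 4 harvests
  (30, 45, 60, 75 d) × 4 replicates = 64 plants; mass = logistic mean ×
  $e^\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with
  $\sigma = 0.15$ by default. Multiplicative log-normal noise was chosen
  because biomass is positive and heteroscedastic; the real experiments'
  noise structure is unknown, and this is an assumption.
* **Propagule experiment**: 28 plants (7 per N level) grown 45 days. Per
  plant, total mass is the logistic mean times a log-normal *vigor* factor
  (`vigor_sd`, default 0.40) times measurement noise; count and mean mass
  follow the power laws applied to that observed mass with their own
  multiplicative noise; propagule masses are then Weibull draws.

The vigor component deserves explanation. At 45 days the four nitrogen
levels alone span only a ~1.35-fold range of parent mass, and a 28-point
power-law fit over so narrow a range cannot identify the exponents in the
presence of realistic noise. Real greenhouse fragments vary substantially
in individual vigor (the measured initial masses already had ~20% CV, and
total-biomass CVs of 30–50% within treatments are typical), and the
quality of the original allometric fits implies their parent masses were
well spread. A 40% between-plant vigor sd reproduces both: identifiable
exponents and power-law fits of roughly the reported quality.

**Zero-noise mode.** With `noise_sd = 0` and `vigor_sd = 0` the trajectory
rows sit exactly on the logistic surface and every fitted growth parameter
round-trips exactly. Integer propagule counts would still break exactness
of the number law by up to ~1%, so `gen_propagule_plants()` takes
`round_counts = FALSE` as a validation mode that keeps real-valued expected
counts; the default (`TRUE`) emits faithful integer counts.

**Recovery tolerances.** `recovery_tolerances()` fixes per-parameter
relative-error bands for the end-to-end recovery run, set in advance at
roughly twice the first-order standard error the designs propagate into
each estimate: $r$ 10%; $\gamma, \delta$ 25%; exponents $\beta_1$ 25% and
$\beta_2$ 45% (the mean-mass exponent is smaller, so the same absolute SE
is a larger relative one); scale-link slope $\alpha_4$ 45%; and the
power-law multipliers $\alpha_1, \alpha_2$ a wide factor-3 band, because a
multiplier's log-scale error is the exponent's error amplified by the mean
log-mass of the design (~7.4). The capacity intercept $\delta$ is the
hardest of these: it extrapolates the capacity line to $N = 0$, far
outside the 10–60 mg/L design, and its sampling spread in practice
somewhat exceeds the pre-set band, which the package reports honestly
rather than adjusting after the fact.

**What passing tests do and do not show.** The generator reproduces the
designs, the mean structure, and a plausible noise model — not the real
plants. Parameter-recovery results validate that the estimators invert the
generative model; they say nothing about model adequacy for real
*A. philoxeroides* data, greenhouse covariates (temperature, humidity),
root/shoot partitioning, or size-dependent survival.

## Problem sizes

The packaged tests run the full 4320-run factorial once and the 120-run
propagule factorial a handful of times; Monte-Carlo checks use $10^3$
replicate pools and $10^5$ draws for moment checks; oracle comparisons use
40-row random tables. A full pipeline run completes in seconds on a single
CPU.

## Known limitations

* Exactly two generations; no multi-generation accumulation of effects.
* Deterministic growth within a scenario — environmental stochasticity is
  not modelled, so all replicate variation comes from propagule sampling
  and survival thinning.
* Survival is size-independent and applied once, at fragmentation.
* The propagule-stage ANOVA's absolute F magnitudes depend on the residual
  variance contributed by the i.i.d. Weibull sampling of the pool;
  alternative unstated micro-conventions (e.g. pools rescaled to their
  expected mean) change those magnitudes substantially while leaving the
  significance pattern intact, and this package commits to the i.i.d.
  reading stated by the model's assumptions.
* No confidence intervals beyond rss-based summaries; no mixed-effects
  extensions for per-plant random curves.
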