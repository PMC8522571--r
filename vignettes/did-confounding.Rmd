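---
title: "Confounding, adjustment, and matching in difference-in-differences: the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounding, adjustment, and matching in difference-in-differences: the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(didconfound)
```

## The estimand and the model

Difference-in-differences (DiD) compares the pre-to-post outcome change of a
treated group with that of an untreated comparison group. The estimand is the
average treatment effect on the treated at posttreatment time $t^*$,

$$\mathrm{ATT}(t^*) = E\{Y^1(t^*) - Y^0(t^*) \mid D = 1\},$$

identified under no-anticipation, consistency, and *parallel trends*: the
untreated potential outcomes of both groups change identically in
expectation between any two time points. This package studies how a single
covariate $x_{it}$ can break parallel trends, and which adjustment or
matching strategies repair the damage.

Outcomes are generated from the linear panel model

$$y_{it} = \alpha_0 + \alpha_1 d_i + \zeta_t + \lambda_t x_{it}
          + \gamma\, p_t d_i + \varepsilon_{it},$$

with unit-constant treatment indicator $d_i$, time fixed effects $\zeta_t$,
posttreatment indicator $p_t = \mathbf{1}(t \ge t_0)$, an additive constant
treatment effect $\gamma$, and i.i.d. Gaussian noise. The covariate enters
with a possibly time-varying coefficient $\lambda_t$; its group mean path is

$$m_d(t) = a_0 + a_1 d + (b_0 + b_1 d)\,t,$$

plus, in scenario 6 only, a treatment-induced shift
$\Delta x(t) = \delta\,(t - t_0 + 1)$ for treated units after $t_0$.

The covariate-driven gap between group outcome trends is
$g(t) = \lambda_t\{m_1(t) - m_0(t)\}$ (computed along the *untreated*
covariate path, since parallel trends is a statement about untreated
potential outcomes). Parallel trends hold exactly when $g$ is constant in
$t$: a constant gap is absorbed by the group intercept. `violation_profile()`
returns $g$ and this flag; `classify_confounding()` distinguishes
*no confounding* ($g$ constant, $\delta = 0$), *covariate confounding*
($g$ non-constant), and a *treatment-affected covariate* ($\delta \neq 0$),
where the covariate additionally mediates part of the effect.

## The nine scenarios

```{r}
scenario_table()
```

Scenarios 1–3 use a time-invariant covariate: unequal group means with a
constant effect (1; harmless), unequal means with a time-varying effect
(2; confounded), equal means with a time-varying effect (3; harmless but
adjustment buys efficiency). Scenarios 4–6 use a time-varying covariate
whose group paths are parallel (4), divergent from baseline (5), or
divergent only after treatment and only because of it (6); the `a`/`b`
suffix selects a constant or time-varying $\lambda_t$.

With $\delta = 0$ the population ATT equals $\gamma$ ($= 1$ by default).
In scenario 6 the treatment moves the covariate, so the ATT gains a mediated
component: `true_att()` returns
$\gamma + \operatorname{mean}_{t \ge t_0} \lambda_t\,\delta\,(t - t_0 + 1)$.

### Default parameters

The numerical defaults are fixed in one place (`make_scenario()`) and
chosen so that every confounded cell exhibits bias that is large relative
to Monte Carlo error at the study's sample sizes: $\alpha_0 = 1$,
$\alpha_1 = 0.5$, $\zeta_t = 0.1t$, $\gamma = 1$, $\sigma_y = 1$,
$\sigma_x = 0.5$; constant schedule $\lambda = 1$ and time-varying schedule
$\lambda_t = 0.5 + 0.2t$ (outcome units per covariate unit); time-invariant
means $\mu_0 = 0$, $\mu_1 = 1$ (equal in scenario 3); time-varying process
$a_0 = 0$, $b_0 = 0.2$, with $a_1 = 0.5$ where group levels differ,
$b_1 = 0.2$ in scenario 5, and $\delta = 0.3$ in scenario 6. Scenario 6's
divergence is linear in elapsed posttreatment time — the simplest monotone
post-only form. Every value can be overridden per run; overrides that
contradict a scenario's defining structure (for example $\delta \neq 0$
outside scenario 6) raise an error rather than silently changing the
scenario's meaning.

## Estimators

All six estimators target the treated-by-post interaction coefficient.
Three regressions differ in the covariate terms:

* **simple** — time fixed effects, treated, treated×post; covariate ignored.
* **CA** — adds the covariate main effect $\lambda x_{it}$ (the common
  practice of adjusting "for" a covariate).
* **TVA** — adds covariate-by-time interactions $\lambda_t x_{it}$, one
  coefficient per time point, so a time-varying effect is in the span.

Three matching strategies pair each treated unit with its nearest control
(with replacement) by Euclidean distance on pooled-standardized vectors of
pretreatment outcome levels, pretreatment outcome first differences, or
pretreatment covariate values (the scalar value when the covariate is
time-invariant), then refit the simple model on the matched sample. Reused
controls enter through frequency weights rather than duplicated rows —
identical point estimates, cleaner clustering semantics — and distance ties
break to the lowest control unit id so that matches are reproducible.
Propensity-score distances, calipers, and matching on posttreatment values
are deliberately out of scope.

Standard errors are CR1 cluster-robust, clustered on unit:
$(X'WX)^{-1}\big[\sum_g X_g'W_g e_g e_g' W_g X_g\big](X'WX)^{-1}$ scaled by
$\frac{G}{G-1}\frac{N-1}{N-k}$. With singleton clusters this reduces to
HC1, which the test suite exploits as one of several oracles (alongside a
hand-computed example and a null-coverage simulation that checks the
nominal 95% interval covers between 93% and 97% of the time).

## The Monte Carlo engine

`run_study()` draws `n_reps` panels (default 400, each $n = 800$ units over
$T = 10$ times with five pretreatment periods and
$P(\text{treated}) = 0.5$), applies the requested estimators, and
aggregates three metrics against `true_att()`:

* mean absolute percent bias $|\bar{\hat\gamma} - \mathrm{ATT}| /
  |\mathrm{ATT}| \times 100$ (undefined at a zero ATT, by design — callers
  are directed to absolute bias);
* mean cluster-robust SE;
* RMSE, which dominates absolute bias by the bias–variance identity.

Reproducibility uses one master seed with L'Ecuyer-CMRG substreams:
replicate $k$ runs on substream $k$, so any single replicate can be
regenerated without storing panels, and identical `(seed, stream)` pairs
give bit-identical panels. A replicate on which an estimator fails is
excluded from that estimator's aggregate; more than 1% exclusions aborts
the study (matching can produce degenerate samples only at very small $n$,
so in practice the count is zero).

## What the generator emulates — and what it does not

The generator produces balanced unit-level panels, homoskedastic Gaussian
noise, serially independent covariate noise, a single covariate, a constant
additive effect, and a single adoption time. Real policy panels have
attrition, serial correlation, heterogeneous and dynamic effects, staggered
adoption, and many covariates; passing tests here show the estimators'
algebraic behavior under clean conditions, not robustness to any of those
features. An AR(1) covariate process would be a natural extension.

Two findings from running the default study deserve emphasis because they
are properties of the *parameterization*, not of the estimators in
general:

* **Matching regresses to the mean wherever groups differ in the matching
  variable.** The defaults put a 1–2 SD group gap in outcome levels and in
  the time-varying covariate. Nearest-neighbor matching then preferentially
  selects controls whose pretreatment noise is transiently high; the noise
  reverts after $t_0$ and biases the matched contrast — visibly even in
  scenarios without confounding (level-matching in scenarios 1 and 4a,
  covariate-matching in 4a/4b). With small group gaps this bias shrinks
  toward zero; the effect's size is a function of the gap-to-noise ratio,
  which is why matched and unmatched results can look interchangeable in
  one parameterization and far apart in another.
* **In scenario 6, the unadjusted estimators recover the total ATT.** When
  the only post-period divergence is treatment-caused, untreated potential
  outcome trends are parallel, and the simple DiD contrast consistently
  estimates direct + mediated effect; adjusting for the covariate (CA/TVA)
  removes the mediated path and *creates* bias relative to the total ATT.
  If part of the divergence were not treatment-caused (mediation mixed with
  confounding), no estimator in the suite would recover the ATT; that
  variant is expressible here only by overriding the covariate process.

## Numerical choices

* Parallel-trends constancy tolerance: absolute range of $g$ below
  $10^{-10}$ — all profile quantities are closed-form, so only
  floating-point noise is tolerated.
* Matching distances use a sum-of-squares expansion; exact-zero distances
  therefore surface as cancellation noise of order $\sqrt{\epsilon}$.
* Rank problems are not silently repaired: aliased coefficients raise a
  singular-design error (e.g., the CA model on a constant covariate, or
  noise-free time-invariant covariates that are collinear with the group
  indicator).
* Degenerate all-treated/all-control assignments are redrawn up to 100
  times, then error.

## Problem sizes used by the checks

The test suite runs each scenario at 200 replicates (seed 42) — enough to
put confounded cells hundreds of Monte Carlo SEs from the truth while
keeping the whole grid around five minutes on one core; the brute-force
parallel-trends oracle uses $10^6$ units; the coverage simulation uses
1000 replicates of a 120-unit, 4-period null panel. The acceptance script
(`scripts/acceptance.R`) reruns the four headline studies at 200
replicates. `analysis/03_monte_carlo.R` runs the full grid at 400
replicates.

## Known limitations

Linear outcome model only (no GLM links; parallel trends is
scale-dependent, so a logit/log variant is a different study); one
covariate; panel data rather than repeated cross-sections; 1:1
nearest-neighbor matching only; no doubly robust, synthetic-control, or
lagged-dependent-variable estimators. Scenario 6's printed ATT depends on
the chosen mediation form and defaults; its value is a property of this
parameterization, not a universal constant.
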