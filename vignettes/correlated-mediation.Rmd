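---
title: "Quasi-Bayesian mediation analysis with correlated mediators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-Bayesian mediation analysis with correlated mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrmediate)
```

## The model

corrmediate estimates how much of the per-unit effect of a continuous
exposure $A$ on an outcome $Y$ is transmitted through $K$ measured
mediators $M_1, \dots, M_K$, adjusting for confounders $C$. The working
structural model is linear with no exposure–mediator interaction:

$$
M_k = \beta_{k0} + \beta_{kA} A + \beta_{kC}' C + \varepsilon_k,
\qquad
Y = \theta_0 + \theta_A A + \sum_k \theta_{M_k} M_k + \theta_C' C + \eta,
$$

where the mediator residuals $\varepsilon = (\varepsilon_1, \dots,
\varepsilon_K)$ are jointly multivariate normal with covariance $\Sigma$.
$\Sigma$ is not assumed diagonal: the mediators may be substantially
correlated after confounder adjustment. What *is* assumed is that they do
not causally affect one another — their association is residual, not
structural. The other identifying assumptions are the usual sequential
ignorability conditions (no unmeasured exposure–outcome,
exposure–mediator, or mediator–outcome confounding given $C$), and that
the exposure does not causally affect the confounders.

Effects are defined counterfactually, as differences of expected potential
outcomes for an exposure contrast $a^\ast \to a$ (default one unit), and
are therefore expressed in outcome units:

* total effect: $E[Y(a, M(a)) - Y(a^\ast, M(a^\ast))]$;
* average direct effect (ADE): $E[Y(a, M(a^\ast)) - Y(a^\ast, M(a^\ast))]$;
* joint ACME: $E[Y(a, M(a)) - Y(a, M(a^\ast))]$;
* mediator-specific ACME for $M_k$: the target mediator is switched
  $a^\ast \to a$ while the non-target mediators are held at their
  $a^\ast$ potential values.

Under the linear no-interaction model these reduce to products of
coefficients: $\mathrm{ACME}_k = \theta_{M_k}\,\beta_{kA}\,(a - a^\ast)$,
$\mathrm{ADE} = \theta_A\,(a - a^\ast)$, and the decomposition identities
$\mathrm{total} = \mathrm{ADE} + \mathrm{ACME}_{\mathrm{joint}}$ and
$\mathrm{ACME}_{\mathrm{joint}} = \sum_k \mathrm{ACME}_k$ hold exactly —
the package asserts them on every draw. Because there is no interaction,
effects do not depend on the baseline level $a^\ast$, and the alternative
per-mediator convention (non-targets held at their $a$ values) coincides;
both facts are checked numerically in the test suite rather than taken on
faith.

## Estimation

The two structural components are fit by ordinary least squares:
the outcome model on $(1, A, M_1, \dots, M_K, C)$, and the mediator
system equation by equation on $(1, A, C)$. Since all mediator equations
share the same regressors, per-equation OLS coincides with the
seemingly-unrelated-regressions estimator and is jointly efficient.
$\Sigma$ is estimated from residual cross-products on $n - p$ degrees of
freedom, and the sampling covariance of the stacked mediator coefficients
is $\widehat\Sigma \otimes (X'X)^{-1}$. Coefficient covariances are the
classical homoskedastic estimators — the linear-normal machinery below
presumes them, and no robust option is offered.

Inference is quasi-Bayesian: $J$ draws of $(\theta, \beta)$ are simulated
from multivariate normals centred at the estimates with their sampling
covariances, the effect decomposition is evaluated per draw, and each
effect is summarised by

* the mean of its draws (the point estimate),
* the 2.5/97.5 percentile interval of the draws (at the default 95% level),
* a two-sided sign-based p-value
  $p = \max\!\big(2\min(\#\{d \le 0\}, \#\{d \ge 0\})/J,\; 2/J\big)$,
  reported as "< 2/J" at its floor.

Three conventions deserve flagging, since alternatives exist:

* **$\Sigma$ is plugged in at its estimate** rather than drawn; the
  coefficient uncertainty dominates in this scheme, and drawing $\Sigma$
  (e.g. from an inverse-Wishart) is left out of scope.
* **The point estimate is the mean of draws**, not the median; in this
  linear model the two agree to within Monte-Carlo error.
* **The p-value floor is $2/J$**, so a threshold $t$ can only be resolved
  when $J \ge 2/t$. With the default $J = 1000$ the floor is 0.002: small
  enough for the per-analysis Bonferroni threshold 0.05/6, not for the
  global 0.05/60, which needs $J \ge 2410$. Significance flags compare
  the floored value itself, so an unresolvable threshold is simply never
  passed — conservative, never anti-conservative.

Two estimation paths are provided and must agree. `method =
"closed_form"` (the default) evaluates the product-of-coefficients
reduction per draw. `method = "counterfactual"` simulates the
counterfactual compositions directly: per participant and Monte-Carlo
replicate it draws joint mediator residuals from $MVN(0,
\widehat\Sigma)$, forms $M(a)$ and $M(a^\ast)$, and averages the outcome
differences. The two exposure arms share residual draws (common random
numbers), which leaves the expectation unchanged, removes Monte-Carlo
variance in the linear case, and makes the path an exact cross-check of
the closed form; with independent draws per arm the agreement is within
Monte-Carlo error, and the test suite checks both.

```{r single-analysis}
cohort <- generate_cohort(cohort_config(n = 184), seed = 7)
fit <- mediate_multi(cohort, exposure = "temps_anxious", outcome = "edi_dt",
                     J = 500, seed = 7)
fit
```

## The analysis battery and two-tier error control

The intended application runs one mediation analysis per
exposure–outcome pair: five affective temperaments (TEMPS-A depressive,
cyclothymic, hyperthymic, irritable, anxious subscales) crossed with two
eating-psychopathology outcomes (EDI-2 drive for thinness and body
dissatisfaction), each with the three mediators state anxiety, trait
anxiety (STAI) and depressive symptoms (BDI), adjusted for age and BMI.
Each of the 10 analyses reports 6 effects, so the battery performs 60
tests. Family-wise error is controlled at 0.05 on two tiers by
Bonferroni: an intermediate per-analysis threshold $0.05/6 = 0.0083$ and
a global threshold $0.05/60 = 0.00083$, both applied with strict
inequality. Footnote markers `^a` (intermediate) and `^b` (global) are
attached in the formatted table. Each analysis refits both structural
models and draws fresh quasi-Bayesian samples from a sub-seed derived
from the master seed, so the whole battery is bit-reproducible.

## The synthetic cohort generator

Raw participant data for the motivating setting are not publicly
deposited, so the package ships a generator that emulates the
psychometric structure the analysis assumes, and all calibration
experiments run against it. Its defaults describe an inpatient anorexia
nervosa cohort of $n = 184$:

* **Published descriptives** anchor what is published: age $23.7 \pm
  8.7$ years, admission BMI $14.4 \pm 1.8$ kg/m², a 70.1%/29.9%
  restricting/binge–purging subtype split, TEMPS-A subscales bounded by
  their item counts (22, 20, 21, 21, 26; Yes/No scoring), STAI scores in
  20–80, BDI in 0–39.
* **Chosen once where nothing is published**: temperament subscale means
  and SDs, the structural coefficients, the mediator residual covariance
  (SDs 8/9/6 with pairwise residual correlation 0.5) and outcome noise
  SDs were set to values plausible for severely ill inpatients — e.g.
  STAI means in the mid-50s, BDI around 20, positive temperament paths
  except a protective hyperthymic one — and are not tuned thereafter.
  EDI-2 subscale bounds are not published in the motivating material;
  conventional ranges 0–21 (drive for thinness) and 0–27 (body
  dissatisfaction) are the configurable default.
* Bounded variables are drawn truncated-normal; mediators and outcomes
  are built from the structural equations. Scale scores are generated
  directly — no item-level simulation, since the analysis consumes
  totals only. The exposure is continuous in subscale points.

Generated values can be clipped into their instrument bounds and rounded
to integers, which is what real questionnaire totals look like — but
clipping biases the linear model at the margins. Estimator-calibration
experiments therefore default to clipping and rounding **off**
(`calibration_config()`), where the configured equations are the exact
truth. What passing calibration shows is that the estimator is correct
*under its own assumptions*; it does not show robustness to the
discreteness, floor/ceiling effects, non-normality or missingness of real
questionnaire data, nor to violations of sequential ignorability or to
mediators that do causally affect each other.

## Numerical and design choices

* Rank-deficient designs abort with the collinear columns named;
  constant mediators abort (zero residual variance); rows with missing
  values among analysis columns are dropped complete-case with a logged
  count.
* Multivariate normal draws use an eigendecomposition square root, so
  singular covariances (including the all-zero degenerate case, where
  every draw equals the point estimate) are handled exactly; matrices
  with negative eigenvalues beyond tolerance are rejected.
* Percentile intervals use the empirical quantiles of the draws
  (`stats::quantile` type 7); no normal approximation is applied.
* All randomness flows from a mandatory integer seed; sub-seeds for
  replicates and battery analyses are derived arithmetically and stay
  within the 32-bit range. Seeded functions restore the caller's RNG
  state.

## Validation at a glance

The test suite exercises, at sizes chosen to keep a full run around a
minute: exact recovery on noiseless fixtures and agreement with explicit
normal-equations oracles on 8-row hand fixtures; distributional fidelity
of the generator (200 replicates at $n = 1000$, residual covariance
entrywise within 4 Monte-Carlo SEs of $\Sigma$); per-draw decomposition
identities at $10^{-10}$ relative tolerance; closed-form versus
counterfactual agreement on 20 randomised configurations; bias $\le
0.02$ outcome units over 200 replicates at $n = 500$; 95%-interval
coverage within [92%, 98%] and null-ACME rejection within [2%, 8%] over
300 replicates at $n = 300$ with $J = 300$; and family-wise error under
a global-null battery $\le 7.5\%$ over 400 replicates with $J = 6000$
(chosen so the draw floor resolves the global threshold; coarser grids
inflate strict-threshold calls).

## Limitations

Linear models only: no binary or survival outcomes, no
exposure–mediator interactions, no robust covariance, no sensitivity
analysis for ignorability violations. The generator does not model
item-level responses, reliability, missing-data mechanisms or
longitudinal structure. Whether temperament subscales enter as raw
counts or proportions is a linear rescaling and does not change
conclusions; raw counts are the default.
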