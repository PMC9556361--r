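# corrmediate

Causal mediation analysis with multiple correlated mediators, for
psychiatric-epidemiology settings where several symptom scales plausibly
transmit an exposure's effect but cannot be assumed independent.

The motivating design is an inpatient anorexia nervosa cohort: five
affective temperaments (TEMPS-A subscales) as exposures, state anxiety,
trait anxiety (STAI) and depressive symptoms (BDI) as mediators, the
EDI-2 drive-for-thinness (DT) and body-dissatisfaction (BD) subscales as
outcomes, adjusted for age and BMI. The mediators are correlated after
confounder adjustment but are assumed not to causally affect one another
— their association lives in the residual covariance Σ of the mediator
equations.

## The model

For exposure $A$, mediators $M_1..M_K$, outcome $Y$ and confounders $C$:

$$M_k = \beta_{k0} + \beta_{kA} A + \beta_{kC}'C + \varepsilon_k,
\qquad \varepsilon \sim MVN(0, \Sigma)$$
$$Y = \theta_0 + \theta_A A + \textstyle\sum_k \theta_{M_k} M_k + \theta_C'C + \eta$$

Effects are counterfactual contrasts per unit of exposure, on the outcome
scale. Under this linear no-interaction model they reduce to products of
coefficients — ACME$_k$ = $\theta_{M_k}\beta_{kA}$, ADE = $\theta_A$,
total = ADE + Σ$_k$ ACME$_k$ — and inference is quasi-Bayesian: J draws
of $(\theta, \beta)$ from their asymptotic sampling distributions,
percentile intervals and sign-based p-values (floor 2/J, reported
"< 2/J"). A direct counterfactual-simulation path is included and must
agree with the closed form; the package tests both routes against each
other. A 5 × 2 exposure-by-outcome battery applies two-tier Bonferroni
control: intermediate threshold 0.05/6 = 0.0083 per analysis, global
threshold 0.05/60 = 0.00083 over all 60 tests.

Because participant-level data of this kind are rarely shareable, the
package includes a synthetic cohort generator with the published
descriptive structure (age 23.7 ± 8.7, BMI 14.4 ± 1.8, 70.1%/29.9%
subtype split, instrument scale bounds) and fully known structural
coefficients, which drives the calibration machinery
(`run_calibration()`: bias, RMSE, interval coverage, rejection rates).

## Worked example

```r
library(corrmediate)

cohort <- generate_cohort(cohort_config(n = 184), seed = 7)
fit <- mediate_multi(cohort, exposure = "temps_anxious", outcome = "edi_dt",
                     J = 500, seed = 7)
fit
#> Multiple-mediator causal mediation model
#>   temps_anxious -> (stai_trait, stai_state, bdi) -> edi_dt, adjusted for age, bmi
#> Quasi-Bayesian mediation effects (closed_form, J = 500, n = 184, contrast 0 -> 1)
#>           effect estimate          95% CI       p
#>            total    0.387  [0.272, 0.504] < 0.004
#>  acme_stai_trait    0.015 [-0.014, 0.050]   0.312
#>  acme_stai_state    0.036  [0.001, 0.075]   0.052
#>         acme_bdi    0.021 [-0.007, 0.063]   0.148
#>       acme_joint    0.072  [0.014, 0.131]   0.016
#>              ade    0.315  [0.198, 0.423] < 0.004
```

Read: one additional anxious-temperament point raises drive for thinness
by 0.39 points in total, of which 0.07 is transmitted jointly through the
three mediators and 0.31 is direct; the total and direct effects are
resolved below the p-value floor 2/J = 0.004, while among individual
mediators none is individually significant at this cohort size. Per-draw
identities total = ade + acme_joint and acme_joint = Σ acme_k hold
exactly.

The full battery and its formatted table:

```r
res <- run_battery(cohort, J = 5000, seed = 7)   # 10 analyses, 60 rows
print(res)                                       # ^a/^b Bonferroni markers
write_results_csv(res, "results.csv")
```

A command-line wrapper over the same functions is in
`inst/cli/corrmediate` (subcommands `simulate`, `mediate`, `battery`,
`calibrate`, `summarize`; `--seed` is mandatory for anything stochastic).

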