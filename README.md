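# rpcohort: risk-period-cohort models

Age-period-cohort (APC) analysis decomposes a time-varying outcome into
effects of growing older (age), of calendar time (period), and of being
born around the same time (cohort). The classical formulation is
unidentified: because *age = period − cohort* holds exactly, the three
single measures form a perfectly collinear system and only two of the
three effects are estimable without extra constraints — the
"identification problem". Constrained regression, intrinsic estimators
and proxy-variable approaches all resolve it by assumptions that can
fail to recover the underlying effects.

`rpcohort` implements the **risk-period-cohort (RPC)** alternative for
epidemiologists, gerontologists and social scientists working with
subject-level panel or repeated cross-sectional data. Instead of
modelling chronological age directly, an *internal risk model* turns age
plus other risk factors into a multidimensional **age-related risk
index**, whose inherent heterogeneity breaks the linear dependency so
that period and cohort effects become estimable alongside an age-related
effect.

## The model

Stage 1 — internal risk model and index (for a baseline outcome
*Y⁰*, covariates **X**):

    Y⁰ᵢ = μ + β·Ageᵢ + αᵀXᵢ + εᵢ
    Riskᵢ = μ̂ + β̂·Ageᵢ + α̂ᵀXᵢ

(or, the *predicted-age* variant: regress age itself on **X** and use
the fitted age). The index is admissible for period-cohort modelling
when |cor(Age, Risk)| ≤ 0.85 (rounded to two decimals) — above that the
design approaches the collinear system the method avoids. A companion
diagnostic, the *proportionate chronological age effect*
β̂ / (β̂ + Σα̂ⱼ), measures how much of the risk model the age slope
accounts for; indices dominated by age (> 0.60) are the ones that fail
the correlation check.

Stage 2 — the RPC regression (fixed effects):

    Yᵢ = μ* + β*·Riskᵢ + Γ*·Cohortᵢ + Λ*·Periodᵢ + εᵢ

with cohort and period numeric or categorical, or the hierarchical
variant with crossed random intercepts for period *j* and cohort *k*
estimated by REML:

    Yᵢⱼₖ = αⱼₖ + β₁·Riskᵢ + εᵢⱼₖ,   αⱼₖ = η₀ + τ₀ⱼ + λ₀ₖ

Monte Carlo drivers evaluate the method over the full slope-parameter
grids (each slope in {0, 0.2, 0.4, 0.6, 0.8, 1}): `run_study1()` maps
how the age slope drives the age-risk correlation (216 patterns), and
`run_study2()` checks recovery of injected cohort effects and of the
null period effect (1296 patterns), flagging a pattern when the
absolute mean of Γ − Γ* or of Λ* across replications exceeds 0.01.
Recovery fails exactly in the pathological patterns where age is the
*only* risk factor (β > 0, α₁ = α₂ = 0) — the case the admissibility
diagnostic exists to catch.

## Worked example

A synthetic survey panel patterned after a repeated depression-screening
design: a right-skewed 0–27 questionnaire score over six two-year
periods (2006–2016), demographic covariates that moderately predict
age, and an injected cohort trend of 0.3 per decade on the
log(score + 1) scale.

```r
library(rpcohort)
d <- simulate_nhanes_like(27496, seed = 1)
m <- rpc(score ~ sex + comorbidities + race + income_ratio + social_support,
         data = d, index = "age", log_score = TRUE, cohort_origin = 1926)
m
#> Risk-period-cohort model: score (log(x+1) scale) on predicted chronological age + cohort + period
#> n = 27496, cor(age, risk) = 0.51
#>
#> RPC regression (n = 27496 )
#>                  Estimate    SE        p
#> (Intercept)         0.240 0.079  2.2e-03
#> risk                0.006 0.001  3.2e-15
#> .cohort1926-1930    0.071 0.073  3.3e-01
#> .cohort1931-1935    0.201 0.070  4.0e-03
#> ...
#> .cohort1991-1995    1.829 0.074 1.2e-133
#> .cohort1996-2000    1.958 0.104  1.5e-78
#> .period2008         0.131 0.017  3.2e-14
#> .period2010         0.126 0.017  2.4e-13
#> .period2012         0.054 0.017  1.8e-03
#> .period2014         0.067 0.017  1.1e-04
#> .period2016         0.075 0.018  2.4e-05
#> R-squared: 0.2124   adjusted: 0.2118
```

The age-risk correlation 0.51 is comfortably below the 0.85 threshold,
so all three effect families are estimable at once. The cohort
estimates rise monotonically across birth cohorts — the injected trend
(0.3 per decade × ~7.7 decades ≈ 2 at the youngest bin) is recovered —
and the period estimates sit near their injected values (e.g. 0.131 vs
0.11 for 2008). `run_demo()` runs this pipeline end to end against a
traditional APC fit and reports the variance inflation (APC standard
errors are about twice the RPC ones on the shared terms).

The correlation study in miniature:

```r
s1 <- run_study1(data.frame(beta = c(0.2, 1, 1), alpha1 = c(0, 0.2, 0.6),
                            alpha2 = c(0, 0.2, 0.6)),
                 reps = 200, n = 10000, base_seed = 1)
s1[, c("beta", "alpha1", "alpha2", "mean_corr", "mean_prop_effect",
       "flagged_high_corr")]
#>   beta alpha1 alpha2 mean_corr mean_prop_effect flagged_high_corr
#> 1  0.2    0.0    0.0     0.998            1.004              TRUE
#> 2  1.0    0.2    0.2     0.962            0.714              TRUE
#> 3  1.0    0.6    0.6     0.762            0.454             FALSE
```

A pure-age risk model (first row) is flagged — its index is just a
rescaled age. Adding real covariate signal (third row) drops the
correlation into the admissible range.

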