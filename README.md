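# apctrend

Bayesian age-period-cohort (APC) decomposition and 10-year projection of
mean blood pressure and body mass index in children and adolescents, with a
synthetic school-health-record generator for end-to-end testing.

## Who this is for

Epidemiologists and biostatisticians working with school-health surveillance
data: yearly examination records of outcomes such as systolic/diastolic
blood pressure (mmHg) or BMI (kg/m²), indexed by a child's whole-year age
and the examination year. Such registries are usually access-restricted, so
the package is built to be fully exercised on synthetic populations whose
age, period and cohort structure is known exactly.

## The model

Records are aggregated by sex into strata (age `a`, examination year `p`),
and each stratum mean is modelled as

```
y_ap ~ Normal(alpha_a + pi_p + gamma_(p-a), sigma^2 / w_ap)
```

with age effects `alpha` on the absolute outcome scale and period/cohort
effects `pi`, `gamma` as mean differences. An `A`-age, `P`-period design
induces `C = A + P - 1` birth cohorts via `c = p - a`; that exact linear
dependency makes the three linear trends non-identifiable, so the model uses
corner constraints (second and penultimate period and central cohort fixed
at zero, age unconstrained) and only second-order features — curvature,
inflection points — are interpreted. Each effect vector carries a
second-order random-walk (RW2) smoothing prior; posterior inference is by a
blocked Gibbs sampler (joint Gaussian draws of all effects, slice-sampled
`sigma` and RW2 innovation SDs), monitored by split-chain R-hat across 5
dispersed chains. Period and cohort effects are extrapolated 10 steps
through the RW2 predictive to project yearly means with 95% credible
intervals; DIC compares A/AP/AC/APC sub-models; curvature flags and MBIC
joinpoint regression locate trend changes. The methods vignette
(`vignettes/apc-trend-methods.Rmd`) documents every modelling choice.

## Worked example

Simulate a surveillance-scale population (10 ages × 16 periods, ~625
children per stratum) whose period effect reverses from falling to rising in
2005, then recover the structure:

```r
library(apctrend)

design <- build_design(9, 18, 1999, 2014)
truth  <- default_truth(design, "sbp", "male")
p <- design$periods
truth$period_curve[] <- 0.5 * abs(p - 2005) - mean(0.5 * abs(p - 2005))

records <- generate_population(truth, design, visits_per_child = 10,
                               n_children_per_birth_year = 4000, seed = 2024)
one <- select_one_record_per_child(records, seed = 2024)   # 100,000 records
tab <- aggregate_records(one, design)
head(tab, 3)
#>    sex age period cohort_index cohort_label   n      mean        sd
#> 1 male   9   1999         1990    1989-1990 422 100.22758  9.991892
#> 2 male   9   2000         1991    1990-1991 383 100.18899  9.395029
#> 3 male   9   2001         1992    1991-1992 404  99.56257 10.022835

fit <- fit_apc(tab, design, chains = 5, iterations = 1000, seed = 2024,
               weighting = "n")
fit
#> Bayesian APC fit (age+period+cohort model): 5 chains x 2000 iterations (burn-in 1000)
#> converged: TRUE (max R-hat 1.039)
head(summarize_draws(fit), 3)
#>    param effect level     mean    lower    upper     rhat
#> 1  age_9    age     9 100.4754 100.0967 100.8517 1.015847
#> 2 age_10    age    10 101.8465 101.5329 102.1610 1.011278
#> 3 age_11    age    11 103.3490 103.0662 103.6552 1.010819
```

(The sampler doubled its chains once to 2000 iterations to pass the R-hat
1.05 gate.) Age effects are estimated mean SBP at each age — about 100 mmHg
at age 9, rising with age. Project ten years ahead and average over ages:

```r
ext    <- extend_effects(fit, horizon = 10, seed = 2024)
series <- yearly_mean_series(fit, ext)
tail(series, 4)
#>    year     mean    lower    upper      type
#> 23 2021 112.7123 105.8808 120.6091 projected
#> 24 2022 113.2485 105.0020 122.6005 projected
#> 25 2023 113.7894 103.9484 124.7473 projected
#> 26 2024 114.3279 102.9076 126.9682 projected
```

The projected yearly means continue the post-2005 rise, and the credible
intervals widen with the horizon, as the RW2 predictive dictates. The trend
reversal is recovered by both changepoint tools:

```r
inflection_points(curvature(effect_draws(fit, "period")))
#>   position     mean      lower     upper direction
#> 1     2005 0.418688 0.04297431 0.8670087    upward

joinpoint_fit(series$year[series$type == "observed"],
              series$mean[series$type == "observed"])
#> Joinpoint fit: 2 joinpoint(s) at 2005, 2010
#>   segment slopes: -0.3903, 0.5269, 0.3791
#>   SSE: 0.0910845  MBIC: -66.0614
```

The period effect's curvature interval excludes zero exactly at 2005
(an upward inflection: falling before, rising after), and the joinpoint
search independently places its first breakpoint there.

The published childhood series are available for worked comparisons:
`shs_table1()` returns the observed yearly means by sex and age group; e.g.
the boys' ages-9–11 systolic series bottoms out at 101.9 mmHg in 2004 and
their BMI series peaks at 18.0 kg/m² in 2009.

A YAML-driven command line for the same pipeline lives at
`inst/cli/apctrend.R` (subcommands `simulate | tabulate | fit | project |
changepoints | report`).

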