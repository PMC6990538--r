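---
title: "Bayesian age-period-cohort decomposition and projection: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian age-period-cohort decomposition and projection: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apctrend)
```

## The problem

Mean blood pressure (BP) and body mass index (BMI) in school-aged children
drift over time for reasons that mix three confounded clocks: *age* (growth
and puberty), *period* (contemporaneous population-wide conditions in the
examination year) and *birth cohort* (exposures shared by children born in
the same years). `apctrend` decomposes yearly surveillance means into these
three additive effects, projects the series a decade ahead, and locates the
inflection points that are the scientifically interpretable features of such
a decomposition. Because school-health registries of this kind are typically
access-restricted, the package also ships a synthetic record generator with
known age-period-cohort (APC) structure, so the whole pipeline is testable
end to end against exact oracles.

## The model

Records are aggregated (separately by sex) to strata indexed by whole-year
age $a$ and examination year $p$; each stratum contributes its count $n_{ap}$
and mean outcome $y_{ap}$. The cell mean is modelled as

$$y_{ap} \sim \mathcal{N}\!\left(\alpha_a + \pi_p + \gamma_{p-a},\;
\sigma^2 / w_{ap}\right),$$

where $\alpha$ is the age effect on the absolute outcome scale (mmHg or
kg/m²), $\pi$ and $\gamma$ are period and cohort effects expressed as mean
differences, and $c = p - a$ indexes birth cohorts. A design with $A$ ages
and $P$ periods induces $C = A + P - 1$ cohorts. Because each cohort index
covers children born in two adjacent calendar years, cohorts are displayed
with two-year labels, `"1992-1993"` for $c = 1993$.

**Identification.** The exact relation $c = p - a$ makes the three linear
trends jointly unidentifiable: adding any straight line in $p$ to $\pi$ and
subtracting matching lines from $\alpha$ and $\gamma$ leaves every cell mean
unchanged. We adopt the corner-constraint convention of fixing the *second*
and *penultimate* period effects and the *central* cohort effect at zero,
with age unconstrained. The constrained design matrix then has full column
rank $A + (P-2) + (C-1)$, which `build_design_matrix()` verifies
numerically. Only *second-order* features of the fitted effects — changes of
slope, i.e. curvature — are invariant to the constraint choice, so those are
what the package flags and interprets; `curvature()` is exactly invariant to
added affine trends, and the test suite asserts both that invariance and
that refitting under a different valid constraint set reproduces the fitted
cell means up to Monte-Carlo error.

**Smoothing priors.** Each effect vector carries a second-order random-walk
(RW2) prior in the forward direction: the conditional expectation of each
element is the linear extrapolation of its two predecessors,
$\theta_j \mid \ldots \sim \mathcal{N}(2\theta_{j-1} - \theta_{j-2},
\tau^2)$, equivalently a Gaussian penalty on second differences with flat
priors on the first two elements. The innovation SDs $\tau_\alpha, \tau_\pi,
\tau_\gamma$ and the residual SD $\sigma$ get uniform$(0, U)$ priors with
$U = 100$ outcome units by default — effectively flat over any plausible
scale for mmHg or kg/m² data while keeping the posterior proper. The RW2
null space is the set of straight lines, so as $\tau \to 0$ an effect
collapses onto its best linear representation consistent with its zero
constraints (for the period block, whose constraint pins two points, that
limit is identically zero), and as $\tau \to \infty$ the fit approaches the
unpenalised least-squares solution.

## Computation

At fixed $(\sigma, \tau)$ the posterior over the constrained coefficients is
exactly Gaussian; `penalized_fit()` returns its mode in closed form (a
generalised ridge solution). The full posterior is explored by
`fit_apc()` with a blocked Gibbs sampler:

1. all free effect coefficients are drawn *jointly* from their Gaussian full
   conditional via a Cholesky factorisation of the precision matrix;
2. $\sigma$ and each $\tau$ are updated by univariate slice sampling
   (stepping-out with shrinkage) on their bounded supports.

This design was chosen over a generic HMC engine because the Gaussian full
conditional is exact — at fixed hyperparameters the draws are i.i.d. from
the true posterior, which turns the closed-form mode into a sharp
cross-check: the test suite requires the Gibbs posterior mean to agree with
`penalized_fit()` within three Monte-Carlo standard errors.

Five chains run by default from dispersed starts (the penalised mode plus
chain-indexed Gaussian jitter). The first half of every chain is discarded
as burn-in. Convergence is monitored by split-chain R-hat over all
monitored parameters with threshold 1.05; on failure the chain length is
doubled (twice at most, configurable) and a still-unconverged result is
returned *flagged*, with a warning — the pipeline driver refuses to proceed
unless explicitly told to. Parameters held constant by construction
(constrained zeros, fixed hyperparameters) are excluded from monitoring;
R-hat is defined as 1 for agreeing constant chains and $\infty$ for chains
stuck at different constants. Identical seeds reproduce draws bit for bit.

Model fit is compared by DIC, $\mathrm{DIC} = \bar{D} + p_D$ with
$p_D = \bar{D} - D(\bar\theta)$ evaluated at the posterior mean of all
parameters (the standard plug-in). Sub-models (`A`, `AP`, `AC`, `APC`) drop
whole effect blocks together with their constraints.

## Projection

`extend_effects()` pushes each posterior draw of $\pi$ and $\gamma$ forward
$H$ steps (default 10) through the RW2 predictive,
$\theta_{J+h} = 2\theta_{J+h-1} - \theta_{J+h-2} + \mathcal{N}(0, \tau^2)$,
using that draw's own $\tau$. With $\tau = 0$ this is the exact straight-line
continuation; with $\tau > 0$ the predictive variance grows with the step,
so credible intervals widen with the horizon (asserted in the tests).
Projected cell means are $\alpha_a + \pi_p + \gamma_{p-a}$ per draw — no
refitting on extended grids — and `yearly_mean_series()` collapses them to a
per-year series using equal age weights by default (a configurable weight
vector is accepted; the observed segment can show fitted or raw means — both
are provided because either is a defensible way to draw the observed curve).
A 10-year projection of a design with ages 9–18 needs cohorts up to
$(\max p + 10) - 9$, which is exactly the 10th cohort extension; requesting
more raises an error that states the required horizon.

## Changepoints

Two complementary tools locate trend changes. `inflection_points()` flags
interior positions whose curvature credible interval (default 95%) excludes
zero, optionally with a minimum-magnitude rule — a reproducible version of
what is usually done by eye on curvature plots. `joinpoint_fit()` fits
continuous piecewise-linear trends with breakpoints restricted to observed
years (at least two observations strictly on each side of any breakpoint),
by exhaustive search, selecting the number of joinpoints with a modified
BIC, $n\log(\mathrm{SSE}/n) + (2k+2)\log n$. The penalty form is a
documented, configurable choice: the criterion family is standard but its
exact published variants differ, and the permutation-test machinery of the
NCI software is intentionally out of scope. Ties break toward fewer
joinpoints, then earlier placements; zero-SSE fits are floored at $10^{-12}$
before the log so that exact piecewise-linear data remain well-defined and
the tie-break still applies.

## The synthetic generator

`generate_population()` emulates an annual school-health assessment: each
synthetic child is assigned a birth year, attends up to `visits_per_child`
consecutive yearly check-ups along its cohort diagonal (the follow-up window
is placed uniformly within the observable part of the diagonal), and
contributes outcome draws
$\alpha_a + \pi_p + \gamma_{p-a} + \mathcal{N}(0, \sigma)$. Downstream,
`select_one_record_per_child()` keeps one uniformly chosen visit per child —
the same device the surveillance analysis uses to remove within-child
correlation — and `aggregate_records()` forms the stratum table.

The default truth curves (`default_truth()`) qualitatively mimic the
observed series: an age curve rising through puberty with an upward
inflection near age 10 in boys and 9 in girls, a V-shaped period effect
with its minimum near 2005, and a cohort effect rising to the 1993 cohort
and falling after 1998, with residual SDs of 10 mmHg for blood pressure and
2.5 kg/m² for BMI — magnitudes a school-surveillance analyst would call
realistic. They are simulation defaults, not estimates. Repeat visits of
one child are conditionally independent given the cell mean: the registry
reports no within-child correlation structure, and the one-record-per-child
step removes the question from the analysed data anyway. The generator does
*not* emulate measurement-protocol artifacts (nurse re-checks, cuff sizes)
or year-to-year participation variation, so passing tests say nothing about
robustness to those features of real registry data.

## Problem sizes and numerical choices used in the checks

The replicate studies in the tests and in `scripts/acceptance.R` use sizes
chosen to make each check sharp at desk scale:

* *Sampler-vs-oracle* and *coverage*: a 5-age × 6-period design with 200
  children per cell and individual SD 5 — coverage of the 95% intervals for
  the true cell means is evaluated over 200 replicates (2 chains × 500
  iterations each; the joint Gaussian effect update makes short chains
  adequate here).
* *DIC selection*: run at the full surveillance scale of 10 ages × 16
  periods (160 strata). At the toy scale the A-only vs APC contrast is
  genuinely marginal — the expected DIC margin grows roughly like the number
  of extra effective parameters while its spread grows like its square
  root, so small designs under-separate the models regardless of
  implementation. 160 strata is also the stratum count the decomposition is
  designed for.
* *Joinpoint*: exact-recovery on a 17-point noiseless V; false-positive
  behaviour on 50 pure-noise series of 16 points.

Degenerate inputs are handled explicitly rather than silently: truth curves
missing a grid point name the point; empty aggregations, rank-deficient
design matrices, uncovered projection cohorts and too-short joinpoint
series all raise targeted errors; `tau` slice updates are floored at
$10^{-6}$ to keep penalty matrices finite.

## Known limitations

* The decomposition is descriptive; nothing here supports causal claims
  about why a trend bends.
* First-order trends of the individual effects are not identified and are
  deliberately never interpreted or reported as such.
* Projections assume the RW2 predictive — futures that continue recent
  second-order behaviour. Policy shocks or abrupt environmental change are
  outside the model.
* The MBIC joinpoint selector is a simplified stand-alone criterion;
  its selected model can differ from permutation-test-based software on
  noisy series.
* With uniform hyperpriors and weak curvature information (very short
  effect vectors), $\tau$ posteriors are diffuse and R-hat may demand the
  doubling fallback; the flagged-result path is the intended behaviour, not
  an error state.
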