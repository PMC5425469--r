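---
title: "Modelling weather-driven 'dead' condemnations in slaughter swine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weather-driven 'dead' condemnations in slaughter swine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinecondemn)
```

## The problem

Pigs that die in transit to slaughter or in lairage pens before ante-mortem
inspection are recorded as "dead" condemnations. These deaths are an animal
welfare concern, a potential disease signal for surveillance analysts, and a
direct revenue loss: a condemned animal yields no sale. Ambient heat — and,
less intuitively, cold — is a major driver, and its effect differs by swine
class: market hogs (finished pigs, 220–260 lbs), roasters (small pigs under
220 lbs), and cull sows (breeding females over 400 lbs, with high metabolic
heat production and long journeys to the few plants that process sows).

`swinecondemn` implements the full analysis chain from raw surveillance-style
inputs to risk tables and a priced counterfactual loss account:

1. **geoweather** — link each plant to its closest 1–3 weather stations
   within 100 statute miles (haversine distance on a fixed-radius sphere,
   3,958.8 mi) and pool daily observations, unweighted, into plant-week
   means. Plants with no station in range are dropped and counted.
2. **heat exposure** — compute the weekly heat index (HI) from weekly mean
   temperature and relative humidity, and assign each plant-week to one
   exposure category.
3. **zinb_glmm** — fit zero-inflated negative binomial mixed models of the
   weekly condemned count.
4. **risk metrics** — condemnation rate (CR), expected incidence per 10,000
   (EIR), attributable risk (AR), risk ratio (RR) with Wald intervals, and
   the dead loss ratio (DLR).
5. **revenue** — predict each extreme-temperature week's counterfactual
   condemnations from a baseline-weeks model, attribute the signed residual
   to temperature, and price it with monthly carcass price series.
6. **synthetic data** — generate all four input streams with known ground
   truth so that every stage is testable end to end without restricted
   surveillance extracts.

## Exposure construction

The heat index is the NWS Rothfusz regression — a nine-coefficient
polynomial in temperature and relative humidity — plus the two standard NWS
adjustments (a low-humidity subtraction for RH < 13% at 80–112 °F, a
high-humidity addition for RH > 85% at 80–87 °F). It is an *apparent*
temperature and is defined only at 80 °F and above; the pipeline computes it
from the weekly averaged temperature and humidity (not as an average of
daily indices).

Each plant-week lands in exactly one bin, compared on integer-rounded °F
(the bins are integer-labelled, so 84.4 °F is moderate and 84.6 °F is hot):

| axis | category | bounds (°F) |
|---|---|---|
| HI | moderate / hot / very hot | 80–84 / 85–92 / 93–106 |
| weekly-mean daily minimum | cool / cold / very cold | 40–50 / 10–39 / −17–9 |
| baseline | minimum > 50 and average 54–79 | |

The cold axis takes priority: any week whose rounded mean minimum is 50 °F
or below is a cold-axis week regardless of its average. Weeks that fit no
bin are excluded with a logged reason — average 51–53 °F with a warm
minimum (the gap between the cold axis and the baseline definition), an HI
under 80 at very low humidity, an HI above 106 or a minimum below −17
(outside the range the categories were calibrated on). The baseline's lower
bound is 54 °F on the weekly average; an alternative published variant uses
50 °F, and the bound table (`EXPOSURE_BOUNDS`) can be edited for sensitivity
analysis.

The category bounds themselves are fixed, but `fit_offset_spline()` and
`suggest_breakpoints()` reproduce the exploratory step that motivates them:
a cubic smoothing spline of the per-head rate with head-count weights (the
offset-as-weight reading of a log-total offset — high-volume plants carry
proportionally more information), smoothing chosen by generalized
cross-validation, and advisory cutpoints at the largest-curvature positions
of the fitted curve. GCV occasionally undersmooths flat rate curves by a few
percent; the fitted grid spans the 1st–99th percentile of the predictor
because the sparse tails cannot support a stable rate estimate.

## The count model

Weekly condemned counts are overdispersed and about half the plant-weeks
record no condemnations at all, so the model is a zero-inflated negative
binomial with a random intercept:

$$
y_{ig} \sim \pi\,\delta_0 + (1-\pi)\,\mathrm{NB}\!\left(\mu_{ig},\theta\right),
\qquad
\log \mu_{ig} = x_{ig}'\beta + \log N_{ig} + u_g,
\qquad u_g \sim \mathcal N(0, \sigma_u^2),
$$

with NB2 variance $\mu + \mu^2/\theta$, $N$ the head slaughtered (offset, so
$\beta$ is on the per-head rate scale), and $u_g$ a random intercept on the
five-level processing-volume category (VS to VL, 30 to >15,000 head/week) —
plants of different scale differ in facilities and handling. The zero part
is intercept-only: nothing in the data motivates covariate-dependent
structural zeros, and this matches the convention of the mixed-model
packages this model family comes from. The random intercept enters the
count part only.

The fixed design is *nested*: one indicator per class (each class's own
baseline) plus one per class × non-baseline category. Two consequences:
every class has its own reference cell, and the log risk ratio against the
class baseline **is** a single coefficient, so its delta-method Wald SE is
read directly off the coefficient covariance.

### Estimation

The marginal likelihood integrates $u_g$ out per group with **adaptive
Gauss–Hermite quadrature**: the integrand's mode is located by a damped
Newton search (warm-started across likelihood evaluations), the rule is
centred there and scaled by the curvature, and `quad_points = 1` gives the
Laplace approximation. The likelihood kernel is compiled (Rcpp); the outer
optimizer is BFGS on the transformed scale ($\beta$, $\log\theta$,
$\mathrm{logit}\,\pi$, $\log\sigma_u$) with finite-difference gradients,
started from a Poisson fit with method-of-moments dispersion, with three
deterministic restarts on non-convergence. Standard errors come from the
inverted finite-difference Hessian at the optimum; a fit that fails to
converge or produce a positive-definite covariance is flagged, never
silently returned.

Numerical choices that matter:

* 15 quadrature nodes by default; the shipped pipeline configurations use 7,
  which the quadrature self-consistency test shows changes the
  log-likelihood by well under $10^{-4}$ per observation relative to 31
  nodes on recovery-scale data.
* $\sigma_u < 10^{-8}$ collapses the integral to $u = 0$ (the degenerate
  submodel), which is also how the plain-NB equivalence oracle is reached.
* With only five groups, $\sigma_u$ itself is weakly identified and one
  realized draw of the five $u_g$ shifts all population-level rates by
  roughly $\exp(\bar u)$ — contrasts (risk ratios) are immune, which is why
  recovery and coverage checks focus on them.

### Derived metrics

`predict_rate()` returns the population-level per-head rate
$\mathrm{CR} = (1-\hat\pi)\exp(x'\hat\beta)$ — the random effect is set to
zero and the offset removed. Calling this a "probability condemned" uses the
Poisson-thinning approximation, excellent at rates of a few per thousand.
EIR is $\mathrm{round}(10^4\,\mathrm{CR})$ (half away from zero, guarded
against binary representation error); AR is the signed risk difference
against the class baseline; RR the ratio with
$\exp(\log RR \pm 1.96\,\mathrm{SE})$ Wald intervals. Interval method is a
design choice — a profile-likelihood interval would also be defensible; only
coverage properties, not specific interval endpoints, are asserted in tests.

## Counterfactual revenue attribution

Baseline weeks (minimum > 50, average 54–79 °F) are assumed free of
temperature-driven mortality. A second model — swine class only, same
offset and random intercept — is fitted to them and used to predict each
extreme week's expected count, *including* the estimated random-effect mode
of the record's volume category (these are predictions for the same plants,
not for a hypothetical population; a configuration flag switches to
population-level prediction, and which variant the original analysis used
is not documented). The signed residual `observed − expected` is the excess
attributed to temperature: category sums are **not** floored at zero, and
negative category totals are reported as such (cull sows in cool weeks sit
*below* their baseline counterfactual).

Excess counts are priced by the ISO week's majority month (the month of the
week's Thursday): market hogs and cull sows at the class's monthly price
per head, roasters — absent from price reports — at
$(70\,\mathrm{lbs}/100) \times$ the market dressed price per hundredweight,
70 lbs being the median roaster carcass. Foregone revenue is a gross, not
net, figure, and deliberately ignores the price response to supply changes.

## What the generator emulates — and what it does not

`generator_config()` defaults are the study conditions: 150 plants over six
calendar years; a volume-category mix matching the published share of
plant-weeks per category (VS 22%, S 38%, M 10%, L 10%, VL 20%) with weekly
head drawn per category range; class mixes in which the largest plants are
market-only and roasters come almost entirely from the smallest plants;
per-head condemnation rates set to the published class × category estimates
(so the default regime reproduces the published qualitative pattern: cull
sows most heat-sensitive, roasters cold-sensitive and heat-insensitive);
$\theta = 1.5$, $\pi = 0.45$, $\sigma_u = 0.3$. The count-part mean is
$N\cdot\mathrm{CR}/(1-\pi)\cdot e^{u_g}$ so that the marginal per-head rate
at $u = 0$ equals the stated CR — the quantity `predict_rate()` estimates.

Weather is a per-station seasonal sinusoid driven by latitude (annual mean
72 − 1.8·(lat − 30) °F, amplitude 16 + 0.5·(lat − 30), peak around 18
July), with daily noise, a temperature-dependent humidity model, and a
drawn daily minimum spread — calibrated so that all seven exposure
categories occur at realistic frequencies across a 30–47° latitude band.
Stations are jittered 5–90 mi around their plant; a configurable fraction
of plants is placed on a remote grid with stations 150–400 mi away to
exercise the weather-linkage exclusion path deterministically. Prices are
seasonal with a summer peak for market hogs and an early-autumn peak for
cull sows.

Category assignment flows through the *real* linkage and exposure modules —
there is no shortcut labelling — so a category-assignment bug breaks
parameter recovery visibly.

Deliberate non-realism, and hence what passing tests do not show: no real
geography or station network, no spatial or temporal autocorrelation in
weather beyond the seasonal cycle, no within-class covariates (journey
length, trailer type, stocking density), no disease outbreaks, and no price
feedback. Recovery tests demonstrate that the estimation machinery inverts
the generating process; they cannot validate the causal reading of the
model on real surveillance data. Note also that with $\pi = 0.45$ the
*total* zero share of generated plant-weeks runs somewhat above one half,
since small-plant sampling zeros add to the structural ones.

## Problem sizes used in the shipped checks

Unit and property tests run on direct simulations of 500–12,000 plant-weeks;
Wald coverage is estimated from 100 replicates at n = 2,000; end-to-end
recovery uses 50 scaled-down replicates (25 plants × 1 year) through the
full weather chain, asserting that at least 90% of (replicate, cell) pairs
cover the generating risk ratio; the smoke run uses the full default scale
(150 plants × 6 years, ≈85,000 records). `scripts/acceptance.R` re-runs the
default-scale pipeline from scratch and emits both the published
worked-example reproductions and the synthetic-run estimates as JSON.

## Known limitations

* Wald intervals with five random-effect groups undercover slightly for the
  class-baseline coefficients at small n (a well-known small-G phenomenon);
  ratio contrasts are calibrated.
* A class × category cell with no condemnations at all has no finite rate
  estimate; such zero-event strata (possible in very small runs) are
  dropped from the fit with a warning and listed in the fit object.
* The exposure scheme inherits the published calibration range; weeks
  beyond it (HI > 106 °F, minimum < −17 °F) are excluded, not extrapolated.
* DLR and the revenue ledger are computed on linked records only; the
  excluded-plant share is reported in the run manifest so the loss is
  visible.
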