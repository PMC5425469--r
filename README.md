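# swinecondemn

Weather-driven "dead" condemnation risk and foregone revenue in slaughter
swine.

Pigs that die in transit or in lairage before inspection ("dead"
condemnations) are an animal-welfare problem, a possible disease signal,
and a direct revenue loss. `swinecondemn` is an R implementation of the
full surveillance analysis chain that quantifies how ambient heat and cold
drive these deaths across three swine classes (market hogs, roasters, cull
sows), and what the deaths cost:

* **Weather linkage** — each slaughter plant is matched to its closest 1–3
  weather stations within 100 statute miles (haversine distance, fixed
  Earth radius 3,958.8 mi) and daily observations are pooled into
  plant-week means.
* **Exposure** — warm weeks are scored with the NWS Rothfusz heat index
  (HI, defined at 80 °F and above, with both standard humidity
  adjustments) and binned *moderate* (80–84 °F), *hot* (85–92), *very hot*
  (93–106); cold weeks are binned on the weekly mean daily minimum:
  *cool* (40–50), *cold* (10–39), *very cold* (−17–9). The reference is
  mild weeks (minimum > 50, average 54–79 °F).
* **Count model** — a zero-inflated negative binomial mixed model of weekly
  condemned counts:
  log μ = x'β + log N + u_g, y ~ π·δ₀ + (1−π)·NB(μ, θ),
  with a log-head offset (so β is per head), exposure categories nested
  within swine class, and a random intercept u_g on the five-level
  processing-volume category. The marginal likelihood is maximized
  directly, integrating u by adaptive Gauss–Hermite quadrature (compiled
  kernel; Laplace at one node).
* **Risk metrics** — condemnation rate CR = (1−π̂)·exp(x'β̂), expected
  incidence EIR = round(10⁴·CR), attributable risk AR = CR − CR_baseline,
  risk ratio RR = CR / CR_baseline with Wald 95% intervals, and the dead
  loss ratio DLR = condemned/total × 100.
* **Revenue attribution** — a baseline-weeks counterfactual model (class
  only) predicts what each extreme week would have condemned anyway; the
  signed residual is attributed to temperature and priced with monthly
  carcass price series (roasters at 70 lbs/100 × the market dressed price
  per cwt).
* **Synthetic data** — a generator that emulates all four input streams
  (slaughter records, stations, daily weather, prices) with known ground
  truth, so the whole pipeline is testable without restricted surveillance
  extracts.

## Worked example

```r
library(swinecondemn)

# published class x category condemnation rates ship with the package;
# the derived columns are recomputed, not copied
tab <- risk_table_from_cr(
  subset(cr_reference(), axis %in% c("baseline", "hi"),
         select = c(class, category, cr)))
subset(tab, class == "market")
#> # A tibble: 4 × 6
#>   class  category      cr   eir      ar    rr
#>   <chr>  <chr>      <dbl> <dbl>   <dbl> <dbl>
#> 1 market baseline  0.003     30 NA       1
#> 2 market moderate  0.0038    38  0.0008  1.27
#> 3 market hot       0.0041    41  0.0011  1.37
#> 4 market very_hot  0.0035    35  0.0005  1.17
```

Market hogs in hot heat-index weeks (85–92 °F) die at 1.37 times the
baseline rate — 41 head per 10,000 slaughtered instead of 30.

An end-to-end run on synthetic data with known truth:

```r
res <- run_pipeline(list(
  synthetic = list(seed = 7, n_plants = 40, years = 2),
  out_dir = "run_out", quad_points = 7))

res$risk$hi      # fitted CR/AR/EIR/RR per class x HI category
res$revenue      # excess condemnations and foregone USD per category
```

The output directory receives six table files (monthly DLR, risk and RR
tables on both exposure axes, the revenue summary), three figure-data files
(weekly DLR vs foregone revenue per class), two model reports (JSON + text)
per fit, and a JSON manifest that accounts for every input record as
modelled, baseline, or excluded (no weather within 100 mi / out of
calibration range / invalid).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/swinecondemn.R", package="swinecondemn"))')" \
  run --synthetic --seed 7 --out run_out
```

## Scope notes

The package models temperature and humidity only: journey length, trailer
type, stocking density, and other transport covariates are not in the data
it targets. Foregone revenue is gross (no price-equilibrium feedback). Map
rendering and live weather/price retrieval are out of scope.
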