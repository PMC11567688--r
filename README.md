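# mmtrend

Temporal trends in the minimum mortality temperature (MMT) and its
percentile (MMTP) from multi-community daily mortality and temperature
time series.

The MMT is the daily mean temperature at which the temperature–mortality
association, cumulated over a window of lag days, is lowest; the MMTP is
the same optimum expressed as a percentile of the local temperature
distribution. Whether these optima have drifted upward with a warming
climate — a signature of adaptation — is a question for environmental
epidemiologists working with multi-site daily time-series archives.
`mmtrend` provides the full two-stage machinery to answer it, plus a
synthetic-data generator with known ground truth for validation.

## The method

**Stage 1 — per community × 5-year subperiod.** A quasi-Poisson regression

```
log λ_t = α₀ + s(x_t, …, x_{t−L}; β) + seasonal spline (8 df/year) + day-of-week
```

where `s(·)` is a DLNM cross-basis: natural cubic spline in temperature
(knots at the 10th/75th/90th percentiles, `v_x = 4`) × natural cubic spline
in lag (intercept + 3 log-spaced knots over 0..21 days, `v_l = 5`), giving
20 coefficients. These are reduced over lags with
`θ = (I ⊗ 1'C) β`, and the MMT is the argmin of `Σ_k θ_k f_k(x)` over the
25th–99th percentile window (0.1 °C grid), with a Monte-Carlo standard
error from 1000 draws `θ⁽ʲ⁾ ~ N(θ̂, V(θ̂))`.

**Stage 2 — pooling.** A two-level mixed-effects meta-regression with known
sampling variances,

```
MMT̂_ijw = (α + a_ij + c_i) + (β + b_ij + d_i)·time_w + ε_ijw,
(a,b)' ~ N(0, Ψ⁽²⁾),  (c,d)' ~ N(0, Ψ⁽¹⁾),  ε_ijw ~ N(0, sd²_ijw)
```

fitted by profiled REML/ML over log-Cholesky factors of the Ψ matrices.
The linear slope `β` (per 5-year subperiod) is the headline trend. BLUPs,
stratified fits (climate zone / region / country), likelihood-ratio model
comparisons and average-temperature adjustment are built in.

## Worked example

Generate a 10-country × 3-community synthetic archive (30 years of daily
data) whose true MMT warms by 0.5 °C per subperiod, run both stages, and
pool the trend:

```r
library(mmtrend)

spec <- truth_spec(n_countries = 10, communities_per_country = 3, years = 30,
                   mmt0 = 20, mmt_slope = 0.5,
                   country_int_sd = 0.5, community_int_sd = 0.5,
                   country_slope_sd = 0.1, community_slope_sd = 0.1, seed = 2)
sim     <- simulate_dataset(spec)
records <- run_first_stage(sim$data, n_sim = 300, seed = 3)

dplyr::select(head(records, 4), community_id, w, metric, estimate, sd, AT)
#> # A tibble: 4 × 6
#>   community_id     w metric estimate    sd    AT
#>   <chr>        <int> <chr>     <dbl> <dbl> <dbl>
#> 1 c01_01           1 MMT        21.6  3.50  21.1
#> 2 c01_01           1 MMTP       52.6 16.1   21.1
#> 3 c01_01           2 MMT        21.0  2.66  21.2
#> 4 c01_01           2 MMTP       49.7 11.6   21.2

mmt <- dplyr::filter(records, metric == "MMT", converged)
fit <- fit_memr(mmt, method = "REML")
pooled_trajectory(fit)
#> Pooled trajectory: 20.22 (19.43, 21.01) at w=1 -> 22.76 (21.52, 23.99) at w=6
#> Linear slope (per subperiod): 0.507 (se 0.176, P = 0.00387)
```

The pooled slope recovers the 0.5 °C/subperiod truth within one standard
error; the pooled MMT rises from 20.2 °C in the first subperiod to 22.8 °C
in the last. Each row of `records` carries the estimate, its Monte-Carlo
standard error, the subperiod average temperature `AT` and its community
time-average `TAT`, ready for `heterogeneity_suite()`, `at_adjustment()`
and `stratified_trajectories()`. `tidy()`/`glance()` methods and
`autoplot()` for curves, Monte-Carlo samples and trajectories round out the
interface, and `run_pipeline()` drives the whole analysis (synthetic or
CSV input) from one YAML/list configuration.

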