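---
title: "Estimating temporal trends in the minimum mortality temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temporal trends in the minimum mortality temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The minimum mortality temperature (MMT) is the daily mean temperature at
which the temperature–mortality association, cumulated over a window of lag
days, attains its minimum. Its percentile under the local temperature
distribution (MMTP) expresses the same optimum relative to the climate a
population actually experiences. Both are indicators of population
susceptibility to non-optimal temperatures, and whether they track a warming
climate — adaptation — or stay put is an empirical question that requires
comparing estimates across communities, countries and decades.

`mmtrend` implements a two-stage design for that comparison:

1. **First stage.** For each community and each 5-year calendar subperiod,
   a quasi-Poisson regression of daily all-cause death counts on a
   distributed lag non-linear model (DLNM) cross-basis in daily mean
   temperature, with a seasonality/trend spline and day-of-week indicators
   as controls. The cross-basis coefficients are reduced to the
   lag-cumulative exposure–response curve, whose argmin over a restricted
   percentile window is the MMT; its standard error comes from Monte-Carlo
   sampling of the reduced coefficients.
2. **Second stage.** The per-(community, subperiod) estimates, with their
   known sampling variances, are pooled by a two-level mixed-effects
   meta-regression (MEMR) with random intercepts and slopes for country and
   for community nested in country. The fixed-effect coefficient of the
   integer subperiod index — the linear slope (LS) — is the trend of
   interest. Stratified fits, likelihood-ratio comparisons and
   average-temperature adjustment probe where the trend is heterogeneous
   and whether warming itself accounts for it.

## First-stage model

For day $t$ in one community-subperiod, with death count $y_t$ and
temperature history $x_t, x_{t-1}, \dots, x_{t-L}$:

$$
\log \lambda_t = \alpha_0 + s(\mathbf{x}_t;\boldsymbol\beta)
  + \text{seasonal spline}(t) + \text{day-of-week}_t ,
\qquad \operatorname{var}(y_t) = \phi\,\lambda_t .
$$

$s(\cdot)$ is the DLNM bilinear expansion
$\sum_{j,k} \big[\sum_{l=0}^{L} f_j(x_{t-l})\,g_k(l)\big]\beta_{jk}$ with

* temperature basis $f_1,\dots,f_{v_x}$: natural cubic spline, internal
  knots at the 10th/75th/90th percentiles of the subperiod's temperatures,
  boundary knots at its observed range ($v_x = 4$);
* lag basis $g_1,\dots,g_{v_l}$: natural cubic spline over lags $0..L$ with
  an explicit intercept column and 3 internal knots equally spaced on the
  log-lag scale, $\exp(i \log L/4)$ ($v_l = 5$); $L = 21$ days;
* controls: a natural cubic spline of time with 8 degrees of freedom per
  year (rounded over the subperiod's length in days), plus six day-of-week
  indicators with Monday as reference.

Coefficients are Poisson maximum likelihood (IRLS); the covariance is
inflated by the Pearson dispersion $\hat\phi = \chi^2_P/(n-p)$. The 20
cross-basis coefficients are reduced over lags with
$M_1 = I_{v_x} \otimes \mathbf{1}' C$ (where $C$ is the $(L{+}1)\times v_l$
lag basis matrix), giving $\hat{\boldsymbol\theta} = M_1\hat{\boldsymbol\beta}$
and $V(\hat{\boldsymbol\theta}) = M_1 V(\hat{\boldsymbol\beta}) M_1'$.

The MMT point estimate is the argmin of
$\sum_k \hat\theta_k f_k(x)$ on a 0.1 °C grid covering the 25th–99th
percentile window of the subperiod's temperatures (a 1st–99th window is the
standard sensitivity variant). Ties go to the lowest temperature. The
standard error is the sample standard deviation of 1000 argmins recomputed
from draws $\boldsymbol\theta^{(j)} \sim N(\hat{\boldsymbol\theta},
V(\hat{\boldsymbol\theta}))$; MMTP applies the empirical CDF
(weak inequality, ties counted fully) to the MMT.

## Second-stage model

With $\widehat{\text{MMT}}_{ijw}$ and known $sd_{ijw}$ for country $i$,
community $j$, subperiod $w$ (`time` = 1..6):

$$
\widehat{\text{MMT}}_{ijw} = (\alpha + a_{ij} + c_i)
 + (\beta + b_{ij} + d_i)\,time_w + \epsilon_{ijw},
$$
$$
(a_{ij},b_{ij})' \sim N(0,\Psi^{(2)}),\quad
(c_i,d_i)' \sim N(0,\Psi^{(1)}),\quad
\epsilon_{ijw} \sim N(0, sd_{ijw}^2).
$$

`fit_memr()` maximizes the likelihood over the log-Cholesky factors of
$\Psi^{(1)}, \Psi^{(2)}$ with the fixed effects profiled out by generalized
least squares, exploiting the block-diagonal structure by country. BLUPs
are the standard conditional means
$\Psi Z' V^{-1}(y - X\hat\beta)$; a community's predicted slope is the
fixed slope plus its country and community BLUPs. MMT and MMTP are always
pooled in separate runs, and stratified results (climate zone, region,
country) refit the same model on the stratum's records only.

Average-temperature adjustment adds the subperiod mean temperature
$AT_{ijw}$, either raw or centered ($AT_{ijw} - TAT_{ij}$, the community's
time-averaged value); both variants are fitted and reported side by side,
since they answer slightly different questions (between- plus
within-community versus purely within-community warming). MMTP trends are
reported in percentile points per subperiod; MMT trends in °C per
subperiod (5 years).

## Estimation flavors and model comparison

* REML is used for reported fits and for comparing random-effect
  structures at identical fixed effects; ML refits are used whenever the
  fixed part changes (zone/region × time interactions, AT adjustment),
  since REML likelihoods are not comparable across fixed designs.
* Likelihood-ratio statistics are referred to a chi-square with degrees of
  freedom equal to the difference in parameter counts. For variance
  components on the boundary this naive reference is conservative; no
  50:50 mixture correction is applied.
* AIC $= -2\ell + 2p$ and BIC $= -2\ell + p\log(\text{\#records})$ count
  $p$ as fixed effects plus variance parameters under both flavors.
  (Some implementations add the constant $\tfrac12\log|X'X|$ to the REML
  log-likelihood; this cancels in every comparison made here.)

## Numerical choices

* Quantiles (temperature knots, search windows) use linear interpolation
  between order statistics (`stats::quantile` type 7). Knot placement moves
  the MMT slightly, so the convention is fixed and documented.
* The intercept-carrying lag basis keeps an explicit column of ones; the
  span equals the usual intercept-augmented natural-spline basis.
* Rows in the first $L$ days of a subperiod, or with any missing lagged
  temperature, are excluded from the fit; subperiods are treated as
  independent series (no lag carry-over across boundaries).
* $V(\hat{\boldsymbol\theta})$ is projected to the nearest symmetric PSD
  matrix (eigenvalue clipping at zero) before Monte-Carlo sampling —
  near-singularity occurs in short subperiods.
* Usability filter: a community × subperiod is skipped (with an explicit
  non-converged record, never a silent drop) if it has fewer than 730 days,
  fewer than 500 total deaths, or a failed/rank-deficient fit. Multi-site
  daily mortality archives always lose some units to such exclusions; the
  thresholds are package policy and configurable.
* MEMR optimization: Nelder–Mead on 1–6 log-Cholesky parameters from a
  small grid of starting scales, relative tolerance 1e-8 on the objective;
  fixed effects are never part of the search space.
* All randomness flows from one root seed through a deterministic per-unit
  derivation, so identical configurations reproduce byte-identical output.

## The synthetic-data generator

The study's multi-country daily mortality archive is not public, so the
generator produces data with the statistical structure the two-stage
analysis assumes, plus the ground truth needed to test it:

* **Temperature**: community mean (population mean 18 °C, between-community
  sd 3) + annual sinusoid (amplitude 8 °C, peak mid-July) + linear warming
  (0.3 °C/decade) + stationary AR(1) noise (sd 2 °C, lag-1 correlation 0.6).
* **Mortality**: negative-binomial daily counts (baseline 30 deaths/day,
  overdispersion 1.3 — variance/mean), log-rate adding mild seasonality
  (amplitude 0.1, peak mid-January), small day-of-week effects, and a
  U-shaped term $\sum_l w(l)\,\kappa\,(x_{t-l} - \text{MMT}^*_w)^2$ with
  lag weights decaying exponentially (half-life 3 days over lags 0..21,
  normalized) and cumulative curvature $\kappa = 0.004$ per °C²
  (≈ 50% excess risk 10 °C from the optimum).
* **Truth**: the true MMT is a step function, constant within each 5-year
  subperiod, moving by a fixed slope per subperiod plus country- and
  community-level random intercepts/slopes (the true $\Psi$ diagonals);
  per-unit true MMT, MMTP and average temperature are tabulated alongside
  the daily data.

The generator intentionally omits demography, holidays, influenza
epidemics and heat-wave clustering, and its counts are conditionally
independent given the rate. Passing tests therefore demonstrate that the
pipeline recovers the structure it models — not that real mortality data
satisfy that structure.

One property worth knowing: a sinusoid-plus-noise temperature model has
relatively few days near mid-range temperatures, so the argmin of a
shallow exposure–response is genuinely hard to pin down in a single 5-year
subperiod (Monte-Carlo sds near 2 °C at the defaults). The package's
recovery tests consequently check the *median* across many communities
(bias), and the calibration of the Monte-Carlo standard errors against
empirical scatter, rather than per-unit accuracy.

## Problem sizes used by the test suite

Simulation-based checks are scaled to desk hardware: MMT recovery uses 50
communities × 6 subperiods of 5 years each (~1826 days per fit); the
end-to-end trend-recovery study uses 20 replicates of 10 countries × 5
communities with true slope 0.5 °C/subperiod and Monte-Carlo size 300; the
type-I-error study of the region × time interaction uses 200 replicates of
subperiod records simulated directly from the pooling model (6 countries ×
3 communities, community-level random effects), as do the
average-temperature confounding scenarios. These sizes are the package's
own validation design; all are reproducible from fixed seeds.

## Known limitations

* The exposure is daily mean temperature only; humidity, cause-specific and
  age/sex-stratified mortality are out of scope.
* The trend model is linear in the subperiod index; with six subperiods a
  nonlinear temporal structure is deliberately not modeled.
* The boundary-naive chi-square reference makes random-slope tests
  conservative.
* When the search window's ends attract the argmin (monotone curves), the
  MMT sits at a window edge and its Monte-Carlo distribution piles up
  there; the `converged` flag does not distinguish this — inspect
  `samples` via `autoplot()` when it matters.
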