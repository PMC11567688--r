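#' Ground-truth specification for the synthetic multi-country dataset
#'
#' Collects every parameter of the generator: the study layout, the daily
#' temperature model (seasonal sinusoid + warming trend + AR(1) noise), the
#' mortality model (overdispersed counts whose log-rate adds seasonality,
#' day-of-week effects and a U-shaped lag-distributed temperature term with
#' a known, subperiod-varying vertex), and the between-community /
#' between-country heterogeneity of the true MMT level and trend.
#'
#' Defaults describe a plausible mid-latitude study population: 30-year
#' series starting 1986; community mean temperatures around 18 degrees C
#' (between-community sd 3), seasonal amplitude 8, warming 0.3 degrees C
#' per decade, AR(1) day-to-day noise (sd 2, rho 0.6); a baseline of 30
#' deaths/day with mild seasonality (0.1 on the log scale), small
#' day-of-week effects and overdispersion 1.3; a true MMT of 20 degrees C in
#' the first subperiod, cumulative log-rate curvature 0.004 per squared
#' degree, and an exponential lag decay with a 3-day half-life over lags
#' 0..21.
#'
#' @param n_countries,communities_per_country Study layout.
#' @param years,start_year Series length and first calendar year.
#' @param temp_mean,temp_offset_sd Population mean temperature and sd of
#'   community offsets (degrees C).
#' @param amplitude Seasonal amplitude (degrees C).
#' @param warming Warming trend, degrees C per decade.
#' @param ar_sd,ar_rho Stationary sd and lag-1 autocorrelation of the AR(1)
#'   temperature noise.
#' @param baseline Expected deaths/day at the MMT, mid-season, Monday.
#' @param seasonal_amplitude Log-scale amplitude of mortality seasonality.
#' @param dow_effects Length-7 log-scale day-of-week effects, Monday first.
#' @param overdispersion Variance/mean ratio of daily counts (1 = Poisson).
#' @param mmt0 True MMT (degrees C) in the first subperiod.
#' @param mmt_slope True change in MMT per subperiod (degrees C); the truth
#'   is a step function, constant within each subperiod.
#' @param curvature Lag-cumulative log-rate curvature per squared degree C.
#' @param lag_halflife,max_lag Exponential lag-decay half-life (days) and
#'   maximum lag.
#' @param country_int_sd,country_slope_sd,community_int_sd,community_slope_sd
#'   Standard deviations of the random intercepts/slopes of the true MMT
#'   (the square roots of the diagonals of the true Psi matrices).
#' @param width_years Subperiod width used to step the true MMT.
#' @param region_slopes Optional numeric vector, one entry per region
#'   (countries are assigned to regions round-robin), added to `mmt_slope`
#'   region-wide; use to create genuine region x time heterogeneity.
#' @param n_regions Number of region labels.
#' @param seed Root seed; all randomness derives from it.
#' @return Object of class `truth_spec`.
#' @export
truth_spec <- function(n_countries = 2L, communities_per_country = 3L,
                       years = 30L, start_year = 1986L,
                       temp_mean = 18, temp_offset_sd = 3,
                       amplitude = 8, warming = 0.3,
                       ar_sd = 2, ar_rho = 0.6,
                       baseline = 30, seasonal_amplitude = 0.1,
                       dow_effects = c(0, 0, 0, 0, 0.01, -0.02, -0.03),
                       overdispersion = 1.3,
                       mmt0 = 20, mmt_slope = 0, curvature = 0.004,
                       lag_halflife = 3, max_lag = 21L,
                       country_int_sd = 0, country_slope_sd = 0,
                       community_int_sd = 0, community_slope_sd = 0,
                       width_years = 5L,
                       region_slopes = NULL, n_regions = 1L,
                       seed = 1L) {
  stopifnot(n_countries >= 1, communities_per_country >= 1, years >= 1,
            baseline > 0, overdispersion >= 1, curvature >= 0,
            lag_halflife > 0, length(dow_effects) == 7)
  structure(as.list(environment()), class = "truth_spec")
}

#' Simulate a community's daily mean temperature series
#'
#' `mean + amplitude * cos(2 pi (doy - peak) / 365.25) + warming * years/10`
#' plus stationary AR(1) noise. Reproducible under `seed`.
#'
#' @param years Number of calendar years.
#' @param start_year First year.
#' @param mean Community mean temperature (degrees C).
#' @param amplitude,peak_doy Seasonal amplitude and day-of-year of the peak.
#' @param warming Degrees C per decade.
#' @param ar_sd,ar_rho Stationary sd and lag-1 correlation of the noise
#'   (`ar_sd = 0` gives the exact deterministic sinusoid).
#' @param seed Integer seed.
#' @return Tibble with `date` and `tmean`.
#' @export
simulate_temperature <- function(years, start_year = 1986L, mean = 18,
                                 amplitude = 8, peak_doy = 197,
                                 warming = 0.3, ar_sd = 2, ar_rho = 0.6,
                                 seed = 1L) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1L)),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  elapsed <- as.numeric(dates - dates[1]) / 365.25
  det <- mean + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25) +
    warming * elapsed / 10
  noise <- 0
  if (ar_sd > 0) {
    set.seed(seed)
    innov <- stats::rnorm(length(dates), 0, ar_sd * sqrt(1 - ar_rho^2))
    noise <- as.numeric(stats::filter(innov, ar_rho, method = "recursive",
                                      init = stats::rnorm(1, 0, ar_sd)))
  }
  tibble::tibble(date = dates, tmean = det + noise)
}

#' Exponential-decay lag weights over lags 0..max_lag, summing to one
#' @noRd
lag_weights <- function(halflife, max_lag) {
  w <- 0.5^((0:max_lag) / halflife)
  w / sum(w)
}

#' Simulate daily death counts from a lagged U-shaped temperature response
#'
#' Counts are drawn from a negative binomial with mean `lambda_t` and
#' variance `overdispersion * lambda_t`, where
#' `log lambda_t = log(baseline) + seasonality + day-of-week +
#' sum_l w(l) * curvature * (x_{t-l} - MMT*_t)^2`, with `w(l)` an
#' exponential decay over lags 0..`max_lag` normalized to sum to 1 (so
#' `curvature` is the curvature of the lag-cumulative curve) and `MMT*_t`
#' the true minimum of the cumulative curve on day `t`. Early days reuse
#' the first observed temperature for unavailable lags.
#'
#' @param dates,tmean Daily dates and temperatures.
#' @param mmt_true True MMT per day (scalar or vector; a step function over
#'   subperiods in the full generator).
#' @param baseline,seasonal_amplitude,dow_effects,overdispersion,curvature,
#'   lag_halflife,max_lag See [truth_spec()].
#' @param peak_doy Day-of-year of peak mortality (default mid-January).
#' @param seed Integer seed.
#' @return Integer vector of daily counts.
#' @export
simulate_mortality <- function(dates, tmean, mmt_true,
                               baseline = 30, seasonal_amplitude = 0.1,
                               dow_effects = c(0, 0, 0, 0, 0.01, -0.02, -0.03),
                               overdispersion = 1.3,
                               curvature = 0.004, lag_halflife = 3,
                               max_lag = 21L, peak_doy = 15,
                               seed = 1L) {
  stopifnot(all(is.finite(tmean)), length(dates) == length(tmean))
  n <- length(tmean)
  mmt_true <- rep_len(mmt_true, n)
  w <- lag_weights(lag_halflife, max_lag)
  # lagged quadratic exposure term, cumulated with the lag weights
  xpad <- c(rep(tmean[1], max_lag), tmean)
  expo <- numeric(n)
  for (l in 0:max_lag) {
    xl <- xpad[(max_lag - l + 1):(max_lag - l + n)]
    expo <- expo + w[l + 1] * curvature * (xl - mmt_true)^2
  }
  doy <- as.integer(format(dates, "%j"))
  dow <- dow_effects[((as.integer(dates) + 3L) %% 7L) + 1L]
  log_lambda <- log(baseline) +
    seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25) +
    dow + expo
  lambda <- exp(log_lambda)
  set.seed(seed)
  if (overdispersion <= 1) {
    stats::rpois(n, lambda)
  } else {
    size <- lambda / (overdispersion - 1)
    stats::rnbinom(n, size = size, mu = lambda)
  }
}

#' Generate the full synthetic multi-country dataset with ground truth
#'
#' Draws country- and community-level random intercepts and slopes for the
#' true MMT, simulates each community's temperature and mortality series,
#' and tabulates the per-subperiod truth: true MMT, its percentile under
#' the community-subperiod temperature distribution, and the subperiod
#' average temperature.
#'
#' @param spec A [truth_spec()].
#' @return List: `data` (daily tibble: `community_id`, `country_id`,
#'   `region`, `climate_zone`, `date`, `deaths`, `tmean`), `meta` (one row
#'   per community), `truth` (per community x subperiod: `mmt_true`,
#'   `mmtp_true`, `at_true`, plus the true slope per community), and `spec`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(spec$seed)
  n_comm <- spec$n_countries * spec$communities_per_country
  c_int <- stats::rnorm(spec$n_countries, 0, spec$country_int_sd)
  c_slope <- stats::rnorm(spec$n_countries, 0, spec$country_slope_sd)
  a_int <- stats::rnorm(n_comm, 0, spec$community_int_sd)
  b_slope <- stats::rnorm(n_comm, 0, spec$community_slope_sd)
  offsets <- stats::rnorm(n_comm, 0, spec$temp_offset_sd)

  region_of <- ((seq_len(spec$n_countries) - 1L) %% spec$n_regions) + 1L
  reg_slopes <- spec$region_slopes %||% rep(0, spec$n_regions)
  stopifnot(length(reg_slopes) == spec$n_regions)

  n_periods <- ceiling(spec$years / spec$width_years)
  zone_labels <- c("Continental", "Temperate", "Dry", "Tropical")

  data_rows <- vector("list", n_comm)
  truth_rows <- vector("list", n_comm)
  meta_rows <- vector("list", n_comm)
  k <- 0L
  for (i in seq_len(spec$n_countries)) {
    for (j in seq_len(spec$communities_per_country)) {
      k <- k + 1L
      cid <- sprintf("c%02d_%02d", i, j)
      cty <- sprintf("country_%02d", i)
      temp <- simulate_temperature(
        years = spec$years, start_year = spec$start_year,
        mean = spec$temp_mean + offsets[k],
        amplitude = spec$amplitude, warming = spec$warming,
        ar_sd = spec$ar_sd, ar_rho = spec$ar_rho,
        seed = unit_seed(spec$seed, k)
      )
      slope_k <- spec$mmt_slope + reg_slopes[region_of[i]] +
        c_slope[i] + b_slope[k]
      yr <- as.integer(format(temp$date, "%Y"))
      w_of_day <- pmin(((yr - spec$start_year) %/% spec$width_years) + 1L,
                       n_periods)
      mmt_day <- spec$mmt0 + c_int[i] + a_int[k] + slope_k * (w_of_day - 1L)
      deaths <- simulate_mortality(
        temp$date, temp$tmean, mmt_day,
        baseline = spec$baseline,
        seasonal_amplitude = spec$seasonal_amplitude,
        dow_effects = spec$dow_effects,
        overdispersion = spec$overdispersion,
        curvature = spec$curvature, lag_halflife = spec$lag_halflife,
        max_lag = spec$max_lag,
        seed = unit_seed(spec$seed, k + n_comm)
      )
      zone <- zone_labels[findInterval(spec$temp_mean + offsets[k],
                                       c(12, 17, 22)) + 1L]
      region <- sprintf("region_%02d", region_of[i])
      data_rows[[k]] <- tibble::tibble(
        community_id = cid, country_id = cty, region = region,
        climate_zone = zone, date = temp$date, deaths = deaths,
        tmean = temp$tmean
      )
      tr <- tibble::tibble(
        community_id = cid, country_id = cty, w = seq_len(n_periods)
      )
      tr$mmt_true <- spec$mmt0 + c_int[i] + a_int[k] + slope_k * (tr$w - 1L)
      tr$mmtp_true <- vapply(seq_len(n_periods), function(w) {
        mmt_to_percentile(tr$mmt_true[w], temp$tmean[w_of_day == w])
      }, numeric(1))
      tr$at_true <- vapply(seq_len(n_periods), function(w) {
        mean(temp$tmean[w_of_day == w])
      }, numeric(1))
      tr$slope_true <- slope_k
      truth_rows[[k]] <- tr
      meta_rows[[k]] <- tibble::tibble(
        community_id = cid, country_id = cty, region = region,
        climate_zone = zone
      )
    }
  }
  list(data = dplyr::bind_rows(data_rows),
       meta = dplyr::bind_rows(meta_rows),
       truth = dplyr::bind_rows(truth_rows),
       spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate subperiod records directly from the pooling model
#'
#' Draws (community, subperiod) MMT records straight from the second-stage
#' model -- fixed intercept and slope, country- and community-level random
#' intercepts and slopes, and known-variance sampling error -- without
#' generating daily series. This is the natural scale for replicate-heavy
#' simulation studies of the pooling stage (type-I error, power,
#' confounding by average temperature).
#'
#' @param n_countries,communities_per_country,n_periods Layout.
#' @param alpha,beta Fixed intercept and slope (per subperiod) of the true
#'   mean; ignored for the outcome when `kappa` is given.
#' @param sd Known sampling standard deviation of each record (scalar or
#'   recycled).
#' @param psi1,psi2 Length-2 vectors: variances of the (intercept, slope)
#'   random effects at the country and community level (diagonal truth).
#' @param region_slopes Optional per-region additions to `beta`
#'   (round-robin assignment of countries to regions).
#' @param n_regions Number of regions.
#' @param at_base_mean,at_base_sd Community-level mean of the subperiod
#'   average temperature AT and its between-community sd.
#' @param at_trend Warming of AT per subperiod (degrees C).
#' @param at_noise Within-community noise sd of AT around its trend.
#' @param kappa If non-`NULL`, the outcome is driven *only* by AT:
#'   `estimate = alpha + kappa * AT + random effects + error` (no direct
#'   time term), the confounded scenario.
#' @param seed Integer seed.
#' @return Tibble of records ready for [fit_memr()]: `country_id`,
#'   `community_id`, `w`, `time`, `metric`, `estimate`, `sd`, `AT`, `TAT`,
#'   `region`, `converged`.
#' @export
simulate_records <- function(n_countries = 10L, communities_per_country = 5L,
                             n_periods = 6L, alpha = 20, beta = 0.2,
                             sd = 0.5,
                             psi1 = c(0, 0), psi2 = c(0.25, 0.01),
                             region_slopes = NULL, n_regions = 1L,
                             at_base_mean = 18, at_base_sd = 3,
                             at_trend = 0.15, at_noise = 0.1,
                             kappa = NULL, seed = 1L) {
  set.seed(seed)
  reg_slopes <- region_slopes %||% rep(0, n_regions)
  stopifnot(length(reg_slopes) == n_regions)
  region_of <- ((seq_len(n_countries) - 1L) %% n_regions) + 1L
  rows <- vector("list", n_countries * communities_per_country)
  k <- 0L
  for (i in seq_len(n_countries)) {
    ci_ <- stats::rnorm(1, 0, sqrt(psi1[1]))
    di_ <- stats::rnorm(1, 0, sqrt(psi1[2]))
    for (j in seq_len(communities_per_country)) {
      k <- k + 1L
      aij <- stats::rnorm(1, 0, sqrt(psi2[1]))
      bij <- stats::rnorm(1, 0, sqrt(psi2[2]))
      at_base <- stats::rnorm(1, at_base_mean, at_base_sd)
      w <- seq_len(n_periods)
      AT <- at_base + at_trend * (w - 1L) + stats::rnorm(n_periods, 0, at_noise)
      mu <- if (is.null(kappa)) {
        alpha + ci_ + aij + (beta + reg_slopes[region_of[i]] + di_ + bij) * w
      } else {
        alpha + ci_ + aij + (di_ + bij) * w + kappa * AT
      }
      sds <- rep_len(sd, n_periods)
      rows[[k]] <- tibble::tibble(
        country_id = sprintf("country_%02d", i),
        community_id = sprintf("c%02d_%02d", i, j),
        w = w, time = as.numeric(w), metric = "MMT",
        estimate = stats::rnorm(n_periods, mu, sds),
        sd = sds, AT = AT, TAT = mean(AT),
        region = sprintf("region_%02d", region_of[i]),
        converged = TRUE
      )
    }
  }
  dplyr::bind_rows(rows)
}
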