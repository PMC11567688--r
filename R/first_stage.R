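#' Split a daily series into nonoverlapping calendar subperiods
#'
#' Cuts the study window `start_year..end_year` into consecutive blocks of
#' `width_years` calendar years (e.g. 1986-1990, ..., 2011-2015), indexed
#' `w = 1, 2, ...` from the first block. Each community's rows are
#' intersected with each block; blocks with no overlap are omitted.
#' Subperiods are treated as independent series downstream: lags never carry
#' over a subperiod boundary.
#'
#' @param data Tibble of daily rows with at least `community_id` and `date`
#'   (class `Date`) columns.
#' @param start_year,end_year First and last calendar year of the study
#'   window.
#' @param width_years Width of each block in years.
#' @return The input rows restricted to the window, with an integer
#'   subperiod index column `w` added.
#' @export
#' @examples
#' d <- tibble::tibble(community_id = "a",
#'                     date = seq(as.Date("1986-01-01"),
#'                                as.Date("2015-12-31"), by = "day"))
#' dplyr::count(split_subperiods(d), w)
split_subperiods <- function(data, start_year = 1986L, end_year = 2015L,
                             width_years = 5L) {
  if (start_year > end_year) stop("start year after end year", call. = FALSE)
  stopifnot(width_years >= 1)
  yr <- as.integer(format(data$date, "%Y"))
  keep <- yr >= start_year & yr <= end_year
  out <- data[keep, , drop = FALSE]
  out$w <- ((as.integer(format(out$date, "%Y")) - start_year) %/%
              as.integer(width_years)) + 1L
  dplyr::as_tibble(out)
}

#' Seasonality and day-of-week control design
#'
#' Builds the within-subperiod control block: a natural cubic spline of time
#' with `round(df_per_year * n_days / 365.25)` degrees of freedom (knots
#' equally spaced over the date range) to absorb seasonality and long-term
#' trends, plus six day-of-week indicators (Monday as reference).
#'
#' @param dates Consecutive `Date` vector.
#' @param df_per_year Seasonal degrees of freedom per year (default 8).
#' @return List with `seasonal` (`N x df` matrix), `dow` (`N x 6` 0/1
#'   matrix) and `df` (the seasonal degrees of freedom used).
#' @export
build_control_design <- function(dates, df_per_year = 8) {
  n <- length(dates)
  if (n < 365) {
    warning("fewer than one year of days: seasonal control is weakly identified")
  }
  df <- max(2L, as.integer(round(df_per_year * n / 365.25)))
  t_num <- as.numeric(dates - dates[1])
  seasonal <- splines::ns(t_num, df = df)
  colnames(seasonal) <- paste0("seas_", seq_len(df))
  # day of week computed from the epoch (locale-independent); Monday = ref
  wd <- factor((as.integer(dates) + 3L) %% 7L, levels = 0:6,
               labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  dow <- stats::model.matrix(~ wd)[, -1, drop = FALSE]
  colnames(dow) <- paste0("dow_", levels(wd)[-1])
  list(seasonal = unclass(seasonal)[, , drop = FALSE], dow = dow, df = df)
}

#' Quasi-Poisson fit of a daily count series on a given design
#'
#' Poisson maximum likelihood by iteratively reweighted least squares
#' (via [stats::glm.fit()]), with the quasi-Poisson covariance
#' `dispersion * (X'WX)^-1`, where the dispersion is the Pearson chi-square
#' divided by the residual degrees of freedom.
#'
#' @param y Non-negative integer counts.
#' @param design Numeric design matrix including the intercept column.
#' @param valid_rows Logical mask of rows to use.
#' @param cb_cols Integer indices of the cross-basis columns within
#'   `design`; coefficients and covariance for this block are returned as
#'   `beta` / `vbeta`.
#' @return Object of class `first_stage_fit`: `beta`, `vbeta` (cross-basis
#'   block), `coefficients` and `vcov` (full), `dispersion`, `n_used`,
#'   `converged`.
#' @export
fit_quasi_poisson <- function(y, design, valid_rows = NULL, cb_cols = NULL) {
  if (is.null(valid_rows)) valid_rows <- rep(TRUE, length(y))
  X <- design[valid_rows, , drop = FALSE]
  yy <- y[valid_rows]
  p <- ncol(X)
  fit <- suppressWarnings(
    stats::glm.fit(X, yy, family = stats::poisson())
  )
  aliased <- is.na(fit$coefficients)
  if (any(aliased)) {
    if (!is.null(cb_cols) && any(aliased[cb_cols])) {
      # cannot salvage a fit whose exposure block is rank deficient
      return(structure(list(converged = FALSE, reason = "rank-deficient cross-basis"),
                       class = "first_stage_fit"))
    }
    warning("dropping ", sum(aliased), " aliased control column(s)")
    keep <- which(!aliased)
    return(fit_quasi_poisson(y, design[, keep, drop = FALSE], valid_rows,
                             cb_cols = match(cb_cols, keep)))
  }
  mu <- fit$fitted.values
  n <- length(yy)
  pearson <- sum((yy - mu)^2 / mu)
  dispersion <- pearson / (n - p)
  # X'WX from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  vc <- tryCatch(dispersion * chol2inv(chol(XtWX)),
                 error = function(e) NULL)
  if (is.null(vc) || !isTRUE(fit$converged) || dispersion <= 0) {
    return(structure(list(converged = FALSE, reason = "IRLS failure"),
                     class = "first_stage_fit"))
  }
  coefs <- fit$coefficients
  if (is.null(cb_cols)) cb_cols <- seq_len(p)
  structure(
    list(beta = unname(coefs[cb_cols]),
         vbeta = unname(vc[cb_cols, cb_cols, drop = FALSE]),
         coefficients = coefs,
         vcov = vc,
         dispersion = dispersion,
         n_used = n,
         converged = TRUE),
    class = "first_stage_fit"
  )
}

#' @export
print.first_stage_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Quasi-Poisson DLNM fit: FAILED (", x$reason, ")\n", sep = "")
  } else {
    cat("Quasi-Poisson DLNM fit:", length(x$coefficients), "coefficients,",
        x$n_used, "days, dispersion", round(x$dispersion, 3), "\n")
  }
  invisible(x)
}

#' Reduce cross-basis coefficients to the lag-cumulative curve
#'
#' Collapses the `vx * vl` cross-basis coefficients to the `vx` coefficients
#' of the exposure-response cumulated over lags:
#' `theta = M1 beta`, `V(theta) = M1 V(beta) M1'`, with the reducing matrix
#' `M1 = I_vx (x) (1' C)` built from the lag basis matrix `C`.
#'
#' @param fit A converged [fit_quasi_poisson()] result whose `beta` is the
#'   cross-basis block.
#' @param cb The [build_cross_basis()] object the fit used.
#' @return Object of class `reduced_curve`: `theta` (`vx`), `vtheta`
#'   (`vx x vx`), `temp_basis` ([spline_spec()]) and `temp_range`.
#' @export
reduce_over_lags <- function(fit, cb) {
  stopifnot(inherits(cb, "cross_basis"))
  vx <- cb$spec$vx
  vl <- cb$spec$vl
  if (length(fit$beta) != vx * vl) {
    stop("coefficient vector length does not match the cross-basis (",
         length(fit$beta), " vs ", vx * vl, ")", call. = FALSE)
  }
  csum <- colSums(cb$lag_basis_matrix)       # 1' C, length vl
  M1 <- kronecker(diag(vx), matrix(csum, nrow = 1))
  theta <- drop(M1 %*% fit$beta)
  vtheta <- M1 %*% fit$vbeta %*% t(M1)
  structure(
    list(theta = theta, vtheta = (vtheta + t(vtheta)) / 2,
         temp_basis = cb$spec$temp_spline,
         temp_range = cb$spec$temp_spline$boundary_knots),
    class = "reduced_curve"
  )
}

#' Evaluate the lag-cumulative exposure-response curve
#'
#' Returns `sum_k theta_k f_k(x)` at the requested temperatures: the
#' log relative rate of death, cumulated over lags, up to an additive
#' constant (the model intercept is excluded, so only differences between
#' temperatures are meaningful).
#'
#' @param curve A [reduce_over_lags()] result.
#' @param temps Temperatures at which to evaluate.
#' @return Numeric vector of log-relative-rates.
#' @export
cumulative_curve <- function(curve, temps) {
  stopifnot(inherits(curve, "reduced_curve"))
  drop(natural_cubic_basis(temps, curve$temp_basis) %*% curve$theta)
}

#' Project a covariance matrix to the nearest symmetric PSD matrix
#' (eigenvalue clipping at zero). Used before Monte-Carlo sampling, where
#' short subperiods can yield numerically indefinite covariances.
#' @noRd
psd_project <- function(V) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  list(V = e$vectors %*% (vals * t(e$vectors)),
       root = e$vectors %*% diag(sqrt(vals), length(vals)))
}

#' Estimate the minimum mortality temperature with Monte-Carlo uncertainty
#'
#' The point estimate is the argmin of the lag-cumulative curve over a
#' regular temperature grid spanning the `search_percentiles` of the
#' subperiod's empirical temperature distribution (default 25th-99th; grid
#' step 0.1 degrees C; ties broken at the lowest temperature). The standard
#' error is the sample standard deviation of `n_sim` argmins of curves with
#' coefficients drawn from `N(theta, V(theta))` (`V` projected to PSD if
#' needed). The MMT is also converted to its percentile (MMTP) under the
#' same empirical distribution.
#'
#' @param curve A [reduce_over_lags()] result.
#' @param temps_subperiod Observed daily temperatures of the subperiod.
#' @param search_percentiles Length-2 percentile window, e.g. `c(25, 99)`;
#'   `c(1, 99)` is the conventional sensitivity variant.
#' @param n_sim Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param grid_step Grid resolution in degrees C.
#' @return Object of class `mmt_estimate`: `mmt`, `se`, `mmtp`, `samples`,
#'   `search_range` (temperatures), `converged`.
#' @export
estimate_mmt <- function(curve, temps_subperiod,
                         search_percentiles = c(25, 99),
                         n_sim = 1000L, seed = 1L, grid_step = 0.1) {
  stopifnot(inherits(curve, "reduced_curve"),
            length(search_percentiles) == 2,
            search_percentiles[1] < search_percentiles[2])
  temps <- temps_subperiod[!is.na(temps_subperiod)]
  if (length(temps) < 100L) {
    stop("need at least 100 non-missing temperatures for the MMT search",
         call. = FALSE)
  }
  lims <- stats::quantile(temps, search_percentiles / 100, type = 7)
  if (diff(lims) < grid_step) stop("degenerate MMT search grid", call. = FALSE)
  grid <- seq(lims[1], lims[2], by = grid_step)
  B <- natural_cubic_basis(grid, curve$temp_basis)
  mmt <- grid[which.min(B %*% curve$theta)]

  proj <- psd_project(curve$vtheta)
  k <- length(curve$theta)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_sim * k), k, n_sim)
  Theta <- curve$theta + proj$root %*% Z          # k x n_sim
  samples <- grid[max.col(-t(B %*% Theta), ties.method = "first")]
  structure(
    list(mmt = mmt,
         se = stats::sd(samples),
         mmtp = mmt_to_percentile(mmt, temps),
         samples = samples,
         search_range = unname(lims),
         search_percentiles = search_percentiles,
         converged = TRUE),
    class = "mmt_estimate"
  )
}

#' @export
print.mmt_estimate <- function(x, ...) {
  cat(sprintf("MMT %.1f degC (se %.2f), MMTP %.1f; search %.1f..%.1f degC\n",
              x$mmt, x$se, x$mmtp, x$search_range[1], x$search_range[2]))
  invisible(x)
}

#' Convert an MMT to its percentile in the observed temperature distribution
#'
#' `100 * P(T <= mmt)` under the empirical distribution of the non-missing
#' daily temperatures (weak inequality; ties counted fully).
#'
#' @param mmt Temperature in degrees C.
#' @param temps_subperiod Observed daily temperatures.
#' @return Percentile in `[0, 100]`.
#' @export
mmt_to_percentile <- function(mmt, temps_subperiod) {
  temps <- temps_subperiod[!is.na(temps_subperiod)]
  if (length(temps) == 0L) stop("no non-missing temperatures", call. = FALSE)
  100 * mean(temps <= mmt)
}

#' Derive a per-unit seed from the root seed (kept below 2^31)
#' @noRd
unit_seed <- function(seed, unit_index) {
  as.integer((as.numeric(seed) * 7919 + unit_index * 104729) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Run the first stage over every community and subperiod
#'
#' For each community x subperiod: builds the cross-basis (temperature knots
#' at the subperiod's 10th/75th/90th percentiles, log-spaced lag knots,
#' L = 21), the seasonal + day-of-week control design, fits the
#' quasi-Poisson DLNM, reduces over lags and estimates MMT and MMTP with
#' Monte-Carlo standard errors. Units failing the usability filter (fewer
#' than `min_days` days, fewer than `min_deaths` total deaths, or a failed
#' fit) are returned with `converged = FALSE` and `NA` estimates rather than
#' silently dropped.
#'
#' @param data Tibble of daily rows: `community_id`, `country_id`, `date`,
#'   `deaths`, `tmean`, and optionally `region`, `climate_zone` (else taken
#'   from `meta`).
#' @param meta Optional tibble `community_id`, `country_id`, `region`,
#'   `climate_zone`.
#' @param start_year,end_year,width_years Study window and subperiod width.
#' @param search_percentiles,n_sim,grid_step Passed to [estimate_mmt()].
#' @param df_per_year Seasonal degrees of freedom per year.
#' @param temp_percentiles,max_lag,n_lag_knots Cross-basis settings.
#' @param min_days,min_deaths Usability filter thresholds.
#' @param seed Root seed; each unit draws from a deterministic per-unit seed.
#' @return Tibble of subperiod records in long form, one row per unit and
#'   metric (`MMT`, `MMTP`): `community_id`, `country_id`, `w`, `metric`,
#'   `estimate`, `sd`, `AT`, `TAT`, `region`, `climate_zone`, `n_days`,
#'   `converged`.
#' @export
run_first_stage <- function(data, meta = NULL,
                            start_year = 1986L, end_year = 2015L,
                            width_years = 5L,
                            search_percentiles = c(25, 99),
                            n_sim = 1000L, grid_step = 0.1,
                            df_per_year = 8,
                            temp_percentiles = c(10, 75, 90),
                            max_lag = 21L, n_lag_knots = 3L,
                            min_days = 730L, min_deaths = 500,
                            seed = 1L) {
  data <- dplyr::as_tibble(data)
  if (!is.null(meta)) {
    meta_cols <- intersect(c("country_id", "region", "climate_zone"),
                           names(meta))
    data <- dplyr::left_join(
      dplyr::select(data, -dplyr::any_of(setdiff(meta_cols, "community_id"))),
      meta, by = intersect("community_id", names(meta))
    )
  }
  for (col in c("region", "climate_zone")) {
    if (!col %in% names(data)) data[[col]] <- NA_character_
  }
  data <- split_subperiods(data, start_year, end_year, width_years)

  units <- dplyr::distinct(data, .data$community_id, .data$w)
  units <- dplyr::arrange(units, .data$community_id, .data$w)
  rec <- purrr::pmap(list(units$community_id, units$w, seq_len(nrow(units))),
    function(cid, w, idx) {
      d <- data[data$community_id == cid & data$w == w, , drop = FALSE]
      d <- d[order(d$date), , drop = FALSE]
      base <- tibble::tibble(
        community_id = cid, country_id = d$country_id[1], w = w,
        region = d$region[1], climate_zone = d$climate_zone[1],
        n_days = nrow(d),
        AT = mean(d$tmean, na.rm = TRUE)
      )
      fail <- function(reason) {
        dplyr::mutate(base, metric = list(c("MMT", "MMTP")),
                      estimate = NA_real_, sd = NA_real_,
                      converged = FALSE, reason = reason) |>
          tidyr::unnest("metric")
      }
      if (nrow(d) < min_days) return(fail("too few days"))
      if (sum(d$deaths, na.rm = TRUE) < min_deaths) return(fail("too few deaths"))
      res <- tryCatch({
        cbspec <- default_cross_basis_spec(d$tmean, temp_percentiles,
                                           max_lag, n_lag_knots)
        cb <- build_cross_basis(d$tmean, cbspec)
        ctrl <- build_control_design(d$date, df_per_year)
        design <- cbind(`(Intercept)` = 1, ctrl$seasonal, ctrl$dow, cb$matrix)
        cb_cols <- seq.int(ncol(design) - ncol(cb$matrix) + 1L, ncol(design))
        valid <- cb$valid_rows & !is.na(d$deaths)
        if (sum(valid) < min_days / 2) stop("too few usable rows")
        fit <- fit_quasi_poisson(d$deaths, design, valid, cb_cols)
        if (!isTRUE(fit$converged)) stop(fit$reason)
        curve <- reduce_over_lags(fit, cb)
        estimate_mmt(curve, d$tmean, search_percentiles, n_sim,
                     seed = unit_seed(seed, idx), grid_step = grid_step)
      }, error = function(e) e)
      if (inherits(res, "error")) return(fail(conditionMessage(res)))
      dplyr::bind_rows(
        dplyr::mutate(base, metric = "MMT", estimate = res$mmt,
                      sd = res$se, converged = TRUE, reason = NA_character_),
        dplyr::mutate(base, metric = "MMTP", estimate = res$mmtp,
                      sd = stats::sd(vapply(res$samples, mmt_to_percentile,
                                            numeric(1),
                                            temps_subperiod = d$tmean)),
                      converged = TRUE, reason = NA_character_)
      )
    })
  out <- dplyr::bind_rows(rec)
  # time-averaged AT per community, over its available subperiods
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$community_id),
    TAT = mean(.data$AT[!duplicated(.data$w)], na.rm = TRUE)
  )
  dplyr::select(
    dplyr::ungroup(out),
    "community_id", "country_id", "w", "metric", "estimate", "sd",
    "AT", "TAT", "region", "climate_zone", "n_days", "converged", "reason"
  )
}
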