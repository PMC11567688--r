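#' Heterogeneity model ladder for temporal trends
#'
#' Compares, via likelihood-ratio tests and AIC/BIC, the meta-regression
#' models probing heterogeneity of the temporal trend:
#' (a) climate zone x time interaction, (b) region x time interaction
#' (both tested on ML fits, with the stratum main effect retained in the
#' reduced model), (c) country-level random slope, (d) community-level
#' random slope (both tested on REML fits with identical fixed effects).
#' Rows whose fits fail are reported with `NA` statistics and the error
#' message, never dropped.
#'
#' @param records Subperiod-record tibble for a single metric (`MMT` or
#'   `MMTP`), as produced by [run_first_stage()] (filter on `metric` first).
#' @param strata Character subset of `c("climate_zone", "region")` for the
#'   interaction tests.
#' @return Tibble: `test`, `statistic`, `df`, `p.value`, `aic_reduced`,
#'   `aic_full`, `bic_reduced`, `bic_full`, `method`, `error`.
#' @export
heterogeneity_suite <- function(records, strata = c("climate_zone", "region")) {
  rows <- list()
  run_row <- function(test, method, f_nested, f_full) {
    tryCatch({
      lt <- lr_test(f_nested(), f_full())
      dplyr::mutate(
        dplyr::rename(lt, aic_reduced = "aic_nested", bic_reduced = "bic_nested"),
        test = test, method = method, error = NA_character_,
        .before = 1
      )
    }, error = function(e) {
      tibble::tibble(test = test, method = method, statistic = NA_real_,
                     df = NA_integer_, p.value = NA_real_,
                     aic_reduced = NA_real_, aic_full = NA_real_,
                     bic_reduced = NA_real_, bic_full = NA_real_,
                     error = conditionMessage(e))
    })
  }
  for (st in strata) {
    if (!st %in% names(records) || dplyr::n_distinct(records[[st]]) < 2) next
    f_red <- stats::as.formula(paste("~ time +", st))
    f_ful <- stats::as.formula(paste("~ time *", st))
    rows[[paste0(st, "_x_time")]] <- run_row(
      paste0(st, " x time interaction"), "ML",
      function() fit_memr(records, f_red, method = "ML"),
      function() fit_memr(records, f_ful, method = "ML")
    )
  }
  rows[["country_slope"]] <- run_row(
    "country-level random slope", "REML",
    function() fit_memr(records, method = "REML",
                        country_random = "intercept"),
    function() fit_memr(records, method = "REML")
  )
  rows[["community_slope"]] <- run_row(
    "community-level random slope", "REML",
    function() fit_memr(records, method = "REML",
                        community_random = "intercept"),
    function() fit_memr(records, method = "REML")
  )
  dplyr::bind_rows(rows)
}

#' Does average temperature explain the temporal trend?
#'
#' Fits, by maximum likelihood, the time-only model, the model with the
#' subperiod average temperature `AT` added as a meta-predictor, and the
#' model with the time-centered version `AT - TAT` (the community's
#' time-averaged AT subtracted). Reports the time slope, its standard error
#' and p-value under each adjustment, optionally per stratum.
#'
#' @param records Subperiod-record tibble for one metric, carrying `AT` and
#'   `TAT` columns.
#' @param by Optional stratifying column name (e.g. `"region"`).
#' @return Tibble: one row per (stratum x) model with `model`
#'   (`time_only`, `plus_AT`, `plus_AT_centered`), `time_slope`,
#'   `time_se`, `time_p`, `gamma`, `gamma_p`, `n`, `error`.
#' @export
at_adjustment <- function(records, by = NULL) {
  one_stratum <- function(d, label) {
    forms <- list(time_only = ~ time,
                  plus_AT = ~ time + AT,
                  plus_AT_centered = ~ time + I(AT - TAT))
    purrr::imap_dfr(forms, function(f, nm) {
      out <- tryCatch({
        if (nm != "time_only") {
          Xc <- stats::model.matrix(f, dplyr::mutate(d, time = as.numeric(.data$w)))
          kappa_x <- kappa(Xc, exact = TRUE)
          if (kappa_x > 1e8) {
            warning("average temperature nearly collinear with time (condition number ",
                    format(kappa_x, digits = 3), ")")
          }
        }
        fit <- fit_memr(d, f, method = "ML")
        td <- tidy(fit)
        g <- td[grepl("^AT$|^I\\(AT", td$term), ]
        tibble::tibble(
          model = nm,
          time_slope = td$estimate[td$term == "time"],
          time_se = td$std.error[td$term == "time"],
          time_p = td$p.value[td$term == "time"],
          gamma = if (nrow(g)) g$estimate[1] else NA_real_,
          gamma_p = if (nrow(g)) g$p.value[1] else NA_real_,
          n = fit$n, error = NA_character_
        )
      }, error = function(e) {
        tibble::tibble(model = nm, time_slope = NA_real_, time_se = NA_real_,
                       time_p = NA_real_, gamma = NA_real_, gamma_p = NA_real_,
                       n = nrow(d), error = conditionMessage(e))
      })
      if (!is.null(label)) out <- dplyr::mutate(out, stratum = label, .before = 1)
      out
    })
  }
  if (is.null(by)) return(one_stratum(records, NULL))
  records |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::group_map(~ one_stratum(.x, .y[[1]])) |>
    dplyr::bind_rows()
}

#' Pooled temporal trajectory and linear slope from a fitted model
#'
#' The pooled value at subperiod `w` is `alpha + beta * w` with a Wald 95%
#' confidence interval from the fixed-effect covariance; the linear slope
#' (LS) is `beta` with its standard error and p-value. MMT trajectories are
#' in degrees C, MMTP trajectories in percentile points; slopes are per
#' subperiod (5 years).
#'
#' @param fit A [fit_memr()] object whose fixed effects include
#'   `(Intercept)` and `time`.
#' @param w_values Subperiod indices at which to evaluate (default `1:6`).
#' @param conf.level Confidence level.
#' @return Object of class `trend_summary`: a list with `trajectory`
#'   (tibble `w`, `pooled`, `conf.low`, `conf.high`) and `slope` (tibble
#'   `estimate`, `std.error`, `statistic`, `p.value`).
#' @export
pooled_trajectory <- function(fit, w_values = 1:6, conf.level = 0.95) {
  stopifnot(inherits(fit, "memr_fit"))
  cf <- fit$fixed
  if (!all(c("(Intercept)", "time") %in% names(cf))) {
    stop("fit must contain `(Intercept)` and `time` fixed effects",
         call. = FALSE)
  }
  V <- fit$vcov_fixed[c("(Intercept)", "time"), c("(Intercept)", "time")]
  a <- cf[["(Intercept)"]]; b <- cf[["time"]]
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  pooled <- a + b * w_values
  se <- sqrt(V[1, 1] + w_values^2 * V[2, 2] + 2 * w_values * V[1, 2])
  slope_se <- sqrt(V[2, 2])
  z <- b / slope_se
  structure(
    list(
      trajectory = tibble::tibble(
        w = w_values, pooled = pooled,
        conf.low = pooled - q * se, conf.high = pooled + q * se
      ),
      slope = tibble::tibble(
        estimate = b, std.error = slope_se, statistic = z,
        p.value = 2 * stats::pnorm(-abs(z))
      )
    ),
    class = "trend_summary"
  )
}

#' @export
print.trend_summary <- function(x, ...) {
  first <- x$trajectory[1, ]; last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf(
    "Pooled trajectory: %.2f (%.2f, %.2f) at w=%d -> %.2f (%.2f, %.2f) at w=%d\n",
    first$pooled, first$conf.low, first$conf.high, first$w,
    last$pooled, last$conf.low, last$conf.high, last$w))
  cat(sprintf("Linear slope (per subperiod): %.3f (se %.3f, P = %.3g)\n",
              x$slope$estimate, x$slope$std.error, x$slope$p.value))
  invisible(x)
}

#' Fit the pooling model separately within each stratum
#'
#' Refits the pooling meta-regression on each stratum's records only (as is
#' done per climate zone, geographical region or country) and summarizes
#' each fit's trajectory and linear slope.
#'
#' @param records Subperiod-record tibble for one metric.
#' @param by Stratifying column (`"climate_zone"`, `"region"`,
#'   `"country_id"`), or `NULL` for the whole set.
#' @param w_values Subperiods to evaluate.
#' @param ... Passed to [fit_memr()].
#' @return Tibble with one row per stratum and `w`: stratum label, pooled
#'   value with CI, slope, slope p-value, and an `error` column for strata
#'   whose fit failed (explicit `NA` rows, never dropped).
#' @export
stratified_trajectories <- function(records, by = NULL, w_values = 1:6, ...) {
  strat <- if (is.null(by)) list(overall = records) else
    split(records, records[[by]])
  purrr::imap_dfr(strat, function(d, label) {
    res <- tryCatch({
      fit <- fit_memr(d, ...)
      ts <- pooled_trajectory(fit, w_values)
      dplyr::mutate(ts$trajectory,
                    slope = ts$slope$estimate,
                    slope_p = ts$slope$p.value,
                    error = NA_character_)
    }, error = function(e) {
      tibble::tibble(w = NA_integer_, pooled = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     slope = NA_real_, slope_p = NA_real_,
                     error = conditionMessage(e))
    })
    dplyr::mutate(res, stratum = label, .before = 1)
  })
}
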