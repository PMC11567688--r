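#' Two-level mixed-effects meta-regression with known sampling variances
#'
#' Fits the pooling model for subperiod estimates
#' `y_ijw = x_ijw' beta_fixed + z' u_ij + z' v_i + e_ijw`, where `i` indexes
#' countries, `j` communities nested in countries, `w` subperiods, the
#' residuals `e_ijw ~ N(0, sd_ijw^2)` have *known* variances from the first
#' stage, and the random effects are community-level `u_ij ~ N(0, Psi2)` and
#' country-level `v_i ~ N(0, Psi1)` intercepts and/or slopes in the time
#' variable. Estimation maximizes the (restricted) likelihood over the
#' log-Cholesky factors of `Psi1`, `Psi2`, with the fixed effects profiled
#' out by generalized least squares.
#'
#' @param records Tibble with columns `estimate`, `sd` (> 0), `country_id`,
#'   `community_id`, a `time` column (taken from `w` if absent) and any
#'   covariates named in `fixed`. Rows with `converged == FALSE`, missing
#'   estimates or non-positive `sd` are dropped.
#' @param fixed Right-hand-side formula for the fixed effects, e.g.
#'   `~ time`, `~ time + AT`, `~ time * region`.
#' @param method `"REML"` (default, for reported fits and random-structure
#'   tests) or `"ML"` (for fixed-effect likelihood-ratio tests).
#' @param country_random,community_random Random-effect structure at each
#'   level: `"intercept_slope"`, `"intercept"`, or `"none"`.
#' @param control List: `maxit`, `reltol`, `n_starts`.
#' @return Object of class `memr_fit` with elements `fixed` (named
#'   coefficients), `vcov_fixed`, `psi1`, `psi2`, `loglik`, `aic`, `bic`,
#'   `method`, `blups` (list of `country` and `community` tibbles), `n`,
#'   `n_fixed`, `n_varpar`, `fitted`, `records`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   country_id = rep(c("A", "B"), each = 12),
#'   community_id = rep(c("a1", "a2", "b1", "b2"), each = 6),
#'   w = rep(1:6, 4), estimate = rnorm(24, 20 + 0.2 * rep(1:6, 4), 0.5),
#'   sd = 0.5
#' )
#' fit <- fit_memr(rec)
#' generics::tidy(fit)
fit_memr <- function(records, fixed = ~ time,
                     method = c("REML", "ML"),
                     country_random = c("intercept_slope", "intercept", "none"),
                     community_random = c("intercept_slope", "intercept", "none"),
                     control = list()) {
  method <- match.arg(method)
  country_random <- match.arg(country_random)
  community_random <- match.arg(community_random)
  ctrl <- utils::modifyList(list(maxit = 2000L, reltol = 1e-8, n_starts = 2L),
                            control)

  d <- dplyr::as_tibble(records)
  if (!"time" %in% names(d) && "w" %in% names(d)) d$time <- as.numeric(d$w)
  if ("converged" %in% names(d)) d <- d[isTRUE_vec(d$converged), , drop = FALSE]
  d <- d[is.finite(d$estimate) & is.finite(d$sd) & d$sd > 0, , drop = FALSE]
  if (nrow(d) < 2L) stop("too few usable records", call. = FALSE)

  mf <- stats::model.frame(fixed, data = d, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  d <- d[keep, , drop = FALSE]
  X <- stats::model.matrix(fixed, mf)
  y <- d$estimate
  s2 <- d$sd^2
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient", call. = FALSE)

  q1 <- switch(country_random, none = 0L, intercept = 1L, intercept_slope = 2L)
  q2 <- switch(community_random, none = 0L, intercept = 1L, intercept_slope = 2L)
  zmat <- function(q, tt) {
    if (q == 0L) NULL
    else if (q == 1L) matrix(1, length(tt), 1L)
    else cbind(1, tt)
  }
  country <- factor(d$country_id)
  community <- factor(paste(d$country_id, d$community_id, sep = "\r"))
  ci <- split(seq_len(n), country)
  # per country: positions of each of its communities within the block
  comm_within <- lapply(ci, function(idx) {
    split(seq_along(idx), droplevels(community[idx]))
  })

  npar1 <- c(0L, 1L, 3L)[q1 + 1L]
  npar2 <- c(0L, 1L, 3L)[q2 + 1L]
  n_varpar <- npar1 + npar2

  psi_from_par <- function(par, q) {
    if (q == 0L) return(NULL)
    if (q == 1L) return(matrix(exp(2 * par[1]), 1, 1))
    Lc <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
    tcrossprod(Lc)
  }

  # -2 log (restricted) likelihood, fixed effects profiled out
  neg2ll <- function(par) {
    psi1 <- psi_from_par(par[seq_len(npar1)], q1)
    psi2 <- psi_from_par(par[npar1 + seq_len(npar2)], q2)
    logdet <- 0
    A <- matrix(0, p, p); b <- numeric(p); qq <- 0
    for (g in seq_along(ci)) {
      idx <- ci[[g]]
      Vi <- diag(s2[idx], length(idx))
      if (q1 > 0L) {
        Z1 <- zmat(q1, d$time[idx])
        Vi <- Vi + Z1 %*% psi1 %*% t(Z1)
      }
      if (q2 > 0L) {
        for (sub in comm_within[[g]]) {
          Z2 <- zmat(q2, d$time[idx][sub])
          Vi[sub, sub] <- Vi[sub, sub] + Z2 %*% psi2 %*% t(Z2)
        }
      }
      U <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(U)) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(U)))
      Xs <- backsolve(U, X[idx, , drop = FALSE], transpose = TRUE)
      ys <- backsolve(U, y[idx], transpose = TRUE)
      A <- A + crossprod(Xs); b <- b + drop(crossprod(Xs, ys))
      qq <- qq + sum(ys^2)
    }
    Ainv_b <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(Ainv_b)) return(1e10)
    rss <- qq - sum(b * Ainv_b)
    if (method == "ML") {
      logdet + rss + n * log(2 * pi)
    } else {
      ldA <- determinant(A, logarithm = TRUE)$modulus
      logdet + rss + ldA + (n - p) * log(2 * pi)
    }
  }

  # crude scale for starting values: residual spread around a WLS line
  wls <- stats::lm.wfit(X, y, w = 1 / s2)
  tau0 <- max(stats::sd(wls$residuals), 1e-3)
  make_start <- function(scale) {
    st <- numeric(0)
    if (npar1 == 1L) st <- c(st, log(scale))
    if (npar1 == 3L) st <- c(st, log(scale), 0, log(scale / 4))
    if (npar2 == 1L) st <- c(st, log(scale))
    if (npar2 == 3L) st <- c(st, log(scale), 0, log(scale / 4))
    st
  }
  opt <- NULL
  if (n_varpar > 0L) {
    scales <- tau0 * c(1, 0.2, 3)[seq_len(ctrl$n_starts)]
    for (sc in scales) {
      o <- stats::optim(make_start(sc), neg2ll, method = "Nelder-Mead",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol))
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
    par_hat <- opt$par
  } else {
    par_hat <- numeric(0)
  }
  dev <- neg2ll(par_hat)
  if (dev >= 1e10) stop("meta-regression failed to converge", call. = FALSE)

  psi1 <- psi_from_par(par_hat[seq_len(npar1)], q1)
  psi2 <- psi_from_par(par_hat[npar1 + seq_len(npar2)], q2)

  # final GLS pass at the optimum: fixed effects, covariance, BLUPs
  A <- matrix(0, p, p); b <- numeric(p)
  Vinv_list <- vector("list", length(ci))
  for (g in seq_along(ci)) {
    idx <- ci[[g]]
    Vi <- diag(s2[idx], length(idx))
    if (q1 > 0L) {
      Z1 <- zmat(q1, d$time[idx])
      Vi <- Vi + Z1 %*% psi1 %*% t(Z1)
    }
    if (q2 > 0L) {
      for (sub in comm_within[[g]]) {
        Z2 <- zmat(q2, d$time[idx][sub])
        Vi[sub, sub] <- Vi[sub, sub] + Z2 %*% psi2 %*% t(Z2)
      }
    }
    Vinv_list[[g]] <- chol2inv(chol(Vi))
    A <- A + t(X[idx, , drop = FALSE]) %*% Vinv_list[[g]] %*% X[idx, , drop = FALSE]
    b <- b + drop(t(X[idx, , drop = FALSE]) %*% Vinv_list[[g]] %*% y[idx])
  }
  vcov_fixed <- solve(A)
  beta <- drop(vcov_fixed %*% b)
  names(beta) <- colnames(X)
  dimnames(vcov_fixed) <- list(colnames(X), colnames(X))

  # BLUPs: E[u | y] = Psi Z' V^-1 (y - X beta)
  blup_country <- NULL; blup_comm <- NULL
  resid <- y - drop(X %*% beta)
  cn <- names(ci)
  rows_c <- vector("list", length(ci))
  for (g in seq_along(ci)) {
    idx <- ci[[g]]
    vr <- drop(Vinv_list[[g]] %*% resid[idx])
    if (q1 > 0L) {
      Z1 <- zmat(q1, d$time[idx])
      u <- drop(psi1 %*% t(Z1) %*% vr)
      rows_c[[g]] <- tibble::tibble(
        country_id = cn[g],
        intercept = u[1],
        slope = if (q1 == 2L) u[2] else 0
      )
    }
    if (q2 > 0L) {
      cw <- comm_within[[g]]
      for (h in seq_along(cw)) {
        sub <- cw[[h]]
        Z2 <- zmat(q2, d$time[idx][sub])
        u <- drop(psi2 %*% t(Z2) %*% vr[sub])
        key <- strsplit(names(cw)[h], "\r", fixed = TRUE)[[1]]
        blup_comm <- dplyr::bind_rows(blup_comm, tibble::tibble(
          country_id = key[1], community_id = key[2],
          intercept = u[1],
          slope = if (q2 == 2L) u[2] else 0
        ))
      }
    }
  }
  if (q1 > 0L) blup_country <- dplyr::bind_rows(rows_c)

  loglik <- -dev / 2
  n_param <- p + n_varpar
  fit <- structure(
    list(fixed = beta, vcov_fixed = vcov_fixed,
         psi1 = psi1, psi2 = psi2,
         loglik = loglik, deviance = dev,
         aic = dev + 2 * n_param,
         bic = dev + log(n) * n_param,
         method = method,
         fixed_formula = fixed,
         country_random = country_random,
         community_random = community_random,
         n = n, n_fixed = p, n_varpar = n_varpar,
         blups = list(country = blup_country, community = blup_comm),
         fitted = drop(X %*% beta),
         records = d,
         converged = if (n_varpar > 0L) opt$convergence == 0L else TRUE),
    class = "memr_fit"
  )
  fit
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.memr_fit <- function(x, ...) {
  cat("Mixed-effects meta-regression (", x$method, "), ", x$n,
      " records\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$fixed, 4))
  if (!is.null(x$psi1)) {
    cat("Country-level Psi(1):\n"); print(round(x$psi1, 4))
  }
  if (!is.null(x$psi2)) {
    cat("Community-level Psi(2):\n"); print(round(x$psi2, 4))
  }
  cat(sprintf("logLik %.3f  AIC %.2f  BIC %.2f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a meta-regression fit
#'
#' @param x A [fit_memr()] object.
#' @param conf.level Wald confidence level.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.memr_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_fixed))
  z <- x$fixed / se
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$fixed), estimate = unname(x$fixed),
    std.error = unname(se), statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(x$fixed - q * se),
    conf.high = unname(x$fixed + q * se)
  )
}

#' One-row model summary of a meta-regression fit
#' @param x A [fit_memr()] object.
#' @param ... Unused.
#' @return Tibble with log-likelihood, AIC, BIC, record count and the
#'   random-effect variances.
#' @exportS3Method generics::glance
glance.memr_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = x$aic, BIC = x$bic, nobs = x$n,
    method = x$method,
    psi1_int = if (is.null(x$psi1)) NA_real_ else x$psi1[1, 1],
    psi1_slope = if (!is.null(x$psi1) && nrow(x$psi1) == 2) x$psi1[2, 2] else NA_real_,
    psi2_int = if (is.null(x$psi2)) NA_real_ else x$psi2[1, 1],
    psi2_slope = if (!is.null(x$psi2) && nrow(x$psi2) == 2) x$psi2[2, 2] else NA_real_
  )
}

#' Random-effect predictions (BLUPs) from a meta-regression fit
#'
#' Conditional means of the country- and community-level random effects
#' given the data and the estimated variance components. The
#' community-specific prediction of an intercept or slope is the fixed
#' effect plus the country BLUP plus the community BLUP.
#'
#' @param fit A converged [fit_memr()] object.
#' @return List with tibbles `country` (`country_id`, `intercept`, `slope`),
#'   `community` (`country_id`, `community_id`, `intercept`, `slope`), and
#'   `community_prediction` (`intercept`, `slope` on the outcome scale).
#' @export
blups <- function(fit) {
  stopifnot(inherits(fit, "memr_fit"))
  b <- fit$blups
  pred <- NULL
  if (!is.null(b$community)) {
    fx_int <- unname(fit$fixed["(Intercept)"])
    fx_slope <- if ("time" %in% names(fit$fixed)) unname(fit$fixed["time"]) else NA_real_
    cc <- b$community
    if (!is.null(b$country)) {
      cc <- dplyr::left_join(cc, b$country, by = "country_id",
                             suffix = c("", ".country"))
      cc$intercept.country[is.na(cc$intercept.country)] <- 0
      cc$slope.country[is.na(cc$slope.country)] <- 0
    } else {
      cc$intercept.country <- 0; cc$slope.country <- 0
    }
    pred <- tibble::tibble(
      country_id = cc$country_id, community_id = cc$community_id,
      intercept = fx_int + cc$intercept.country + cc$intercept,
      slope = fx_slope + cc$slope.country + cc$slope
    )
  }
  list(country = b$country, community = b$community,
       community_prediction = pred)
}

#' Likelihood-ratio test between nested meta-regression fits
#'
#' `statistic = 2 (logLik_full - logLik_nested)` referred to a chi-square
#' with degrees of freedom equal to the difference in parameter counts
#' (fixed + variance parameters). Both fits must use the same estimation
#' flavor; REML comparisons additionally require identical fixed-effect
#' formulas (REML likelihoods are not comparable across fixed designs).
#' Variance-component tests on the boundary use the naive chi-square
#' reference, which is conservative.
#'
#' @param nested,full Two [fit_memr()] objects, `nested` within `full`.
#' @return Tibble with `statistic`, `df`, `p.value`, and the AIC/BIC of
#'   both fits.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "memr_fit"), inherits(full, "memr_fit"))
  if (nested$method != full$method) {
    stop("fits use different estimation flavors (", nested$method, " vs ",
         full$method, ")", call. = FALSE)
  }
  if (nested$method == "REML" &&
      !identical(deparse(nested$fixed_formula), deparse(full$fixed_formula))) {
    stop("REML likelihoods are only comparable with identical fixed effects; ",
         "refit with method = \"ML\"", call. = FALSE)
  }
  df <- (full$n_fixed + full$n_varpar) - (nested$n_fixed + nested$n_varpar)
  if (df < 0) stop("`full` has fewer parameters than `nested`", call. = FALSE)
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(
    statistic = stat, df = df, p.value = p,
    aic_nested = nested$aic, aic_full = full$aic,
    bic_nested = nested$bic, bic_full = full$bic
  )
}
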