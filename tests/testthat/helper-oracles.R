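# Independent brute-force oracles used across the test files. These are
# deliberately naive re-implementations, kept separate from the package code
# paths they check.

# Natural cubic spline basis via the truncated-power representation with the
# two natural (zero second derivative beyond the boundary) constraints
# imposed, following the classic textbook construction. Spans the same space
# as the package basis: compared through least-squares fitted values.
oracle_natural_spline_basis <- function(x, internal_knots, boundary_knots) {
  xi <- sort(c(boundary_knots, internal_knots))
  K <- length(xi)
  d <- function(k, x) {
    (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
  }
  out <- cbind(1, x)
  for (k in seq_len(K - 2)) {
    out <- cbind(out, d(k, x) - d(K - 1, x))
  }
  out
}

# Direct double/triple-loop cross-basis entry: sum_l f_j(x[t-l]) g_k(l)
oracle_cross_basis_entry <- function(x, t, j, k, temp_spec, lag_spec, L) {
  acc <- 0
  for (l in 0:L) {
    fx <- natural_cubic_basis(x[t - l], temp_spec)[1, j]
    gl <- natural_cubic_basis(l, lag_spec)[1, k]
    acc <- acc + fx * gl
  }
  acc
}

# Naive Poisson IRLS: weighted least squares on the working response.
oracle_poisson_irls <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w = mu)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      return(new_beta)
    }
    beta <- new_beta
  }
  beta
}

# Generalized-least-squares fixed effects and random-effect conditional
# means for the two-level model with known Psi matrices, built from the full
# marginal covariance (no blocking, no profiling).
oracle_gls_memr <- function(records, psi1, psi2) {
  d <- records
  n <- nrow(d)
  X <- cbind(1, d$time)
  Z <- function(ids, tt) {
    u <- unique(ids)
    out <- matrix(0, n, 2 * length(u))
    for (g in seq_along(u)) {
      rows <- which(ids == u[g])
      out[rows, 2 * g - 1] <- 1
      out[rows, 2 * g] <- tt[rows]
    }
    out
  }
  Z1 <- Z(d$country_id, d$time)
  Z2 <- Z(paste(d$country_id, d$community_id), d$time)
  G1 <- kronecker(diag(length(unique(d$country_id))), psi1)
  G2 <- kronecker(diag(length(unique(paste(d$country_id, d$community_id)))), psi2)
  V <- diag(d$sd^2) + Z1 %*% G1 %*% t(Z1) + Z2 %*% G2 %*% t(Z2)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$estimate)
  r <- d$estimate - X %*% beta
  list(beta = drop(beta),
       u1 = drop(G1 %*% t(Z1) %*% Vi %*% r),
       u2 = drop(G2 %*% t(Z2) %*% Vi %*% r))
}

# Weighted least squares closed form
oracle_wls <- function(y, X, w) {
  drop(solve(t(X) %*% (w * X), t(X) %*% (w * y)))
}

# Small daily synthetic community for unit tests (fast, no full generator)
tiny_series <- function(years = 5, seed = 1, mmt = 20, curvature = 0.004,
                        start_year = 2001) {
  temp <- simulate_temperature(years, start_year = start_year, mean = 18,
                               amplitude = 8, warming = 0, ar_sd = 2,
                               ar_rho = 0.5, seed = seed)
  deaths <- simulate_mortality(temp$date, temp$tmean, mmt,
                               baseline = 25, overdispersion = 1.2,
                               curvature = curvature, seed = seed + 1)
  tibble::tibble(community_id = "t1", country_id = "T",
                 region = "r1", climate_zone = "Temperate",
                 date = temp$date, deaths = deaths, tmean = temp$tmean)
}
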