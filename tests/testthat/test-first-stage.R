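make_dates <- function(from, to) seq(as.Date(from), as.Date(to), by = "day")

test_that("subperiod splitting yields the expected calendar blocks", {
  d <- tibble::tibble(community_id = "a",
                      date = make_dates("1986-01-01", "2015-12-31"))
  s <- split_subperiods(d)
  expect_equal(sort(unique(s$w)), 1:6)
  expect_equal(nrow(s), nrow(d))
  # block boundaries at exact calendar years
  expect_equal(min(s$date[s$w == 2]), as.Date("1991-01-01"))
  expect_equal(max(s$date[s$w == 2]), as.Date("1995-12-31"))

  # partial series: first block absent, second truncated
  d2 <- tibble::tibble(community_id = "a",
                       date = make_dates("1994-06-01", "2015-12-31"))
  s2 <- split_subperiods(d2)
  expect_equal(sort(unique(s2$w)), 2:6)
  expect_equal(min(s2$date[s2$w == 2]), as.Date("1994-06-01"))

  # restricted window
  d3 <- tibble::tibble(community_id = "a",
                       date = make_dates("1986-01-01", "2015-12-31"))
  s3 <- split_subperiods(d3, start_year = 2001, end_year = 2015)
  expect_equal(sort(unique(s3$w)), 1:3)
  expect_error(split_subperiods(d, 2010, 2000), "start year")
})

test_that("control design has the right seasonal df and full column rank", {
  dates5 <- make_dates("2001-01-01", "2005-12-31")
  ctrl <- build_control_design(dates5)
  expect_equal(ctrl$df, 40L)   # 8 df per year over 5 years
  expect_equal(dim(ctrl$seasonal), c(length(dates5), 40L))

  suppressWarnings({
    week <- build_control_design(make_dates("2001-01-01", "2001-01-07"))
  })
  expect_equal(dim(week$dow), c(7L, 6L))
  expect_equal(sum(week$dow), 6)  # one non-reference day per row except Monday

  dates2 <- make_dates("2001-01-01", "2002-12-31")
  ctrl2 <- build_control_design(dates2)
  M <- cbind(1, ctrl2$seasonal, ctrl2$dow)
  expect_equal(qr(M)$rank, 1L + ctrl2$df + 6L)
})

test_that("day-of-week indicators reference Monday regardless of locale", {
  # 2001-01-01 was a Monday
  ctrl <- suppressWarnings(build_control_design(make_dates("2001-01-01",
                                                           "2001-01-07")))
  expect_equal(unname(ctrl$dow[1, ]), rep(0, 6))
  expect_equal(unname(ctrl$dow[2, ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(ctrl$dow[7, ]), c(0, 0, 0, 0, 0, 1))
})

test_that("quasi-Poisson fit: closed form, naive IRLS oracle, dispersion", {
  # intercept-only closed form
  fit0 <- fit_quasi_poisson(c(2L, 2L, 2L, 2L), matrix(1, 4, 1))
  expect_equal(unname(fit0$beta), log(2), tolerance = 1e-10)
  expect_true(is.finite(fit0$dispersion))

  # coefficients match an independently coded IRLS on simulated data
  set.seed(21)
  n <- 500
  X <- cbind(1, rnorm(n), runif(n))
  beta_true <- c(1.2, 0.3, -0.5)
  y <- rpois(n, exp(drop(X %*% beta_true)))
  fit <- fit_quasi_poisson(y, X)
  expect_equal(unname(fit$coefficients), unname(oracle_poisson_irls(y, X)),
               tolerance = 1e-8)

  # Poisson data: dispersion close to 1
  set.seed(22)
  n <- 2000
  X2 <- cbind(1, rnorm(n))
  y2 <- rpois(n, exp(1 + 0.4 * X2[, 2]))
  fit2 <- fit_quasi_poisson(y2, X2)
  expect_lt(abs(fit2$dispersion - 1), 0.1)
  # covariance is symmetric PSD
  ev <- eigen(fit2$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("coefficient RMSE shrinks with sample size", {
  beta_true <- c(1.5, 0.3)
  rmse <- vapply(c(300, 3000), function(n) {
    set.seed(31)
    X <- cbind(1, rnorm(n))
    y <- rpois(n, exp(drop(X %*% beta_true)))
    sqrt(mean((fit_quasi_poisson(y, X)$coefficients - beta_true)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("lag reduction matches the triple-loop oracle and scalar case", {
  set.seed(41)
  x <- rnorm(300, 15, 6)
  spec <- cross_basis_spec(
    spline_spec(percentile_knots(x, c(10, 75, 90)), range(x)),
    spline_spec(log_spaced_lag_knots(21, 3), c(0, 21), TRUE),
    max_lag = 21L
  )
  cb <- build_cross_basis(x, spec)
  beta <- rnorm(20, 0, 0.01)
  fit <- structure(list(beta = beta, vbeta = diag(1e-6, 20), converged = TRUE),
                   class = "first_stage_fit")
  curve <- reduce_over_lags(fit, cb)
  expect_length(curve$theta, 4L)

  # theta' f(x) == triple loop over (j, k, l) at random temperatures
  for (xx in runif(20, min(x), max(x))) {
    direct <- 0
    for (j in 1:4) {
      for (k in 1:5) {
        for (l in 0:21) {
          direct <- direct +
            natural_cubic_basis(xx, spec$temp_spline)[1, j] *
            natural_cubic_basis(l, spec$lag_spline)[1, k] *
            beta[(j - 1) * 5 + k]
        }
      }
    }
    expect_equal(cumulative_curve(curve, xx), direct, tolerance = 1e-10)
  }

  # V(theta) = M1 V(beta) M1'
  csum <- colSums(cb$lag_basis_matrix)
  M1 <- kronecker(diag(4), matrix(csum, 1))
  expect_equal(curve$vtheta, M1 %*% diag(1e-6, 20) %*% t(M1),
               tolerance = 1e-12)

  # scalar Kronecker case vx = vl = 1 reduces to beta * sum_l C_l1
  spec1 <- cross_basis_spec(
    spline_spec(15, range(x)),   # vx = 2 is the minimum; use theta length 2
    spline_spec(sqrt(5), c(0, 5), TRUE),
    max_lag = 5L
  )
  cb1 <- build_cross_basis(x, spec1)
  b1 <- rnorm(2 * 3)
  f1 <- structure(list(beta = b1, vbeta = diag(6)), class = "first_stage_fit")
  r1 <- reduce_over_lags(f1, cb1)
  cs <- colSums(cb1$lag_basis_matrix)
  expect_equal(r1$theta,
               drop(kronecker(diag(2), matrix(cs, 1)) %*% b1),
               tolerance = 1e-12)

  expect_error(reduce_over_lags(structure(list(beta = 1:5), class = "first_stage_fit"), cb),
               "does not match")
})

test_that("cumulative curve is flat for zero theta and intercept-free", {
  spec <- spline_spec(c(10, 15, 20), c(0, 30))
  curve <- structure(list(theta = rep(0, 4), vtheta = diag(0, 4),
                          temp_basis = spec, temp_range = c(0, 30)),
                     class = "reduced_curve")
  expect_equal(cumulative_curve(curve, seq(1, 29)), rep(0, 29))
})

test_that("MMT point estimate: quadratic vertex, zero-noise se, boundary argmin", {
  set.seed(51)
  temps <- rnorm(2000, 20, 6)
  bk <- range(temps)
  spec <- spline_spec(seq(bk[1] + 2, bk[2] - 2, length.out = 8), bk)
  grid_fit <- seq(bk[1], bk[2], by = 0.05)
  B <- natural_cubic_basis(grid_fit, spec)

  # project an exact quadratic with vertex 20.0 onto a rich spline basis
  target <- 0.004 * (grid_fit - 20)^2
  theta <- qr.solve(cbind(1, B), target)[-1]
  curve <- structure(list(theta = theta, vtheta = diag(0, length(theta)),
                          temp_basis = spec, temp_range = bk),
                     class = "reduced_curve")
  est <- estimate_mmt(curve, temps, n_sim = 200, seed = 9)
  expect_lt(abs(est$mmt - 20), 0.1 + 1e-9)
  expect_equal(est$se, 0)           # V(theta) = 0: all draws identical
  expect_equal(length(est$samples), 200L)

  # strictly decreasing curve: argmin at the upper window edge (P99)
  target_dec <- -0.05 * grid_fit
  theta_dec <- qr.solve(cbind(1, B), target_dec)[-1]
  curve_dec <- structure(list(theta = theta_dec,
                              vtheta = diag(0, length(theta_dec)),
                              temp_basis = spec, temp_range = bk),
                         class = "reduced_curve")
  est_dec <- estimate_mmt(curve_dec, temps, n_sim = 50, seed = 9)
  p99 <- unname(quantile(temps, 0.99))
  expect_lt(abs(est_dec$mmt - p99), 0.1 + 1e-9)
  expect_equal(est_dec$mmtp, mmt_to_percentile(est_dec$mmt, temps))

  # search window containment
  expect_gte(est$mmt, est$search_range[1])
  expect_lte(est$mmt, est$search_range[2])
})

test_that("Monte-Carlo se matches a numeric delta-method oracle", {
  set.seed(61)
  temps <- rnorm(3000, 20, 6)
  bk <- range(temps)
  spec <- spline_spec(seq(bk[1] + 2, bk[2] - 2, length.out = 8), bk)
  grid_fit <- seq(bk[1], bk[2], by = 0.05)
  B <- natural_cubic_basis(grid_fit, spec)
  theta <- qr.solve(cbind(1, B), 0.004 * (grid_fit - 20)^2)[-1]
  k <- length(theta)
  V <- diag(1e-6, k)

  curve <- structure(list(theta = theta, vtheta = V,
                          temp_basis = spec, temp_range = bk),
                     class = "reduced_curve")
  # numeric delta method: gradient of the continuous argmin wrt theta,
  # located by smooth minimization rather than a grid
  lims <- quantile(temps, c(0.25, 0.99))
  argmin_of <- function(th) {
    f <- function(xx) drop(natural_cubic_basis(xx, spec) %*% th)
    stats::optimize(f, lower = lims[1], upper = lims[2], tol = 1e-9)$minimum
  }
  grad <- vapply(seq_len(k), function(i) {
    h <- 1e-4
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (argmin_of(tp) - argmin_of(tm)) / (2 * h)
  }, numeric(1))
  sd_delta <- sqrt(drop(t(grad) %*% V %*% grad))

  ses <- vapply(1:20, function(s) {
    estimate_mmt(curve, temps, n_sim = 400, seed = s, grid_step = 0.001)$se
  }, numeric(1))
  expect_lt(abs(mean(ses) - sd_delta) / sd_delta, 0.10)
})

test_that("MMT Monte-Carlo draws are deterministic under a fixed seed", {
  set.seed(71)
  temps <- rnorm(1500, 18, 7)
  d <- tiny_series(years = 5, seed = 3)
  spec <- default_cross_basis_spec(d$tmean)
  cb <- build_cross_basis(d$tmean, spec)
  ctrl <- build_control_design(d$date)
  design <- cbind(1, ctrl$seasonal, ctrl$dow, cb$matrix)
  cbc <- seq.int(ncol(design) - 19L, ncol(design))
  fit <- fit_quasi_poisson(d$deaths, design, cb$valid_rows, cbc)
  curve <- reduce_over_lags(fit, cb)
  e1 <- estimate_mmt(curve, d$tmean, n_sim = 300, seed = 123)
  e2 <- estimate_mmt(curve, d$tmean, n_sim = 300, seed = 123)
  e3 <- estimate_mmt(curve, d$tmean, n_sim = 300, seed = 124)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$se, e2$se)
  expect_false(identical(e1$samples, e3$samples))
  expect_gt(e1$se, 0)
})

test_that("MMT percentile conversion agrees with a counting oracle", {
  set.seed(81)
  temps <- rnorm(750, 15, 8)
  expect_equal(mmt_to_percentile(max(temps), temps), 100)
  expect_equal(mmt_to_percentile(sort(temps)[375], temps), 50)
  for (m in sample(temps, 5)) {
    expect_equal(mmt_to_percentile(m, temps),
                 100 * sum(sort(temps) <= m) / length(temps))
  }
  x <- 1:100
  expect_equal(mmt_to_percentile(50, x), 50)
})

test_that("run_first_stage emits one record pair per usable unit with AT/TAT", {
  spec <- truth_spec(n_countries = 2, communities_per_country = 2,
                     years = 10, start_year = 2006, seed = 5)
  sim <- simulate_dataset(spec)
  rec <- run_first_stage(sim$data, start_year = 2006, end_year = 2015,
                         n_sim = 100, seed = 2)
  expect_equal(nrow(rec), 4 * 2 * 2)   # 4 communities x 2 subperiods x 2 metrics
  expect_setequal(unique(rec$metric), c("MMT", "MMTP"))

  # AT equals the direct mean of the subperiod's temperatures
  d <- sim$data[sim$data$community_id == "c01_01", ]
  yr <- as.integer(format(d$date, "%Y"))
  expect_equal(rec$AT[rec$community_id == "c01_01" & rec$w == 1][1],
               mean(d$tmean[yr <= 2010]), tolerance = 1e-12)
  # TAT is the across-subperiod mean of AT
  at <- unique(rec[rec$community_id == "c01_01", c("w", "AT")])
  expect_equal(rec$TAT[rec$community_id == "c01_01"][1], mean(at$AT),
               tolerance = 1e-12)

  # a community observed only from 2011 contributes only late subperiods
  cut <- sim$data[!(sim$data$community_id == "c01_01" &
                      sim$data$date < as.Date("2011-01-01")), ]
  rec2 <- run_first_stage(cut, start_year = 2006, end_year = 2015,
                          n_sim = 50, seed = 2)
  expect_equal(sort(unique(rec2$w[rec2$community_id == "c01_01"])), 2L)

  # failures are explicit rows, not silent drops
  tiny <- sim$data[sim$data$community_id != "c01_01" |
                     sim$data$date < as.Date("2006-06-01"), ]
  rec3 <- run_first_stage(tiny, start_year = 2006, end_year = 2015,
                          n_sim = 50, seed = 2)
  r3 <- rec3[rec3$community_id == "c01_01" & rec3$w == 1, ]
  expect_true(all(!r3$converged))
  expect_true(all(is.na(r3$estimate)))
})
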