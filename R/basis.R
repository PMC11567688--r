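#' Specify a natural cubic spline basis
#'
#' A `spline_spec` fixes the internal and boundary knots of a natural cubic
#' spline (cubic between knots, linear beyond the boundary knots) and whether
#' the basis carries an intercept column. The basis dimension is
#' `length(internal_knots) + 1 + with_intercept`.
#'
#' @param internal_knots Numeric vector of strictly increasing internal knots
#'   (degrees Celsius for the temperature dimension, days for the lag
#'   dimension).
#' @param boundary_knots Numeric length-2 vector; both internal knots must lie
#'   strictly inside this interval.
#' @param with_intercept Logical; include an intercept column in the basis.
#'
#' @return An object of class `spline_spec`.
#' @export
#' @examples
#' spline_spec(c(10, 18, 24), boundary_knots = c(-5, 35))
spline_spec <- function(internal_knots, boundary_knots, with_intercept = FALSE) {
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0) {
    stop("`boundary_knots` must be two increasing values", call. = FALSE)
  }
  if (length(internal_knots) > 0L) {
    if (anyNA(internal_knots) || is.unsorted(internal_knots, strictly = TRUE)) {
      stop("internal knots must be strictly increasing", call. = FALSE)
    }
    if (min(internal_knots) <= boundary_knots[1] ||
        max(internal_knots) >= boundary_knots[2]) {
      stop("internal knots must lie strictly inside the boundary knots",
           call. = FALSE)
    }
  }
  structure(
    list(internal_knots = internal_knots,
         boundary_knots = boundary_knots,
         with_intercept = isTRUE(with_intercept)),
    class = "spline_spec"
  )
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Natural cubic spline spec:", spline_dim(x), "columns;",
      length(x$internal_knots), "internal knots at",
      paste(signif(x$internal_knots, 4), collapse = ", "),
      "; boundary", paste(signif(x$boundary_knots, 4), collapse = " / "),
      if (x$with_intercept) "(with intercept)" else "", "\n")
  invisible(x)
}

#' Dimension of a spline basis
#' @param spec A [spline_spec()].
#' @return Integer number of basis columns.
#' @export
spline_dim <- function(spec) {
  length(spec$internal_knots) + 1L + as.integer(spec$with_intercept)
}

#' Evaluate a natural cubic spline basis
#'
#' Evaluates the natural cubic spline basis defined by `spec` at `x`. The
#' basis spans the space of cubic splines on the given knots whose second
#' derivative vanishes at and beyond the boundary knots, so evaluation
#' outside the boundary knots extrapolates linearly.
#'
#' @param x Numeric vector (may contain `NA`; those rows are `NA`).
#' @param spec A [spline_spec()].
#' @return A `length(x) x spline_dim(spec)` matrix.
#' @export
natural_cubic_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  n <- length(x)
  dim <- spline_dim(spec)
  out <- matrix(NA_real_, n, dim)
  ok <- !is.na(x)
  if (any(ok)) {
    b <- splines::ns(x[ok], knots = spec$internal_knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = FALSE)
    # an intercept-carrying basis keeps an explicit constant column; the
    # span equals the full natural-spline space either way
    out[ok, ] <- if (spec$with_intercept) cbind(1, b) else b
  }
  out
}

#' Internal lag knots equally spaced on the log scale
#'
#' Places `n_knots` interior knots at equal spacings on `(0, log(max_lag)]`,
#' i.e. `exp(i * log(max_lag) / (n_knots + 1))` for `i = 1..n_knots`. This is
#' the conventional placement for a lag-dimension spline over lags
#' `0..max_lag`.
#'
#' @param max_lag Maximum lag in days (`L`), at least 1.
#' @param n_knots Number of internal knots.
#' @return Strictly increasing numeric vector inside `(1, max_lag)`.
#' @export
#' @examples
#' log_spaced_lag_knots(21, 3) # ~ 2.14, 4.58, 9.81
log_spaced_lag_knots <- function(max_lag, n_knots) {
  stopifnot(max_lag >= 1, n_knots >= 1)
  if (n_knots >= max_lag) {
    stop("`n_knots` must be smaller than `max_lag`", call. = FALSE)
  }
  exp(seq_len(n_knots) * log(max_lag) / (n_knots + 1))
}

#' Knots at percentiles of an observed temperature distribution
#'
#' Empirical quantiles of the non-missing values, linearly interpolated
#' between order statistics (`stats::quantile` type 7).
#'
#' @param temps Numeric vector of temperatures (missing allowed).
#' @param percentiles Percentile positions in (0, 100).
#' @return Numeric vector of knots in the order requested.
#' @export
percentile_knots <- function(temps, percentiles = c(10, 75, 90)) {
  temps <- temps[!is.na(temps)]
  if (length(temps) < 2L) {
    stop("need at least 2 non-missing temperatures to place knots",
         call. = FALSE)
  }
  stopifnot(all(percentiles > 0), all(percentiles < 100))
  unname(stats::quantile(temps, percentiles / 100, type = 7))
}

#' Specify a DLNM cross-basis
#'
#' Combines a temperature spline (`vx` columns, no intercept), a lag spline
#' (`vl` columns, with intercept) and a maximum lag `L` into the
#' specification of an `N x (vx * vl)` cross-basis.
#'
#' @param temp_spline [spline_spec()] for the temperature dimension
#'   (must not carry an intercept).
#' @param lag_spline [spline_spec()] for the lag dimension (typically with
#'   an intercept, knots inside `(0, max_lag)`).
#' @param max_lag Integer maximum lag in days.
#' @return An object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(temp_spline, lag_spline, max_lag = 21L) {
  stopifnot(inherits(temp_spline, "spline_spec"),
            inherits(lag_spline, "spline_spec"),
            max_lag >= 0)
  if (temp_spline$with_intercept) {
    stop("the temperature spline must not carry an intercept", call. = FALSE)
  }
  vx <- spline_dim(temp_spline)
  vl <- spline_dim(lag_spline)
  if (vx < 2L) stop("temperature basis dimension must be >= 2", call. = FALSE)
  structure(
    list(temp_spline = temp_spline, lag_spline = lag_spline,
         max_lag = as.integer(max_lag), vx = vx, vl = vl),
    class = "cross_basis_spec"
  )
}

#' Cross-basis spec with the standard analysis choices
#'
#' Temperature: natural cubic spline with internal knots at the 10th, 75th
#' and 90th percentiles of the observed series, boundary knots at the
#' observed range (`vx = 4`). Lag: natural cubic spline with intercept and 3
#' internal knots equally spaced on the log-lag scale over lags 0..21
#' (`vl = 5`).
#'
#' @param temps Observed daily mean temperatures for the series to model.
#' @param temp_percentiles Percentiles for the temperature knots.
#' @param max_lag Maximum lag in days.
#' @param n_lag_knots Number of internal log-spaced lag knots.
#' @return A [cross_basis_spec()].
#' @export
default_cross_basis_spec <- function(temps,
                                     temp_percentiles = c(10, 75, 90),
                                     max_lag = 21L,
                                     n_lag_knots = 3L) {
  temps_ok <- temps[!is.na(temps)]
  knots <- percentile_knots(temps_ok, temp_percentiles)
  if (anyDuplicated(knots) || any(diff(knots) <= 0)) {
    stop("degenerate temperature knots: percentiles coincide", call. = FALSE)
  }
  bk <- range(temps_ok)
  if (knots[1] <= bk[1] || knots[length(knots)] >= bk[2]) {
    stop("degenerate temperature knots: knot at or beyond the observed range",
         call. = FALSE)
  }
  cross_basis_spec(
    temp_spline = spline_spec(knots, bk, with_intercept = FALSE),
    lag_spline = spline_spec(log_spaced_lag_knots(max_lag, n_lag_knots),
                             boundary_knots = c(0, max_lag),
                             with_intercept = TRUE),
    max_lag = max_lag
  )
}

#' Build the DLNM cross-basis for a daily temperature series
#'
#' Row `t`, column `(j, k)` of the cross-basis equals
#' `sum_{l=0..L} f_j(x[t-l]) * g_k(l)`, where `f` is the temperature basis
#' and `g` the lag basis. Columns are ordered with the lag index `k` varying
#' fastest within each temperature index `j`. Rows within the first `L` days
#' of the series, or with any missing lagged temperature, are flagged
#' invalid and set to `NA`.
#'
#' @param x Daily mean temperature vector (consecutive days).
#' @param spec A [cross_basis_spec()].
#' @return An object of class `cross_basis` with elements `matrix`
#'   (`N x (vx*vl)`), `lag_basis_matrix` (`(L+1) x vl`, the matrix `C`),
#'   `spec`, and `valid_rows` (logical length `N`).
#' @export
build_cross_basis <- function(x, spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  n <- length(x)
  L <- spec$max_lag
  if (n <= L) stop("series length must exceed the maximum lag", call. = FALSE)
  vx <- spec$vx
  vl <- spec$vl
  C <- natural_cubic_basis(0:L, spec$lag_spline)

  Fx <- natural_cubic_basis(x, spec$temp_spline) # N x vx, NA where x missing
  Q <- matrix(0, n, vx * vl)
  valid <- rep(TRUE, n)
  valid[seq_len(min(L, n))] <- FALSE
  jidx <- rep(seq_len(vx), each = vl)
  kidx <- rep(seq_len(vl), times = vx)
  for (l in 0:L) {
    Fl <- rbind(matrix(NA_real_, l, vx),
                Fx[seq_len(n - l), , drop = FALSE])
    valid <- valid & !is.na(Fl[, 1])
    Fl[is.na(Fl)] <- 0
    # column (j,k) at index (j-1)*vl + k accumulates f_j(x_{t-l}) g_k(l)
    Q <- Q + Fl[, jidx, drop = FALSE] *
      matrix(C[l + 1L, kidx], n, vx * vl, byrow = TRUE)
  }
  Q[!valid, ] <- NA_real_
  colnames(Q) <- paste0("cb_", rep(seq_len(vx), each = vl), "_",
                        rep(seq_len(vl), vx))
  structure(
    list(matrix = Q, lag_basis_matrix = C, spec = spec, valid_rows = valid),
    class = "cross_basis"
  )
}

#' @export
print.cross_basis <- function(x, ...) {
  cat("DLNM cross-basis:", nrow(x$matrix), "days x", ncol(x$matrix),
      "columns (vx =", x$spec$vx, ", vl =", x$spec$vl, ", L =",
      x$spec$max_lag, ");", sum(x$valid_rows), "valid rows\n")
  invisible(x)
}
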