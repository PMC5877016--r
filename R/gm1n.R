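#' Build the grey design system
#'
#' Assembles the linear system behind the grey difference equation
#' `x1(k) + a*z(k) = sum_i b_i * (x1_i(k))^gamma_i`, for epochs `k = 2..n`:
#' rows of `B` are `(-z(k), x1_2(k)^gamma_2, ..., x1_N(k)^gamma_N)` and `Y`
#' stacks the normalized system observations `x1(k)`. With all exponents at 1
#' this is the classical GM(1,N) design.
#'
#' @param prep A [prepare_dataset()] object.
#' @param gamma Driver exponents, one per driver (default all 1).
#' @return A list of class `grey_design` with matrix `B` (`n - 1` rows,
#'   `N` columns) and vector `Y` (`n - 1` entries).
#' @export
build_design <- function(prep, gamma = rep(1, prep$N - 1L)) {
  stopifnot(inherits(prep, "grey_prepared"))
  gamma <- as.numeric(gamma)
  if (length(gamma) != prep$N - 1L) {
    stop("need one exponent per driver (", prep$N - 1L, ")", call. = FALSE)
  }
  X <- driver_powers(prep$x1[-1L, , drop = FALSE], gamma)
  B <- cbind(-prep$z, X, deparse.level = 0)
  colnames(B) <- c("z", prep$driver_names)
  structure(list(B = B, Y = prep$y0[-1L], gamma = gamma),
            class = "grey_design")
}

# Element-wise driver powers with the domain guards fractional exponents
# need: a negative base is an error under a non-integer exponent, a zero
# base yields 0 for gamma > 0 and errors for gamma <= 0.
driver_powers <- function(x1, gamma) {
  for (j in seq_along(gamma)) {
    g <- gamma[j]
    if (g != round(g) && any(x1[, j] < 0)) {
      stop("negative accumulated driver in column ", j,
           " with fractional exponent ", g, call. = FALSE)
    }
    if (g <= 0 && any(x1[, j] == 0)) {
      stop("zero accumulated driver in column ", j,
           " with exponent <= 0", call. = FALSE)
    }
  }
  out <- vapply(seq_along(gamma), function(j) x1[, j]^gamma[j],
                numeric(nrow(x1)))
  matrix(out, nrow = nrow(x1))
}

#' Least-squares estimation of the grey parameter vector
#'
#' Solves `Y = B alpha` for `alpha = (a, b_2, ..., b_N)` covering the three
#' rank cases: an overdetermined system is solved by stable least squares
#' (QR), a square non-singular system exactly, and an underdetermined system
#' by the minimum-norm solution `pinv(B) Y` (computed by SVD). In every case
#' the returned vector minimizes `||Y - B alpha||` and, among minimizers of
#' an underdetermined system, has minimal norm.
#'
#' @param design A [build_design()] object, or a list with elements `B`, `Y`.
#' @param cond_warn Warn when the condition number of `B` exceeds this
#'   threshold (default `1e8`).
#' @return Named numeric vector `c(a, b2, ...)`; attribute `"condition"`
#'   carries the condition number of `B`.
#' @export
ols_estimate <- function(design, cond_warn = 1e8) {
  B <- design$B
  Y <- as.numeric(design$Y)
  m <- nrow(B); p <- ncol(B)
  if (!m) stop("empty design", call. = FALSE)
  sv <- svd(B, nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (m >= p) {
    qrB <- qr(B, tol = 1e-12)
    if (qrB$rank < p) {
      stop("rank-deficient design (rank ", qrB$rank, " < ", p,
           ", condition number ", format(cond, digits = 3), ")",
           call. = FALSE)
    }
    alpha <- qr.coef(qrB, Y)
  } else {
    alpha <- lls_min_norm(B, Y)
  }
  if (is.finite(cond) && cond > cond_warn) {
    warning("ill-conditioned design: condition number ",
            format(cond, digits = 3), call. = FALSE)
  }
  names(alpha) <- c("a", paste0("b", seq_len(p - 1L) + 1L))
  attr(alpha, "condition") <- cond
  alpha
}

# Minimum-norm least-squares solution via the SVD pseudoinverse; defined for
# any shape and rank.
lls_min_norm <- function(B, Y) {
  s <- svd(B)
  tol <- max(dim(B)) * .Machine$double.eps * s$d[1]
  keep <- s$d > tol
  drop(s$v[, keep, drop = FALSE] %*%
         ((t(s$u[, keep, drop = FALSE]) %*% Y) / s$d[keep]))
}

# In-sample fitted values by the grey difference equation with actual
# background values: fitted(k) = -a z(k) + sum_i b_i x1_i(k)^gamma_i for
# k = 2..n; the base epoch is pinned to the observed value (error 0).
difference_fit <- function(prep, a, b, gamma) {
  X <- driver_powers(prep$x1[-1L, , drop = FALSE], gamma)
  c(prep$y0[1L], -a * prep$z + drop(X %*% b))
}

new_grey_fit <- function(model, prep, a, b, gamma, diagnostics = list()) {
  fitted <- difference_fit(prep, a, b, gamma)
  errors <- percentage_errors(prep$y0, fitted)
  structure(list(
    model = model,
    system_name = prep$system_name,
    driver_names = prep$driver_names,
    epochs = prep$epochs, n = prep$n, N = prep$N,
    params = list(a = a, b = stats::setNames(b, prep$driver_names),
                  gamma = stats::setNames(gamma, prep$driver_names)),
    actual = prep$y0,
    fitted = fitted,
    errors_pct = errors,
    mape = mape(errors, "exclude_base"),
    mape_include_base = mape(errors, "include_base"),
    diagnostics = diagnostics,
    prep = prep
  ), class = "grey_fit")
}

#' Fit the linear GM(1,N) model
#'
#' Estimates the development coefficient `a` and driving coefficients
#' `b_2..b_N` of the grey multivariate difference equation
#' `x1(k) + a z(k) = sum_i b_i x1_i(k)` by least squares, and evaluates the
#' in-sample fit. In-sample fitted values use the difference equation with
#' actual background values (the convention that reproduces published grey
#' fitting tables); the whitening-equation recursion is available separately
#' through [time_response()] for genuine out-of-sample forecasting.
#'
#' @param prep A [prepare_dataset()] object.
#' @return A `grey_fit` object: parameters, fitted series (base epoch pinned
#'   to the observed value), signed percentage errors, and MAPE under both
#'   denominator conventions.
#' @examples
#' cp <- china_pollutants()
#' prep <- prepare_dataset(
#'   grey_series(cp$wdpc, cp$year, name = "wdpc"),
#'   grey_series(cp$gdp_per_capita, cp$year, name = "gdp"))
#' fit <- gm1n_fit(prep)
#' coef(fit)        # a = -0.1971, b2 = -0.04553
#' fit$mape         # 20.80 (%)
#' @export
gm1n_fit <- function(prep) {
  stopifnot(inherits(prep, "grey_prepared"))
  gamma <- rep(1, prep$N - 1L)
  alpha <- ols_estimate(build_design(prep, gamma))
  new_grey_fit("gm1n", prep, a = alpha[[1L]], b = alpha[-1L], gamma = gamma,
               diagnostics = list(method = "ols",
                                  condition = attr(alpha, "condition")))
}

#' Fitted values for given parameters
#'
#' Evaluates the in-sample difference-equation fit for an externally supplied
#' parameter set (e.g. published coefficients), without re-estimating.
#'
#' @param prep A [prepare_dataset()] object.
#' @param a Development coefficient.
#' @param b Driving coefficients (one per driver).
#' @param gamma Driver exponents (default all 1, the linear model).
#' @return A `grey_fit` object.
#' @export
grey_eval <- function(prep, a, b, gamma = rep(1, prep$N - 1L)) {
  stopifnot(inherits(prep, "grey_prepared"))
  model <- if (all(gamma == 1)) "gm1n" else "tngm1n"
  new_grey_fit(model, prep, a = a, b = as.numeric(b),
               gamma = as.numeric(gamma),
               diagnostics = list(method = "fixed"))
}

#' Approximate time response (out-of-sample recursion)
#'
#' The grey-constant approximation of the whitening equation's solution:
#' `x1hat(k + 1) = (x1_init - S(k + 1) / a) * exp(-a k) + S(k + 1) / a`
#' where `S(k) = sum_i b_i (x1_i(k))^gamma_i` and `x1_init` plays the role of
#' the accumulated series' first value. This is the genuine forecasting mode:
#' it uses only the initial system value and the (accumulated) driver paths,
#' never the observed system series.
#'
#' @param a Development coefficient; must be non-zero (the closed form
#'   degenerates at `a = 0`).
#' @param b Driving coefficients.
#' @param driver_acc Matrix of accumulated driver values, one row per epoch
#'   `1..H`, one column per driver (row 1 is the base epoch).
#' @param gamma Driver exponents (default all 1).
#' @param x1_init Accumulated system value at the base epoch (default 1, the
#'   value after first-value initialization).
#' @return Numeric vector of accumulated forecasts for epochs `1..H`, with
#'   element 1 equal to `x1_init`; apply [iago()] for level forecasts.
#' @examples
#' # pure exponential decay when all driving coefficients vanish
#' time_response(a = 0.5, b = 0, driver_acc = matrix(1:5, ncol = 1))
#' @export
time_response <- function(a, b, driver_acc, gamma = rep(1, length(b)),
                          x1_init = 1) {
  if (a == 0) stop("degenerate model: a = 0 has no exponential time response",
                   call. = FALSE)
  driver_acc <- as.matrix(driver_acc)
  b <- as.numeric(b); gamma <- as.numeric(gamma)
  stopifnot(ncol(driver_acc) == length(b), length(gamma) == length(b))
  H <- nrow(driver_acc)
  out <- numeric(H)
  out[1L] <- x1_init
  if (H > 1L) {
    S <- drop(driver_powers(driver_acc[-1L, , drop = FALSE], gamma) %*% b)
    k <- seq_len(H - 1L)
    out[-1L] <- (x1_init - S / a) * exp(-a * k) + S / a
  }
  out
}

#' Forecast with a fitted grey model
#'
#' Runs the time-response recursion of a `grey_fit` over the sample epochs
#' and, optionally, beyond them. Future driver values must be supplied
#' explicitly (in original units); nothing is extrapolated implicitly --
#' use [extrapolate_driver()] if a driver trend fit is wanted.
#'
#' @param fit A `grey_fit`.
#' @param driver_future Matrix (or vector for one driver) of future raw
#'   driver values, one row per forecast epoch beyond the sample; `NULL` for
#'   in-sample reconstruction only.
#' @param normalize_future Apply the stored normalization bases to
#'   `driver_future` (default `TRUE`; set `FALSE` if already normalized).
#' @return A data frame with columns `epoch`, `accumulated`, `level`, and
#'   `in_sample` (logical); levels are on the normalized scale, column
#'   `level_raw` restores original units.
#' @export
grey_forecast <- function(fit, driver_future = NULL, normalize_future = TRUE) {
  stopifnot(inherits(fit, "grey_fit"))
  prep <- fit$prep
  x1 <- prep$x1
  h <- 0L
  if (!is.null(driver_future)) {
    driver_future <- as.matrix(driver_future)
    if (ncol(driver_future) != prep$N - 1L) {
      stop("driver_future needs one column per driver", call. = FALSE)
    }
    if (normalize_future) {
      driver_future <- sweep(driver_future, 2L, prep$x_bases, "/")
    }
    h <- nrow(driver_future)
    last <- x1[prep$n, ]
    fut_acc <- apply(driver_future, 2L, cumsum)
    fut_acc <- sweep(matrix(fut_acc, nrow = h), 2L, last, "+")
    x1 <- rbind(x1, fut_acc)
  }
  acc <- time_response(fit$params$a, fit$params$b, x1,
                       gamma = fit$params$gamma, x1_init = prep$y0[1L])
  step <- prep$epochs[2L] - prep$epochs[1L]
  epochs <- c(prep$epochs,
              if (h > 0L) prep$epochs[prep$n] + step * seq_len(h))
  lev <- iago(acc)
  data.frame(epoch = epochs, accumulated = acc, level = lev,
             level_raw = lev * prep$y_base,
             in_sample = epochs <= prep$epochs[prep$n])
}

#' Exponential trend extrapolation for a driver series
#'
#' Optional helper for forecasting when future driver values are unknown:
#' fits a univariate grey exponential (GM(1,1)-style) to the driver and
#' returns the next `h` raw values. Use deliberately -- forecasts are only
#' as good as this trend assumption.
#'
#' @param x A `grey_series` (the raw driver).
#' @param h Number of future values.
#' @return Numeric vector of length `h` in the driver's original units.
#' @export
extrapolate_driver <- function(x, h) {
  stopifnot(inherits(x, "grey_series"), h >= 1)
  v <- x$values
  n <- length(v)
  x1 <- cumsum(v)
  z <- background_values(x1)
  alpha <- ols_estimate(list(B = cbind(-z, 1), Y = v[-1L]))
  a <- alpha[[1L]]; u <- alpha[[2L]]
  k <- seq(n, n + h - 1L)
  acc <- (v[1L] - u / a) * exp(-a * k) + u / a
  diff(c(x1[n], acc))
}

#' @export
print.grey_fit <- function(x, digits = 6, ...) {
  lab <- c(gm1n = "GM(1,N)", tngm1n = "NLS-TNGM(1,N)")[x$model]
  cat("<grey_fit> ", lab, " for '", x$system_name, "' on driver(s) ",
      paste(x$driver_names, collapse = ", "), "\n", sep = "")
  cat("  a  = ", format(x$params$a, digits = digits), "\n", sep = "")
  for (i in seq_along(x$params$b)) {
    cat("  b", i + 1L, " = ", format(x$params$b[[i]], digits = digits),
        if (x$model == "tngm1n") paste0("   gamma", i + 1L, " = ",
                                        format(x$params$gamma[[i]],
                                               digits = digits)),
        "\n", sep = "")
  }
  cat("  MAPE = ", format(x$mape, digits = 4),
      "% (epochs 2..n), ", format(x$mape_include_base, digits = 4),
      "% (incl. base)\n", sep = "")
  if (!is.null(x$diagnostics$converged)) {
    cat("  NLS: ", x$diagnostics$iterations, " iterations, ",
        if (x$diagnostics$converged) "converged" else "NOT converged",
        ", objective ", format(x$diagnostics$objective, digits = 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.grey_fit <- function(object, ...) {
  p <- object$params
  out <- c(a = p$a, p$b)
  names(out) <- c("a", paste0("b", seq_along(p$b) + 1L))
  if (object$model == "tngm1n") {
    g <- p$gamma
    names(g) <- paste0("gamma", seq_along(g) + 1L)
    out <- c(out, g)
  }
  out
}

#' @export
fitted.grey_fit <- function(object, ...) {
  stats::setNames(object$fitted, object$epochs)
}

#' @export
residuals.grey_fit <- function(object, ...) {
  stats::setNames(object$actual - object$fitted, object$epochs)
}
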