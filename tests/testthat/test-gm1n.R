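test_that("the design system stacks background and accumulated drivers", {
  prep <- china_prep("wdpc")
  des <- build_design(prep)
  expect_equal(dim(des$B), c(19L, 2L))
  expect_equal(length(des$Y), 19L)
  # first row, recomputed by hand from the raw 1996/1997 observations
  w <- c(32.2193, 33.6343)
  g <- c(5539.01, 6375.74)
  expect_equal(des$B[1, 1], -0.5 * (1 + (1 + w[2] / w[1])),
               ignore_attr = TRUE)
  expect_equal(des$B[1, 2], 1 + g[2] / g[1], ignore_attr = TRUE)
  expect_equal(des$Y[1], w[2] / w[1])
  # exponent 0 turns the driver column into ones; exponent 1 is the default
  expect_equal(build_design(prep, gamma = 0)$B[, 2], rep(1, 19),
               ignore_attr = TRUE)
  expect_equal(build_design(prep, gamma = 1)$B, des$B)
  expect_error(build_design(prep, gamma = c(1, 2)), "one exponent per driver")
})

test_that("driver powers enforce the fractional-exponent domain", {
  prep <- china_prep("wdpc")
  fake <- prep
  fake$x1[3, 1] <- -1
  expect_error(build_design(fake, gamma = 0.5), "negative accumulated driver")
  expect_silent(build_design(fake, gamma = 2))   # integer powers are fine
  fake$x1[3, 1] <- 0
  expect_error(build_design(fake, gamma = -1), "exponent <= 0")
})

test_that("least squares covers the three rank cases", {
  # overdetermined, consistent: exact recovery
  set.seed(7)
  B <- matrix(rnorm(15), 5, 3)
  a0 <- c(0.4, -1.2, 2.5)
  est <- ols_estimate(list(B = B, Y = drop(B %*% a0)))
  expect_equal(as.numeric(est), a0, tolerance = 1e-10)

  # overdetermined, inconsistent: matches an independent normal-equation solve
  Y <- drop(B %*% a0) + rnorm(5, 0, 0.3)
  est <- ols_estimate(list(B = B, Y = Y))
  oracle <- solve(t(B) %*% B, t(B) %*% Y)
  expect_equal(as.numeric(est), as.numeric(oracle), tolerance = 1e-8)
  # residuals orthogonal to the columns of B
  expect_lt(max(abs(t(B) %*% (Y - B %*% est))), 1e-8)

  # square case: direct solve
  Bs <- matrix(c(2, 1, 1, 3), 2, 2)
  Ys <- c(1, 2)
  expect_equal(as.numeric(ols_estimate(list(B = Bs, Y = Ys))),
               as.numeric(solve(Bs, Ys)))

  # underdetermined: minimum-norm solution, checked against MASS::ginv
  skip_if_not_installed("MASS")
  Bu <- matrix(rnorm(6), 2, 3)
  Yu <- c(1, -1)
  mn <- ols_estimate(list(B = Bu, Y = Yu))
  expect_equal(as.numeric(mn), as.numeric(MASS::ginv(Bu) %*% Yu),
               tolerance = 1e-10)
  expect_lt(max(abs(Bu %*% mn - Yu)), 1e-10)   # still a solution
  # any other solution has larger norm
  null_vec <- c(Bu[1, 2] * Bu[2, 3] - Bu[1, 3] * Bu[2, 2],
                Bu[1, 3] * Bu[2, 1] - Bu[1, 1] * Bu[2, 3],
                Bu[1, 1] * Bu[2, 2] - Bu[1, 2] * Bu[2, 1])
  expect_lt(sum(mn^2), sum((as.numeric(mn) + 0.1 * null_vec)^2))

  # rank deficiency raises with the condition number in the message
  Bd <- cbind(1:4, 2 * (1:4))
  expect_error(suppressWarnings(ols_estimate(list(B = Bd, Y = rep(1, 4)))),
               "rank-deficient")
  # ill-conditioning warns but still solves
  Bi <- cbind(rep(1, 4), c(1, 1, 1, 1 + 1e-10))
  expect_warning(ols_estimate(list(B = Bi, Y = c(1, 2, 3, 5))),
                 "ill-conditioned")
})

test_that("exact difference-equation data is recovered to round-off", {
  sim <- simulate_tngm(n = 14, a = -0.08, b = 0.9, gamma = 1, noise_sd = 0,
                       seed = 3)
  prep <- prepare_dataset(sim$system, sim$drivers)
  est <- ols_estimate(build_design(prep))
  expect_equal(as.numeric(est), c(-0.08, 0.9), tolerance = 1e-9)
})

test_that("in-sample fitted values follow the difference-equation convention", {
  fit <- china_gm("wdpc")
  expect_equal(fit$fitted[1], fit$actual[1])   # base epoch pinned
  expect_equal(fit$errors_pct[1], 0)
  # published spot values (2 decimals)
  expect_equal(round(fit$fitted[fit$epochs == 1998], 2), 0.35,
               ignore_attr = TRUE)
  expect_equal(round(fit$fitted[fit$epochs == 1999], 2), 0.49,
               ignore_attr = TRUE)
  # fitted values equal the design prediction row-wise
  des <- build_design(fit$prep)
  expect_equal(fit$fitted[-1],
               drop(des$B %*% c(fit$params$a, fit$params$b)),
               ignore_attr = TRUE)
  # zero parameters give zero fit beyond the base epoch
  zero <- grey_eval(china_prep("wdpc"), a = 0, b = 0)
  expect_equal(zero$fitted[-1], rep(0, 19), ignore_attr = TRUE)
})

test_that("the time response reduces to its closed forms", {
  expect_error(time_response(0, 1, matrix(1:3)), "degenerate")
  # horizon 0: only the initial value, for any parameters
  expect_equal(time_response(0.3, 2, matrix(5, 1, 1), x1_init = 1.7), 1.7)
  # vanishing driving coefficients: pure exponential decay
  acc <- time_response(0.5, 0, matrix(runif(6), 6, 1), x1_init = 2)
  expect_equal(acc, 2 * exp(-0.5 * (0:5)))
  # constant driver path at steady state keeps the trajectory constant:
  # x1_init = S / a is the fixed point
  a <- 0.4; b <- 1.2; s <- 3
  expect_equal(time_response(a, b, matrix(s, 5, 1), x1_init = b * s / a),
               rep(b * s / a, 5))
})

test_that("forecasting recursion reconstructs and extends the sample", {
  fit <- china_gm("wdpc")
  fc <- grey_forecast(fit)
  expect_equal(nrow(fc), 20L)
  expect_true(all(fc$in_sample))
  expect_equal(fc$accumulated[1], 1)
  expect_equal(fc$level, iago(fc$accumulated))
  expect_equal(fc$level_raw, fc$level * 32.2193)
  # the published response-equation constant: b2/a = 0.231
  expect_equal(round(fit$params$b[[1]] / fit$params$a, 3), 0.231)
  # holdout: refit on 1996-2012, feed actual 2013-2015 GDP as the future
  cp <- china_pollutants()
  tr <- 1:17
  prep <- prepare_dataset(
    grey_series(cp$wdpc[tr], cp$year[tr], name = "wdpc"),
    grey_series(cp$gdp_per_capita[tr], cp$year[tr], name = "gdp"))
  f2 <- gm1n_fit(prep)
  fc2 <- grey_forecast(f2, driver_future = cp$gdp_per_capita[18:20])
  expect_equal(fc2$epoch, 1996:2015)
  expect_equal(sum(!fc2$in_sample), 3L)
  expect_true(all(is.finite(fc2$level_raw)))
  # future drivers are mandatory when extending
  expect_error(
    grey_forecast(f2, driver_future = matrix(1, 2, 2)),
    "one column per driver")
})

test_that("driver extrapolation follows a grey exponential trend", {
  g <- grey_series(100 * 1.1^(0:9), 2001:2010, name = "g")
  ext <- extrapolate_driver(g, 3)
  expect_equal(length(ext), 3L)
  # the background-value discretization of the exponential carries a small
  # bias, so agreement with the true geometric path is approximate
  expect_equal(ext, 100 * 1.1^(10:12), tolerance = 0.02)
  expect_equal(ext[2] / ext[1], 1.1, tolerance = 0.01)
})
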