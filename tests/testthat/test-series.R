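test_that("grey_series validates its invariants", {
  expect_s3_class(grey_series(c(1, 2, 3, 4)), "grey_series")
  expect_error(grey_series(c(1, 2, 3)), "at least 4")
  expect_error(grey_series(c(1, NA, 3, 4)), "missing")
  expect_error(grey_series(c(1, -2, 3, 4)), "positive")
  expect_error(grey_series(c(1, Inf, 3, 4), positive = FALSE), "non-finite")
  expect_error(grey_series(1:4, epochs = c(1, 2, 4, 5)), "constant step")
  expect_error(grey_series(1:4, epochs = c(4, 3, 2, 1)), "constant step")
  # negative values allowed when positivity is waived
  expect_silent(grey_series(c(-1, 2, 3, 4), positive = FALSE))
})

test_that("initialization divides by the first value and is scale invariant", {
  wdpc <- china_pollutants()$wdpc
  ini <- initialize_series(wdpc)
  expect_equal(ini$base, 32.2193)
  expect_identical(ini$ratios[1], 1)
  # the 1997 ratio matches the published actual-value column (1.04)
  expect_equal(round(ini$ratios[2], 2), 1.04)
  expect_equal(ini$ratios[2], 33.6343 / 32.2193)
  expect_equal(ini$ratios * ini$base, wdpc)

  gdp <- c(5539.01, 6375.74, 7000, 8000)
  expect_equal(initialize_series(gdp)$ratios[2], 6375.74 / 5539.01)

  expect_equal(initialize_series(rep(3.7, 4))$ratios, rep(1, 4))

  for (s in 1:5) {
    set.seed(s)
    v <- runif(8, 1, 10)
    c0 <- runif(1, 0.1, 100)
    expect_equal(initialize_series(c0 * v)$ratios,
                 initialize_series(v)$ratios)
  }

  expect_equal(initialize_series(c(2, 4, 6), mode = "mean")$base, 4)
  expect_equal(initialize_series(c(2, 4, 6), mode = "none")$ratios, c(2, 4, 6))
  expect_error(initialize_series(c(0, 1, 2)), "positive")
  expect_error(initialize_series(c(-1, 1, 2)), "positive")
})

test_that("ago accumulates and iago inverts it exactly", {
  expect_equal(ago(c(1.00, 1.04, 1.01)), c(1.00, 2.04, 3.05))
  expect_equal(ago(5), 5)
  expect_equal(iago(c(1.00, 2.04, 3.05)), c(1.00, 1.04, 1.01))
  expect_equal(iago(5), 5)
  # accumulated initialized GDP at k = 2 equals 1 + x(2)/x(1)
  gdp <- china_pollutants()$gdp_per_capita
  expect_equal(ago(initialize_series(gdp))[2], 1 + 6375.74 / 5539.01)
  for (s in 1:20) {
    set.seed(s)
    v <- runif(20, 0.01, 50)
    expect_equal(iago(ago(v)), v)
    expect_equal(ago(iago(v)), v)
    expect_true(all(diff(ago(v)) > 0))   # increasing for positive source
  }
})

test_that("background values are nearest-neighbour means in both forms", {
  expect_equal(background_values(c(1.00, 2.04)), 1.52)
  expect_equal(background_values(c(3, 3)), 3)
  set.seed(42)
  x0 <- runif(12, 0.1, 5)
  x1 <- ago(x0)
  z <- background_values(x1)
  n <- length(x1)
  expect_equal(z, 0.5 * (x1[-1] + x1[-n]))
  # identity: z(k) = x1(k-1) + 0.5 x0(k)
  expect_equal(z, x1[-n] + 0.5 * x0[-1])
  expect_error(background_values(3.2), "at least 2")
})

test_that("mean substitution fills gaps with the observed mean", {
  filled <- mean_substitute(c(1, NA, 3))
  expect_equal(as.numeric(filled), c(1, 2, 3))
  expect_equal(attr(filled, "filled"), c(FALSE, TRUE, FALSE))
  expect_equal(as.numeric(mean_substitute(c(2, 5))), c(2, 5))
  expect_equal(as.numeric(mean_substitute(c(NA, 4))), c(4, 4))
  expect_error(mean_substitute(c(NA_real_, NA_real_)), "all values missing")
})

test_that("the packaged China dataset matches the published table", {
  cp <- china_pollutants()
  expect_equal(dim(cp), c(20L, 5L))
  expect_equal(cp$year, 1996:2015)
  expect_equal(cp$wdpc[cp$year == 1996], 32.2193)
  expect_equal(cp$gdp_per_capita[cp$year == 2015], 50223.99)
  expect_equal(cp$dust_per_capita[cp$year == 2014], 0.0127)
  expect_equal(cp$so2_per_capita[cp$year == 2005], 0.0195)
  # column checksums freeze the table digit for digit
  expect_equal(sum(cp$gdp_per_capita), 413121.98)
  expect_equal(sum(cp$wdpc), 817.3126)
  expect_equal(sum(cp$so2_per_capita), 0.3274)
  expect_equal(sum(cp$dust_per_capita), 0.1756)
})

test_that("series CSV round trip is stable at 15 significant digits", {
  cp <- china_pollutants()
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(cp, path)
  back <- read_series_csv(path)
  expect_equal(back, cp, tolerance = 1e-15)
  expect_error(read_series_csv(write_series_csv(
    data.frame(year = 1:3), withr::local_tempfile(fileext = ".csv"))),
    "at least one series")
})

test_that("prepare_dataset bundles system, drivers and backgrounds", {
  prep <- china_prep("wdpc")
  expect_s3_class(prep, "grey_prepared")
  expect_equal(prep$n, 20L)
  expect_equal(prep$N, 2L)
  expect_equal(prep$y0[1], 1)
  expect_equal(length(prep$z), 19L)
  expect_equal(prep$z, background_values(prep$y1))
  expect_equal(prep$x1[, 1], cumsum(prep$x0[, 1]), ignore_attr = TRUE)
  # epochs must agree across series
  expect_error(prepare_dataset(
    grey_series(1:5, 1:5), grey_series(1:5, 2:6)), "epochs")
  # models reject series containing missing markers at construction
  expect_error(prepare_dataset(
    grey_series(c(1, NA, 3, 4), 1:4), grey_series(1:4, 1:4)), "missing")
})
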