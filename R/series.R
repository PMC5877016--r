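#' Construct a grey observation series
#'
#' A `grey_series` is a short, equally spaced, strictly positive observation
#' sequence -- the basic input of every grey multivariate model. Grey models
#' are designed for small samples, so at least four observations are required
#' for a meaningful fit.
#'
#' @param values Numeric vector of observations; all finite. Must be strictly
#'   positive unless `positive = FALSE` (positivity is required whenever the
#'   series enters a model with fractional driver exponents).
#' @param epochs Integer vector of the same length as `values`, strictly
#'   increasing with a constant step (e.g. calendar years). Defaults to
#'   `1, 2, ..., n`.
#' @param name Text label for the series.
#' @param unit Text unit label (informational only).
#' @param positive Require strictly positive values (default `TRUE`).
#' @return An object of class `grey_series` with fields `name`, `epochs`,
#'   `values`, `unit`.
#' @examples
#' s <- grey_series(c(32.2, 33.6, 32.4, 32.6), epochs = 1996:1999, name = "wdpc")
#' s
#' @export
grey_series <- function(values, epochs = seq_along(values), name = "series",
                        unit = "", positive = TRUE) {
  values <- as.numeric(values)
  if (anyNA(values)) {
    stop("series '", name, "' contains missing values; fill them with ",
         "mean_substitute() before modelling", call. = FALSE)
  }
  if (length(values) < 4L) {
    stop("series '", name, "' has ", length(values),
         " observations; at least 4 are required for a grey fit",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("series '", name, "' contains non-finite values", call. = FALSE)
  }
  if (positive && any(values <= 0)) {
    stop("series '", name, "' must be strictly positive", call. = FALSE)
  }
  epochs <- as.integer(epochs)
  if (length(epochs) != length(values)) {
    stop("epochs and values differ in length", call. = FALSE)
  }
  steps <- diff(epochs)
  if (any(steps <= 0L) || length(unique(steps)) > 1L) {
    stop("epochs must be strictly increasing with a constant step",
         call. = FALSE)
  }
  structure(list(name = name, epochs = epochs, values = values, unit = unit),
            class = "grey_series")
}

#' @export
print.grey_series <- function(x, ...) {
  cat("<grey_series> ", x$name,
      if (nzchar(x$unit)) paste0(" [", x$unit, "]"), "\n", sep = "")
  cat("  epochs ", x$epochs[1], "..", x$epochs[length(x$epochs)],
      " (n = ", length(x$values), ")\n", sep = "")
  print(stats::setNames(x$values, x$epochs), ...)
  invisible(x)
}

series_values <- function(x) {
  if (inherits(x, "grey_series")) x$values else as.numeric(x)
}

#' Initialize (normalize) a series
#'
#' Grey multivariate designs are prone to numerical drift when the variables
#' live on very different scales, so raw series are normalized before
#' modelling. The default divides every observation by the first one, so the
#' transformed series starts at exactly 1; `"mean"` divides by the series
#' mean; `"none"` leaves the data untouched.
#'
#' @param x A `grey_series` or numeric vector with a positive first value.
#' @param mode One of `"first"` (default), `"mean"`, `"none"`.
#' @return A list of class `grey_initialized` with `base` (the divisor) and
#'   `ratios` (the normalized values). `ratios * base` reconstructs the raw
#'   series to round-off.
#' @examples
#' initialize_series(c(32.2193, 33.6343, 32.4432, 32.5936))$ratios
#' @export
initialize_series <- function(x, mode = c("first", "mean", "none")) {
  mode <- match.arg(mode)
  v <- series_values(x)
  if (length(v) == 0L) stop("empty series", call. = FALSE)
  base <- switch(mode,
    first = v[1],
    mean  = mean(v),
    none  = 1)
  if (!is.finite(base) || base <= 0) {
    stop("initialization base must be positive and finite (got ", base, ")",
         call. = FALSE)
  }
  structure(list(base = base, ratios = v / base, mode = mode),
            class = "grey_initialized")
}

#' First-order accumulated generating operation (1-AGO)
#'
#' The running cumulative sum of a series. Accumulation smooths short noisy
#' sequences and exposes the quasi-exponential structure that grey models
#' assume.
#'
#' @param x A `grey_series`, `grey_initialized` object, or numeric vector.
#' @return Numeric vector of the same length, `ago(x)[k] = sum(x[1:k])`.
#' @seealso [iago()] for the inverse operation.
#' @examples
#' ago(c(1.00, 1.04, 1.01))   # 1.00 2.04 3.05
#' @export
ago <- function(x) {
  v <- if (inherits(x, "grey_initialized")) x$ratios else series_values(x)
  if (length(v) == 0L) stop("empty series", call. = FALSE)
  cumsum(v)
}

#' Inverse accumulated generating operation (IAGO)
#'
#' First differences with the first element preserved, so that
#' `iago(ago(x))` reproduces `x` to round-off. Applied to an accumulated
#' forecast it recovers the level (per-epoch) forecast.
#'
#' @param x Numeric vector (an accumulated series).
#' @return Numeric vector of the same length.
#' @examples
#' iago(c(1.00, 2.04, 3.05))  # 1.00 1.04 1.01
#' @export
iago <- function(x) {
  v <- as.numeric(x)
  if (length(v) == 0L) stop("empty series", call. = FALSE)
  c(v[1], diff(v))
}

#' Background values of an accumulated series
#'
#' The nearest-neighbour mean of consecutive accumulated values,
#' `z(k) = 0.5 * (x1[k] + x1[k - 1])` for `k = 2..n`. The background series
#' is the discretization anchor of the grey difference equation.
#'
#' @param x1 Numeric vector: an accumulated (1-AGO) series, length >= 2.
#' @return Numeric vector of length `length(x1) - 1`, aligned with epochs
#'   `2..n`.
#' @examples
#' background_values(c(1.00, 2.04))  # 1.52
#' @export
background_values <- function(x1) {
  v <- as.numeric(x1)
  n <- length(v)
  if (n < 2L) stop("at least 2 accumulated values are required", call. = FALSE)
  0.5 * (v[-1] + v[-n])
}

#' Fill missing values by mean substitution
#'
#' Replaces every `NA` with the mean of the observed entries. This is the
#' only route by which missing data enter the package: model constructors
#' reject series containing `NA`.
#'
#' @param values Numeric vector, possibly containing `NA`; at least one
#'   observed value.
#' @return Numeric vector with `NA`s filled; attribute `"filled"` is a
#'   logical vector flagging the substituted positions.
#' @examples
#' mean_substitute(c(1, NA, 3))  # 1 2 3
#' @export
mean_substitute <- function(values) {
  v <- as.numeric(values)
  miss <- is.na(v)
  if (all(miss)) stop("all values missing; nothing to substitute from",
                      call. = FALSE)
  v[miss] <- mean(v[!miss])
  attr(v, "filled") <- miss
  v
}

#' Prepare a dataset for grey multivariate modelling
#'
#' Bundles one system-behaviour series and one or more driving series into
#' the object every model consumes: normalized values, their 1-AGO
#' accumulations, and the background values of the system accumulation.
#'
#' @param system A `grey_series`: the system behaviour variable.
#' @param drivers A `grey_series` or list of them: the driving variables.
#'   All series must share the epochs of `system`.
#' @param normalize Normalization mode passed to [initialize_series()].
#' @return An object of class `grey_prepared` with fields `epochs`, `n`
#'   (observations), `N` (1 + number of drivers), `system_name`,
#'   `driver_names`, `y0` (normalized system values), `y1` (their 1-AGO),
#'   `z` (background values, epochs `2..n`), `x0`/`x1` (matrices of
#'   normalized / accumulated driver values, one column per driver), and the
#'   normalization bases.
#' @examples
#' cp <- china_pollutants()
#' prep <- prepare_dataset(
#'   grey_series(cp$wdpc, cp$year, name = "wdpc", unit = "ton"),
#'   grey_series(cp$gdp_per_capita, cp$year, name = "gdp", unit = "yuan"))
#' prep$n; prep$N
#' @export
prepare_dataset <- function(system, drivers,
                            normalize = c("first", "mean", "none")) {
  normalize <- match.arg(normalize)
  if (!inherits(system, "grey_series")) {
    stop("'system' must be a grey_series", call. = FALSE)
  }
  if (inherits(drivers, "grey_series")) drivers <- list(drivers)
  if (!length(drivers) || !all(vapply(drivers, inherits, TRUE, "grey_series"))) {
    stop("'drivers' must be one grey_series or a list of them", call. = FALSE)
  }
  for (d in drivers) {
    if (!identical(d$epochs, system$epochs)) {
      stop("driver '", d$name, "' does not share the system epochs",
           call. = FALSE)
    }
  }
  n <- length(system$values)
  sy <- initialize_series(system, normalize)
  y0 <- sy$ratios
  y1 <- ago(y0)
  dx <- lapply(drivers, initialize_series, mode = normalize)
  x0 <- vapply(dx, `[[`, numeric(n), "ratios")
  x1 <- apply(x0, 2L, cumsum)
  dimnames(x0) <- dimnames(x1) <-
    list(system$epochs, vapply(drivers, `[[`, "", "name"))
  structure(list(
    epochs = system$epochs, n = n, N = 1L + length(drivers),
    system_name = system$name,
    driver_names = colnames(x0),
    y_raw = system$values, y0 = y0, y1 = y1, z = background_values(y1),
    x_raw = vapply(drivers, `[[`, numeric(n), "values"),
    x0 = x0, x1 = x1,
    normalize = normalize,
    y_base = sy$base,
    x_bases = vapply(dx, `[[`, 0, "base")
  ), class = "grey_prepared")
}

#' @export
print.grey_prepared <- function(x, ...) {
  cat("<grey_prepared> system '", x$system_name, "' with ",
      x$N - 1L, " driver(s): ", paste(x$driver_names, collapse = ", "),
      "\n  n = ", x$n, ", epochs ", x$epochs[1], "..", x$epochs[x$n],
      ", normalization '", x$normalize, "'\n", sep = "")
  invisible(x)
}

#' China pollutant and GDP dataset, 1996--2015
#'
#' Annual GDP per capita (yuan) together with per-capita wastewater discharge
#' (WDPC, ton), SO2 emissions (ton) and dust emissions (ton) for China,
#' 1996--2015, from the National Bureau of Statistics of China. This is the
#' reference dataset on which the package's models were validated; gap years
#' in the original wastewater and SO2 records were filled by mean
#' substitution before publication, so the table is complete as shipped.
#'
#' @return A data frame with columns `year`, `gdp_per_capita`, `wdpc`,
#'   `so2_per_capita`, `dust_per_capita` (20 rows).
#' @examples
#' head(china_pollutants())
#' @export
china_pollutants <- function() {
  path <- system.file("extdata", "china_pollutants_1996_2015.csv",
                      package = "greymulti", mustWork = TRUE)
  read_series_csv(path)
}

#' Read a series table from CSV
#'
#' Expects a header row, one integer epoch column (the first), and one
#' numeric column per series; dot decimal separator, UTF-8.
#'
#' @param path File path.
#' @return Data frame; first column integer epochs, remaining columns numeric.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", check.names = TRUE)
  if (ncol(df) < 2L) stop("expected an epoch column plus at least one series",
                          call. = FALSE)
  df[[1]] <- as.integer(df[[1]])
  for (j in 2:ncol(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write a series table to CSV
#'
#' Values are written with 15 significant digits so a read/write round trip
#' is stable at that precision.
#'
#' @param df Data frame as returned by [read_series_csv()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
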