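#' Signed percentage errors
#'
#' `error(k) = (actual(k) - fitted(k)) / actual(k) * 100`: positive when the
#' model under-predicts.
#'
#' @param actual,fitted Numeric vectors of equal length; `actual` non-zero.
#' @return Numeric vector of signed percentage errors.
#' @examples
#' percentage_errors(c(2, 2), c(1, 2))   # 50 0
#' @export
percentage_errors <- function(actual, fitted) {
  actual <- as.numeric(actual); fitted <- as.numeric(fitted)
  if (length(actual) != length(fitted)) {
    stop("actual and fitted differ in length", call. = FALSE)
  }
  zero <- which(actual == 0)
  if (length(zero)) {
    stop("actual value is zero at position ", zero[1L],
         "; percentage error undefined", call. = FALSE)
  }
  (actual - fitted) / actual * 100
}

#' Mean absolute percentage error
#'
#' Averages `abs(errors)` over the modeled epochs. Under first-value
#' initialization the base epoch has error 0 by construction, so the default
#' convention excludes it (epochs `2..n`, the usual choice in grey-model
#' reporting); `"include_base"` averages over all `n` epochs, which shrinks
#' the MAPE by the factor `(n - 1) / n`. Published tables are not always
#' consistent about the denominator, so both are first-class.
#'
#' @param errors Full-length signed percentage-error vector (element 1 is the
#'   base epoch).
#' @param convention `"exclude_base"` (default) or `"include_base"`.
#' @return MAPE in percent.
#' @examples
#' mape(c(0, 10, -20))                  # 15
#' mape(c(0, 10, -20), "include_base")  # 10
#' @export
mape <- function(errors, convention = c("exclude_base", "include_base")) {
  convention <- match.arg(convention)
  e <- as.numeric(errors)
  if (!length(e)) stop("empty error vector", call. = FALSE)
  if (convention == "exclude_base") e <- e[-1L]
  mean(abs(e))
}

#' Compare fitted grey models side by side
#'
#' Lines up the in-sample fits of several models of the same series (shared
#' epochs and actual values) in a wide table -- actual value, then model
#' value and signed percentage error per model -- and reports each model's
#' MAPE under both denominator conventions plus the lowest-MAPE model.
#'
#' @param fits A (possibly named) list of `grey_fit` objects.
#' @param convention MAPE convention used to pick the winner (default
#'   `"exclude_base"`).
#' @return A list of class `grey_comparison`: `table` (data frame),
#'   `mape` (matrix, one row per model, both conventions), `winner` (model
#'   name, or `NA` on an exact tie of the chosen convention).
#' @export
compare_models <- function(fits,
                           convention = c("exclude_base", "include_base")) {
  convention <- match.arg(convention)
  if (inherits(fits, "grey_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "grey_fit")))
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- make.unique(vapply(fits, `[[`, "", "model"))
    names(fits) <- nm
  }
  ref <- fits[[1L]]
  for (f in fits[-1L]) {
    if (!identical(f$epochs, ref$epochs) ||
        max(abs(f$actual - ref$actual)) > 1e-12) {
      stop("fits do not share epochs and actual values; cannot align",
           call. = FALSE)
    }
  }
  tab <- data.frame(year = ref$epochs, actual_value = ref$actual)
  for (i in seq_along(fits)) {
    tab[[paste0(nm[i], "_model_value")]] <- fits[[i]]$fitted
    tab[[paste0(nm[i], "_error_pct")]] <- fits[[i]]$errors_pct
  }
  mp <- cbind(exclude_base = vapply(fits, `[[`, 0, "mape"),
              include_base = vapply(fits, `[[`, 0, "mape_include_base"))
  rownames(mp) <- nm
  winner <- NA_character_
  if (length(fits) > 1L) {
    m <- mp[, convention]
    if (sum(m == min(m)) == 1L) winner <- nm[which.min(m)]
  }
  structure(list(table = tab, mape = mp, winner = winner,
                 convention = convention),
            class = "grey_comparison")
}

#' @export
print.grey_comparison <- function(x, digits = 4, ...) {
  cat("<grey_comparison> of", nrow(x$mape), "model(s)\n")
  print(round(x$mape, digits))
  if (!is.na(x$winner)) {
    cat("lowest MAPE (", x$convention, "): ", x$winner, "\n", sep = "")
  } else if (nrow(x$mape) > 1L) {
    cat("tie on MAPE (", x$convention, ")\n", sep = "")
  }
  invisible(x)
}

#' Descriptive trend classification
#'
#' Classifies a sequence by the sign pattern of its first differences:
#' monotone patterns give `"increasing"` / `"decreasing"`, exactly one sign
#' change gives `"U_shaped"` (down then up) or `"inverted_U"` (up then down),
#' anything else -- including a constant sequence -- is `"mixed"`.
#' Differences smaller than `rtol * max(abs(x))` count as flat and never flip
#' the class. When classifying a fitted grey curve, pass the modeled epochs
#' only (`fitted[-1]`): the base-epoch value is pinned to the observation by
#' convention, not produced by the model.
#'
#' @param x Numeric vector, length >= 3.
#' @param rtol Relative flatness tolerance (default `1e-6`).
#' @return One of `"increasing"`, `"decreasing"`, `"U_shaped"`,
#'   `"inverted_U"`, `"mixed"`.
#' @examples
#' classify_trend(c(3, 1, 2))     # U_shaped
#' classify_trend(1:5)            # increasing
#' @export
classify_trend <- function(x, rtol = 1e-6) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 values", call. = FALSE)
  d <- diff(x)
  flat <- abs(d) <= rtol * max(abs(x))
  s <- sign(d)[!flat]
  if (!length(s)) return("mixed")
  runs <- rle(s)$values
  if (length(runs) == 1L) return(if (runs > 0) "increasing" else "decreasing")
  if (length(runs) == 2L) {
    return(if (runs[1L] < 0) "U_shaped" else "inverted_U")
  }
  "mixed"
}
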