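# Shared fixture preparation and memoized model fits (the NLS fits are
# reused across test files).

.fit_cache <- new.env(parent = emptyenv())

china_prep <- function(system = c("wdpc", "so2_per_capita",
                                  "dust_per_capita")) {
  system <- match.arg(system)
  key <- paste0("prep_", system)
  if (is.null(.fit_cache[[key]])) {
    cp <- china_pollutants()
    .fit_cache[[key]] <- prepare_dataset(
      grey_series(cp[[system]], cp$year, name = system),
      grey_series(cp$gdp_per_capita, cp$year, name = "gdp"))
  }
  .fit_cache[[key]]
}

china_gm <- function(system = "wdpc") {
  key <- paste0("gm_", system)
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- gm1n_fit(china_prep(system))
  }
  .fit_cache[[key]]
}

china_nls <- function(system = "wdpc") {
  key <- paste0("nls_", system)
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- fit_nls(china_prep(system))
  }
  .fit_cache[[key]]
}

china_nls_lm <- function(system = "wdpc") {
  key <- paste0("lm_", system)
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- fit_nls_lm(china_prep(system))
  }
  .fit_cache[[key]]
}

# A tiny 4-point prepared dataset for hand-checkable arithmetic.
toy_prep <- function() {
  prepare_dataset(
    grey_series(c(1, 2, 1.5, 1.8), 1:4, name = "y"),
    grey_series(c(1, 1.2, 1.4, 1.6), 1:4, name = "x"))
}
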