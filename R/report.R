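#' Serialize a fit report
#'
#' Writes a `grey_fit` as JSON (parameters, fitted table, errors, MAPE under
#' both conventions, solver diagnostics) and optionally as a CSV fitted table
#' with columns `year`, `actual_value`, `model_value`, `error_pct`.
#'
#' @param fit A `grey_fit`.
#' @param json Path for the JSON report, or `NULL` to skip.
#' @param csv Path for the CSV fitted table, or `NULL` to skip.
#' @return The report as a list, invisibly.
#' @export
write_fit_report <- function(fit, json = NULL, csv = NULL) {
  stopifnot(inherits(fit, "grey_fit"))
  tab <- fitted_table(fit)
  diag <- fit$diagnostics
  diag$trace <- NULL    # traces go to write_trace_csv()
  rep <- list(
    model = fit$model,
    system = fit$system_name,
    drivers = fit$driver_names,
    params = list(a = fit$params$a,
                  b = as.list(fit$params$b),
                  gamma = as.list(fit$params$gamma)),
    transformed = transformed_params(fit),
    mape = list(exclude_base = fit$mape,
                include_base = fit$mape_include_base),
    fitted_table = tab,
    diagnostics = diag
  )
  if (!is.null(json)) {
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv)) {
    utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  }
  invisible(rep)
}

#' Fitted table of a grey fit
#'
#' @param fit A `grey_fit`.
#' @return Data frame with `year`, `actual_value`, `model_value`,
#'   `error_pct`.
#' @export
fitted_table <- function(fit) {
  stopifnot(inherits(fit, "grey_fit"))
  data.frame(year = fit$epochs,
             actual_value = fit$actual,
             model_value = fit$fitted,
             error_pct = fit$errors_pct)
}

#' Export an NLS iteration trace
#'
#' Writes the per-sweep trace recorded by [fit_nls()] (iteration number,
#' parameter values, objective, maximum parameter change `e`) to CSV for
#' convergence diagnostics.
#'
#' @param fit A `grey_fit` produced by [fit_nls()] with `trace = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(fit, path) {
  tr <- fit$diagnostics$trace
  if (is.null(tr)) stop("fit carries no iteration trace", call. = FALSE)
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a model comparison
#'
#' @param cmp A [compare_models()] result.
#' @param json,csv Output paths (`NULL` to skip either).
#' @return The comparison list, invisibly.
#' @export
write_comparison <- function(cmp, json = NULL, csv = NULL) {
  stopifnot(inherits(cmp, "grey_comparison"))
  out <- list(table = cmp$table,
              mape = as.data.frame(cmp$mape),
              winner = cmp$winner,
              convention = cmp$convention)
  if (!is.null(json)) {
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv)) {
    utils::write.csv(cmp$table, csv, row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
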