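#' Derived (transformed) parameters of the nonlinear grey model
#'
#' The TNGM(1,N) difference equation can be rewritten with the background
#' value expanded, giving `x1(k) = sum_i beta_i (x1_i(k))^gamma_i -
#' alpha * x1acc(k - 1)` with `alpha = a / (1 + 0.5 a)` and
#' `beta_i = b_i / (1 + 0.5 a)`. These derived coefficients are a pure view
#' of `(a, b)` -- they are recomputed on demand and never estimated
#' independently, so the two parameterizations cannot drift apart.
#'
#' @param a Development coefficient; `1 + 0.5 * a` must be non-zero.
#' @param b Driving coefficients.
#' @return List with `alpha` and `beta`.
#' @examples
#' derive_transformed(0, c(2, 3))     # alpha 0, beta unchanged
#' derive_transformed(-0.042633, 1.016804)
#' @export
derive_transformed <- function(a, b) {
  den <- 1 + 0.5 * a
  if (den == 0) {
    stop("singular transform: a = -2 makes 1 + 0.5a vanish", call. = FALSE)
  }
  list(alpha = a / den, beta = as.numeric(b) / den)
}

#' Fit the nonlinear TNGM(1,N) model for given parameters
#'
#' Evaluates the nonlinear grey difference equation
#' `x1(k) + a z(k) = sum_i b_i (x1_i(k))^gamma_i` in-sample, using actual
#' background values (the same convention as [gm1n_fit()]). With all
#' exponents at 1 the model degenerates exactly to GM(1,N). Parameters are
#' normally estimated with [fit_nls()]; this evaluator serves externally
#' supplied coefficients.
#'
#' @param prep A [prepare_dataset()] object.
#' @param a Development coefficient.
#' @param b Driving coefficients.
#' @param gamma Driver exponents.
#' @return A `grey_fit` object (model `"tngm1n"`).
#' @export
tngm_fit <- function(prep, a, b, gamma) {
  stopifnot(inherits(prep, "grey_prepared"))
  b <- as.numeric(b); gamma <- as.numeric(gamma)
  if (length(b) != prep$N - 1L || length(gamma) != prep$N - 1L) {
    stop("need one b and one gamma per driver", call. = FALSE)
  }
  new_grey_fit("tngm1n", prep, a = a, b = b, gamma = gamma,
               diagnostics = list(method = "fixed"))
}

#' Transformed parameters of a fitted model
#'
#' @param fit A `grey_fit`.
#' @return List with `alpha` and `beta` per [derive_transformed()].
#' @export
transformed_params <- function(fit) {
  stopifnot(inherits(fit, "grey_fit"))
  derive_transformed(fit$params$a, fit$params$b)
}

#' Nonlinear time response
#'
#' The grey-constant approximation for the nonlinear model: identical in form
#' to the linear [time_response()] but with each accumulated driver raised to
#' its exponent. Provided as a named entry point for clarity; see
#' [time_response()] for arguments and semantics.
#'
#' @inheritParams time_response
#' @return Accumulated forecast vector; apply [iago()] for levels.
#' @export
tngm_time_response <- function(a, b, driver_acc, gamma, x1_init = 1) {
  time_response(a, b, driver_acc, gamma = gamma, x1_init = x1_init)
}
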