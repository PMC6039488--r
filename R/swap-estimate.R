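#' Swapped-read fraction estimate
#'
#' Container for a swapped-read fraction produced by either plate-based
#' estimator, always on the proportion scale (0.0218, not 2.18).
#'
#' @param fraction Estimated swapped-read fraction in \[0, 1\].
#' @param std_error Standard error of the fraction (may be `NA` when the
#'   estimator was run without uncertainty quantification).
#' @param method `"impossible_regression"` or `"crossplatform_model"`.
#' @param diagnostics Named list of fit diagnostics (slope/coefficients,
#'   number of fitted units, destination multiplier, ...).
#' @return A `swap_estimate` object.
#' @export
swap_estimate <- function(fraction, std_error, method, diagnostics = list()) {
  method <- match.arg(method, c("impossible_regression", "crossplatform_model"))
  stopifnot(is.numeric(fraction), length(fraction) == 1, is.finite(fraction),
            fraction >= 0, fraction <= 1,
            is.numeric(std_error), length(std_error) == 1,
            is.na(std_error) || std_error >= 0)
  structure(
    list(fraction = fraction, std_error = std_error, method = method,
         diagnostics = diagnostics),
    class = "swap_estimate"
  )
}

#' @export
print.swap_estimate <- function(x, ...) {
  cat("<swap_estimate> ", sprintf("%.3f%%", 100 * x$fraction),
      if (is.finite(x$std_error)) sprintf(" ± %.3f%%", 100 * x$std_error),
      "  (", x$method, ")\n", sep = "")
  invisible(x)
}

#' @rdname swap_estimate
#' @param x A `swap_estimate`.
#' @param ... Unused.
#' @method tidy swap_estimate
#' @export
tidy.swap_estimate <- function(x, ...) {
  tibble::tibble(
    term = "swapped_fraction",
    estimate = x$fraction,
    std.error = x$std_error,
    method = x$method
  )
}

#' @rdname swap_estimate
#' @method glance swap_estimate
#' @export
glance.swap_estimate <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    fraction = x$fraction,
    std_error = x$std_error,
    method = x$method,
    n_units = d$n_units %||% NA_integer_
  )
}
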