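#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted dose-response curve
#'
#' @param x A `dose_response` object from [fit_dose_response()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.dose_response <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = sm[, "Estimate"],
                 std.error = sm[, "Std. Error"])
}

#' One-row summary of a fitted dose-response curve
#'
#' @param x A `dose_response` object.
#' @param ... Unused.
#' @return A tibble with `ec50_app_mM`, `dynamic_range` (r_max - r_min),
#'   `sigma`, `n`, `converged`.
#' @export
glance.dose_response <- function(x, ...) {
  tibble::tibble(
    ec50_app_mM = 10^x$log_ec50,
    dynamic_range = x$r_max - x$r_min,
    sigma = summary(x$fit)$sigma,
    n = nrow(x$points),
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}
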