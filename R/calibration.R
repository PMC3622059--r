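#' Reversal potential from a voltage-current relationship
#'
#' Least-squares line through peak agonist-evoked currents at several
#' holding potentials; the reversal potential is the zero crossing
#' `-intercept / slope`. With bicarbonate-free saline this reversal equals
#' the chloride Nernst potential, so [invert_nernst()] converts it to
#' intracellular chloride.
#'
#' @param vcr A data frame with columns `vh_mv` (holding potentials, >= 2
#'   distinct values) and `i_pa` (peak currents).
#' @return Estimated reversal potential, mV.
#' @export
#' @examples
#' vcr <- tibble::tibble(vh_mv = c(-107, -95, -60, -45),
#'                       i_pa = 0.5 * (vh_mv + 84))
#' estimate_reversal(vcr)
estimate_reversal <- function(vcr) {
  stopifnot(all(c("vh_mv", "i_pa") %in% names(vcr)))
  if (length(unique(vcr$vh_mv)) < 2) {
    stop("need at least 2 distinct holding potentials")
  }
  fit <- stats::lm(i_pa ~ vh_mv, data = vcr)
  slope <- stats::coef(fit)[["vh_mv"]]
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    stop("degenerate (zero-slope) current-voltage fit")
  }
  -stats::coef(fit)[["(Intercept)"]] / slope
}

#' Fit a ratio-chloride dose-response curve
#'
#' Four-parameter logistic in log10 chloride:
#' `R = r_min + (r_max - r_min) / (1 + 10^(slope_h * (log_ec50 - log10 cl)))`,
#' fitted by Levenberg-Marquardt least squares. Noise-free points generated
#' from the same model are recovered to numerical precision.
#'
#' @param points A data frame with columns `cl_mM` (> 0) and `r`, at least
#'   4 points spanning at least one decade of chloride.
#' @return An object of class `dose_response` with elements `r_min`,
#'   `r_max`, `log_ec50`, `slope_h`, and the underlying `fit`. Supports
#'   [predict()][predict.dose_response()], `tidy()` and `glance()`.
#' @export
fit_dose_response <- function(points) {
  stopifnot(all(c("cl_mM", "r") %in% names(points)))
  points <- points[order(points$cl_mM), ]
  if (nrow(points) < 4) stop("need at least 4 dose-response points")
  if (any(points$cl_mM <= 0)) stop("chloride doses must be positive")
  if (log10(max(points$cl_mM) / min(points$cl_mM)) < 1) {
    stop("dose-response points must span at least one decade")
  }
  df <- data.frame(lcl = log10(points$cl_mM), r = points$r)
  span <- max(df$r) - min(df$r)
  start <- list(r_min = min(df$r), r_max = max(df$r) + 0.5 * span,
                log_ec50 = stats::median(df$lcl), slope_h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ r_min + (r_max - r_min) / (1 + 10^(slope_h * (log_ec50 - lcl))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) {
      stop("dose-response fit did not converge: ", conditionMessage(e),
           "\n  doses: ", paste(signif(points$cl_mM, 3), collapse = ", "))
    }
  )
  cf <- stats::coef(fit)
  structure(list(r_min = cf[["r_min"]], r_max = cf[["r_max"]],
                 log_ec50 = cf[["log_ec50"]], slope_h = cf[["slope_h"]],
                 fit = fit, points = tibble::as_tibble(points)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response> 4-parameter logistic in log10([Cl-])\n")
  cat(sprintf("  r_min = %.4g, r_max = %.4g, ec50_app = %.4g mM, slope = %.4g\n",
              x$r_min, x$r_max, 10^x$log_ec50, x$slope_h))
  invisible(x)
}

#' Evaluate a fitted dose-response curve
#'
#' @param object A `dose_response` object.
#' @param cl_mM Chloride concentrations, mM.
#' @param ... Unused.
#' @return Predicted ratio values.
#' @export
predict.dose_response <- function(object, cl_mM, ...) {
  object$r_min + (object$r_max - object$r_min) /
    (1 + 10^(object$slope_h * (object$log_ec50 - log10(cl_mM))))
}

#' Invert a dose-response curve
#'
#' Closed-form inverse of the 4-parameter logistic: the chloride
#' concentration at which the fitted curve takes the value `r`. Round-trips
#' with [predict.dose_response()] to numerical precision.
#'
#' @param r Ratio value(s), strictly inside `(r_min, r_max)`.
#' @param curve A `dose_response` object.
#' @return Estimated intracellular chloride, mM.
#' @export
cl_from_ratio <- function(r, curve) {
  if (any(r <= curve$r_min)) {
    stop(sprintf("ratio below the fitted floor r_min = %.4g", curve$r_min))
  }
  if (any(r >= curve$r_max)) {
    stop(sprintf("ratio above the fitted ceiling r_max = %.4g", curve$r_max))
  }
  frac <- (curve$r_max - curve$r_min) / (r - curve$r_min) - 1
  10^(curve$log_ec50 - log10(frac) / curve$slope_h)
}

#' KCC2 reverse-mode influx assay
#'
#' The rise of the fluorescence ratio produced by a high-KCl challenge:
#' `delta R = R(kcl_time + after_s) - R(kcl_time - before_s)` with
#' nearest-sample lookup (matching the 20 s acquisition cadence).
#'
#' @param ratio A ratio tibble (one ROI) from [pair_ratio()].
#' @param kcl_time Time of the KCl application, seconds.
#' @param before_s,after_s Measurement offsets, seconds (defaults 30 before
#'   and 300 after).
#' @return A one-row tibble: `kind`, `value`, `units`.
#' @export
kcc2_influx_assay <- function(ratio, kcl_time, before_s = 30,
                              after_s = 300) {
  t1 <- kcl_time - before_s
  t2 <- kcl_time + after_s
  if (t1 < min(ratio$time_s) || t2 > max(ratio$time_s)) {
    stop("measurement window outside the recorded trace")
  }
  nearest <- function(tt) ratio$r[which.min(abs(ratio$time_s - tt))]
  tibble::tibble(kind = "influx_delta_r",
                 value = nearest(t2) - nearest(t1),
                 units = "ratio units")
}

#' Chloride extrusion assay
#'
#' Half-recovery time of the fluorescence ratio after an imposed chloride
#' load: locates the peak inside the load window, takes the mean of the
#' last `n_baseline` pre-load samples as baseline (a window over which the
#' resting signal has settled), and delegates to [half_time()] (linear
#' midpoint interpolation, or single-exponential extrapolation flagged as
#' such when the recording never crosses the midpoint).
#'
#' @param ratio A ratio tibble (one ROI) from [pair_ratio()].
#' @param load_window `c(start, end)` of the chloride-loading episode,
#'   seconds.
#' @param n_baseline Number of pre-load samples averaged for the baseline.
#' @return A one-row tibble: `kind`, `value` (minutes), `units`,
#'   `extrapolated`.
#' @export
extrusion_assay <- function(ratio, load_window, n_baseline = 5) {
  stopifnot(length(load_window) == 2, load_window[2] > load_window[1])
  inside <- ratio$time_s >= load_window[1] & ratio$time_s <= load_window[2]
  if (!any(inside)) stop("no samples inside the load window; peak not found")
  pre <- ratio$r[ratio$time_s < load_window[1]]
  if (length(pre) < 1) stop("no pre-load baseline samples")
  baseline <- mean(utils::tail(pre, n_baseline))
  # recovery is timed from the end of the load: the last maximal sample
  idx <- which(inside)
  peak_i <- idx[max(which(ratio$r[idx] == max(ratio$r[idx])))]
  if (ratio$r[peak_i] <= baseline) stop("no chloride-load peak in window")
  ht <- half_time(ratio, peak_time = ratio$time_s[peak_i],
                  baseline_value = baseline, value_col = "r")
  tibble::tibble(kind = "extrusion_half_time", value = ht$minutes,
                 units = "min", extrapolated = ht$extrapolated)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Exact maximum ECDF gap `D` with the asymptotic Kolmogorov-distribution
#' p-value.
#'
#' @param a,b Numeric samples, each of size >= 5.
#' @return A one-row tibble with `d`, `p`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 5 || length(b) < 5) {
    stop("both samples must have at least 5 observations")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  tibble::tibble(d = unname(kt$statistic), p = kt$p.value,
                 n_a = length(a), n_b = length(b))
}
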