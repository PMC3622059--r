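#' Re-grid an image between camera binnings
#'
#' Downsampling (to a coarser binning) is by block mean, upsampling (to a
#' finer binning) by pixel replication; both preserve the mean intensity, so
#' arithmetic between channels acquired at different binnings is valid after
#' alignment.
#'
#' @param img Numeric matrix.
#' @param from_bin,to_bin Source and target binning factors; their ratio
#'   must be an integer (in one direction or the other).
#' @return The re-gridded matrix.
#' @export
#' @examples
#' align_binning(matrix(c(1, 5, 3, 7), 2), from_bin = 1, to_bin = 2)
align_binning <- function(img, from_bin, to_bin) {
  stopifnot(from_bin >= 1, to_bin >= 1)
  if (from_bin == to_bin) return(img)
  if (to_bin > from_bin) {
    if (to_bin %% from_bin != 0) stop("binning ratio must be an integer")
    block_mean(img, to_bin %/% from_bin)
  } else {
    if (from_bin %% to_bin != 0) stop("binning ratio must be an integer")
    block_replicate(img, from_bin %/% to_bin)
  }
}

#' Extract background-subtracted ROI traces
#'
#' For every frame, every ROI value is the mean over the ROI's pixels minus
#' the mean over the designated background region, after aligning the frame
#' to the unbinned pixel grid of the ROI mask.
#'
#' @param stack A `frame_stack` from [generate_experiment()] or
#'   [read_run()].
#' @param rois Integer label matrix on the unbinned grid (default: the
#'   stack's own mask). Label 0 is background.
#' @param background_label ROI label(s) treated as background (default 0,
#'   i.e. all cell-free pixels).
#' @return A tibble with columns `roi_id`, `channel`, `time_s`, `value`
#'   (background-subtracted mean counts).
#' @export
extract_traces <- function(stack, rois = NULL, background_label = 0L) {
  rois <- rois %||% stack$roi
  ids <- sort(setdiff(unique(as.vector(rois)), background_label))
  if (length(ids) == 0) stop("ROI mask contains no ROIs")
  bg_mask <- rois %in% background_label
  dim(bg_mask) <- dim(rois)
  if (!any(bg_mask)) stop("background region is empty")
  masks <- lapply(ids, function(id) {
    m <- rois == id
    if (!any(m)) stop("empty ROI label: ", id)
    m
  })
  out <- vector("list", length(stack$frames))
  for (fi in seq_along(stack$frames)) {
    info <- stack$meta[fi, ]
    img <- align_binning(stack$frames[[fi]], info$binning, 1L)
    if (!all(dim(img) == dim(rois))) {
      stop("ROI mask does not match the unbinned frame size")
    }
    bg <- mean(img[bg_mask])
    out[[fi]] <- tibble::tibble(
      roi_id = ids,
      channel = info$channel,
      time_s = info$time_s,
      value = vapply(masks, function(m) mean(img[m]), numeric(1)) - bg
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$roi_id, .data$channel,
                 .data$time_s)
}

#' Pair channel traces into a ratio trace
#'
#' One ratio sample per acquisition cycle: the 430 nm value divided by the
#' 500 nm value of the same cycle (division after background subtraction),
#' timestamped at the cycle's first acquisition. Unpaired frames at the end
#' of the stack are dropped; their count is attached as the
#' `n_dropped` attribute and reported via a warning.
#'
#' @param traces A trace tibble from [extract_traces()] containing both
#'   channels (any number of ROIs).
#' @param order Which channel opens each cycle: `"500_first"` (default) or
#'   `"430_first"`.
#' @return A tibble with columns `roi_id`, `time_s`, `r` (R430/500).
#' @export
pair_ratio <- function(traces, order = c("500_first", "430_first")) {
  order <- match.arg(order)
  first_chan <- if (order == "500_first") 500L else 430L
  dropped <- 0L
  paired <- lapply(split(traces, traces$roi_id), function(tr) {
    tr <- tr[order(tr$time_s), ]
    tr$cycle <- cumsum(tr$channel == first_chan)
    ok <- tr$cycle >= 1
    dropped <<- dropped + sum(!ok)
    tr <- tr[ok, ]
    per <- dplyr::summarise(
      dplyr::group_by(tr, .data$cycle),
      roi_id = .data$roi_id[1],
      time_s = min(.data$time_s),
      f430 = .data$value[.data$channel == 430L][1],
      f500 = .data$value[.data$channel == 500L][1],
      n = dplyr::n(),
      .groups = "drop"
    )
    bad <- per$n != 2 | is.na(per$f430) | is.na(per$f500)
    dropped <<- dropped + sum(per$n[bad])
    per <- per[!bad, ]
    tibble::tibble(roi_id = per$roi_id, time_s = per$time_s,
                   r = per$f430 / per$f500)
  })
  out <- dplyr::bind_rows(paired)
  if (dropped > 0) {
    warning(sprintf("%d unpaired frame(s) dropped", dropped))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Normalize a trace to its first sample
#'
#' The delta-F/F (or delta-R/R) convention: each sample minus the first
#' recorded value, divided by the first recorded value. The first sample is
#' exactly 0 and the output is invariant to rescaling the input.
#'
#' @param trace A tibble with a time column and a value column (`value` or
#'   `r`), e.g. one ROI-channel of [extract_traces()] or one ROI of
#'   [pair_ratio()].
#' @param value_col Name of the value column (default: `"value"` if present,
#'   else `"r"`).
#' @return The input tibble with the value column replaced by its
#'   first-sample-normalized version, in a column named `dff`.
#' @export
normalize_first <- function(trace, value_col = NULL) {
  value_col <- value_col %||% intersect(c("value", "r"), names(trace))[1]
  v <- trace[[value_col]]
  if (length(v) < 1 || v[1] == 0) stop("first trace value must be non-zero")
  trace$dff <- (v - v[1]) / v[1]
  trace
}

#' Percent inhibition at an event
#'
#' `100 * (baseline - first post-event value) / baseline`, where the
#' baseline is the mean of the last `n_baseline` samples strictly before
#' `event_time`. Invariant to trace scaling.
#'
#' @param trace A tibble with `time_s` and a value column.
#' @param event_time Event time, seconds.
#' @param n_baseline Number of pre-event samples averaged (default 3).
#' @param value_col Name of the value column (auto-detected).
#' @return Percent inhibition (positive for a drop).
#' @export
inhibition_percent <- function(trace, event_time, n_baseline = 3,
                               value_col = NULL) {
  value_col <- value_col %||% intersect(c("value", "r"), names(trace))[1]
  trace <- trace[order(trace$time_s), ]
  pre <- trace[[value_col]][trace$time_s < event_time]
  post <- trace[[value_col]][trace$time_s >= event_time]
  if (length(pre) < n_baseline || length(post) < 1) {
    stop("need at least ", n_baseline, " pre-event and 1 post-event sample")
  }
  baseline <- mean(utils::tail(pre, n_baseline))
  100 * (baseline - post[1]) / baseline
}

#' Peak fractional drop after an event
#'
#' `100 * (baseline - minimum value in the response window) / baseline`,
#' with the baseline defined as in [inhibition_percent()]. Used to quantify
#' the transient fluorescence decrease during an agonist/KCl challenge.
#'
#' @inheritParams inhibition_percent
#' @param window_s Length of the post-event search window, seconds
#'   (default: to the end of the trace).
#' @return Percent drop (positive for a decrease).
#' @export
peak_drop_percent <- function(trace, event_time, window_s = Inf,
                              n_baseline = 3, value_col = NULL) {
  value_col <- value_col %||% intersect(c("value", "r"), names(trace))[1]
  trace <- trace[order(trace$time_s), ]
  pre <- trace[[value_col]][trace$time_s < event_time]
  sel <- trace$time_s >= event_time & trace$time_s <= event_time + window_s
  post <- trace[[value_col]][sel]
  if (length(pre) < n_baseline || length(post) < 1) {
    stop("need at least ", n_baseline, " pre-event and 1 post-event sample")
  }
  baseline <- mean(utils::tail(pre, n_baseline))
  100 * (baseline - min(post)) / baseline
}

#' Half-recovery time of a trace
#'
#' Time from the peak until the trace first crosses the midpoint between
#' the peak value and the baseline. The crossing is located by linear
#' interpolation between the two bracketing samples. If the trace never
#' crosses the midpoint within the recording, the decay towards the
#' baseline is fitted with a single exponential and the half time is
#' extrapolated from the fitted time constant (`tau * ln 2`); the result is
#' then flagged as extrapolated.
#'
#' @param trace A tibble with `time_s` and a value column.
#' @param peak_time Time of the response peak, seconds (samples before it
#'   are ignored).
#' @param baseline_value Pre-load baseline the trace recovers towards.
#' @param value_col Name of the value column (auto-detected).
#' @return A list with `minutes` (half-recovery time) and `extrapolated`
#'   (logical).
#' @export
half_time <- function(trace, peak_time, baseline_value, value_col = NULL) {
  value_col <- value_col %||% intersect(c("value", "r"), names(trace))[1]
  trace <- trace[order(trace$time_s), ]
  sel <- trace$time_s >= peak_time
  tt <- trace$time_s[sel]
  vv <- trace[[value_col]][sel]
  if (length(tt) < 3) stop("peak not found or too few post-peak samples")
  peak_val <- vv[1]
  mid <- (peak_val + baseline_value) / 2
  below <- which(vv <= mid)
  if (length(below) > 0) {
    i <- below[1]
    if (i == 1) return(list(minutes = 0, extrapolated = FALSE))
    frac <- (vv[i - 1] - mid) / (vv[i - 1] - vv[i])
    t_half <- tt[i - 1] + frac * (tt[i] - tt[i - 1]) - tt[1]
    return(list(minutes = t_half / 60, extrapolated = FALSE))
  }
  # never crossed: single-exponential fit of the decay towards baseline
  y <- vv - baseline_value
  if (any(y <= 0)) stop("trace does not decay monotonically above baseline")
  fit <- stats::lm(log(y) ~ tt)
  rate <- -stats::coef(fit)[[2]]
  if (rate <= 0) stop("trace is not decaying; half time undefined")
  list(minutes = log(2) / rate / 60, extrapolated = TRUE)
}

#' Steady-state level as percent of the initial value
#'
#' `100 * mean(last tail_n samples) / first value`.
#'
#' @param trace A tibble with `time_s` and a value column.
#' @param tail_n Number of tail samples averaged (default 5).
#' @param value_col Name of the value column (auto-detected).
#' @return Percent of the initial value.
#' @export
steady_state_level <- function(trace, tail_n = 5, value_col = NULL) {
  value_col <- value_col %||% intersect(c("value", "r"), names(trace))[1]
  trace <- trace[order(trace$time_s), ]
  v <- trace[[value_col]]
  if (length(v) < tail_n + 1) stop("need at least tail_n + 1 samples")
  100 * mean(utils::tail(v, tail_n)) / v[1]
}

#' Filter cells by baseline 430 nm fluorescence
#'
#' Keeps cells whose baseline F430 lies in `[low, high]` (inclusive), the
#' expression window within which the ratio response is
#' expression-independent.
#'
#' @param cells A data frame with a baseline F430 column.
#' @param low,high Window bounds, relative fluorescence units (defaults
#'   1000 and 8000).
#' @param f430_col Name of the baseline column (default `"f430"`).
#' @return The filtered data frame.
#' @export
expression_filter <- function(cells, low = 1000, high = 8000,
                              f430_col = "f430") {
  cells[cells[[f430_col]] >= low & cells[[f430_col]] <= high, , drop = FALSE]
}

#' Pearson correlation with optional stratification
#'
#' Sample Pearson correlation with the two-tailed p-value from the
#' t-distribution on `n - 2` degrees of freedom, computed per stratum of
#' `x` when `strata` ranges are given.
#'
#' @param x,y Numeric vectors of equal length.
#' @param strata Optional list of `c(low, high)` ranges applied to `x`
#'   (inclusive).
#' @return A tibble with columns `stratum`, `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y, strata = NULL) {
  one <- function(xx, yy, label) {
    if (length(xx) < 3) stop("need at least 3 points per stratum")
    if (stats::sd(xx) == 0 || stats::sd(yy) == 0) {
      stop("zero variance in stratum ", label)
    }
    ct <- stats::cor.test(xx, yy, method = "pearson",
                          alternative = "two.sided")
    tibble::tibble(stratum = label, r = unname(ct$estimate),
                   p = ct$p.value, n = length(xx))
  }
  if (is.null(strata)) return(one(x, y, "all"))
  dplyr::bind_rows(lapply(strata, function(rg) {
    sel <- x >= rg[1] & x <= rg[2]
    one(x[sel], y[sel], paste0("[", rg[1], ", ", rg[2], "]"))
  }))
}

#' Gain-balancing factor
#'
#' Recommended multiplier for the 500 nm exposure so that the median ratio
#' over a calibration snippet is close to 1 (`median(F430) / median(F500)`).
#'
#' @param traces A trace tibble from [extract_traces()] with both channels.
#' @return The scalar balancing factor.
#' @export
balance_gains <- function(traces) {
  stats::median(traces$value[traces$channel == 430L]) /
    stats::median(traces$value[traces$channel == 500L])
}
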