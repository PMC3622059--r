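#' Write a simulated experiment to disk
#'
#' Runs [generate_experiment()] and writes the standard artifact set:
#'
#' * `stack.tiff`: multi-page 16-bit grayscale image stack (counts are kept
#'   as floats internally and rounded only here; values above 65535 are
#'   clipped and flagged),
#' * `meta.jsonl`: one JSON record per frame (`index`, `t_s`, `channel`,
#'   `exposure_ms`, `binning`, `intensity_factor`, `saturated`),
#' * `truth.csv`: ground-truth per-cell chloride and dark states per
#'   illumination event,
#' * `roi.tiff`: single-page integer label mask (0 = background),
#' * `config.yaml`: resolved configuration echo (name, seed, parameter
#'   blocks, analysis landmarks).
#'
#' Re-running with the same config and seed reproduces the files
#' byte-identically.
#'
#' @param config A configuration from [canned_config()] (or compatible).
#' @param out_dir Output directory (created if missing).
#' @param seed Camera-noise seed; mandatory when noise is enabled.
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  stack <- generate_experiment(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    stack = file.path(out_dir, "stack.tiff"),
    meta = file.path(out_dir, "meta.jsonl"),
    truth = file.path(out_dir, "truth.csv"),
    roi = file.path(out_dir, "roi.tiff"),
    config = file.path(out_dir, "config.yaml")
  )
  ints <- lapply(stack$frames, function(f) pmin(round(f), 65535))
  saturated <- vapply(stack$frames, function(f) any(round(f) > 65535),
                      logical(1))
  tiff::writeTIFF(lapply(ints, function(f) f / 65535), paths$stack,
                  bits.per.sample = 16L)
  meta <- stack$meta
  meta$saturated <- saturated
  con <- file(paths$meta, "w")
  for (i in seq_len(nrow(meta))) {
    writeLines(jsonlite::toJSON(list(
      index = meta$frame[i], t_s = meta$time_s[i],
      channel = meta$channel[i], exposure_ms = meta$exposure_ms[i],
      binning = meta$binning[i],
      intensity_factor = meta$intensity_factor[i],
      saturated = meta$saturated[i]
    ), auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  readr::write_csv(stack$truth, paths$truth)
  tiff::writeTIFF(stack$roi / 65535, paths$roi, bits.per.sample = 16L)
  cfg_echo <- list(
    name = config$name %||% "custom",
    seed = seed,
    q_ref_cl = config$q_ref_cl,
    photophysics = unclass(config$params),
    transport = Filter(Negate(is.null), unclass(config$transport)),
    membrane = Filter(Negate(is.null), unclass(config$membrane)),
    noise = unclass(config$noise %||% noise_model()),
    events = config$events %||% list(),
    n_frames = length(stack$frames)
  )
  yaml::write_yaml(cfg_echo, paths$config)
  invisible(paths)
}

#' Read a simulated run back from disk
#'
#' @param run_dir Directory written by [run_simulate()] (or any conforming
#'   data: a multi-page TIFF, a JSON-lines metadata file and an ROI label
#'   TIFF).
#' @return A `frame_stack`-compatible list with `frames`, `meta`, `roi`,
#'   `truth` (if present) and `config_echo`.
#' @export
read_run <- function(run_dir) {
  need <- c("stack.tiff", "meta.jsonl", "roi.tiff")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    stop("missing run artifact(s) in ", run_dir, ": ",
         paste(missing, collapse = ", "))
  }
  frames <- tiff::readTIFF(file.path(run_dir, "stack.tiff"), all = TRUE)
  frames <- lapply(frames, function(f) round(f * 65535))
  meta_lines <- readLines(file.path(run_dir, "meta.jsonl"))
  meta <- dplyr::bind_rows(lapply(meta_lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
  if (nrow(meta) != length(frames)) {
    stop("metadata length does not match frame count")
  }
  names(meta)[names(meta) == "index"] <- "frame"
  names(meta)[names(meta) == "t_s"] <- "time_s"
  roi <- round(tiff::readTIFF(file.path(run_dir, "roi.tiff")) * 65535)
  storage.mode(roi) <- "integer"
  truth_path <- file.path(run_dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else NULL
  cfg_path <- file.path(run_dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  structure(list(frames = frames, meta = meta, roi = roi, truth = truth,
                 config_echo = cfg),
            class = "frame_stack")
}

#' Analyze a simulated (or conforming external) run
#'
#' Reads the artifacts of a run directory, extracts background-subtracted
#' traces, pairs the ratio, and writes `traces.csv`
#' (`roi_id, t_s, channel, value`), `ratios.csv` (`roi_id, t_s, r`) and
#' `metrics.json` (per-ROI baseline intensities, mean ratio and drift;
#' plus the requested assay results).
#'
#' @param run_dir Run directory (see [read_run()]).
#' @param rois Optional ROI label matrix overriding the stored mask.
#' @param assay `"none"`, `"extrusion"` (needs a `load_window` landmark in
#'   the stored config) or `"influx"` (needs `kcl_time`).
#' @param out_dir Where to write reports (default: the run directory).
#' @return Invisibly, a list with `traces`, `ratios`, `metrics` and the
#'   written paths.
#' @export
run_analyze <- function(run_dir, rois = NULL,
                        assay = c("none", "extrusion", "influx"),
                        out_dir = run_dir) {
  assay <- match.arg(assay)
  run <- read_run(run_dir)
  if (!is.null(rois)) {
    if (any(dim(rois) != dim(run$roi))) {
      stop("ROI mask shape does not match the stack's unbinned field")
    }
    bad <- setdiff(setdiff(unique(as.vector(rois)), 0L),
                   unique(as.vector(run$roi)))
    if (length(bad)) {
      stop("ROI label(s) absent from the stack's mask: ",
           paste(bad, collapse = ", "))
    }
  }
  traces <- extract_traces(run, rois = rois)
  order <- if (run$meta$channel[1] == 500L) "500_first" else "430_first"
  both <- length(unique(run$meta$channel)) == 2
  ratios <- if (both) pair_ratio(traces, order = order) else NULL
  metrics <- dplyr::summarise(
    dplyr::group_by(traces, .data$roi_id, .data$channel),
    baseline = stats::median(.data$value[seq_len(min(3, length(.data$value)))]),
    n = dplyr::n(), .groups = "drop"
  )
  events <- run$config_echo$events %||% list()
  assay_out <- NULL
  if (assay == "extrusion") {
    if (is.null(events$load_window)) stop("run has no load_window landmark")
    assay_out <- dplyr::bind_rows(lapply(split(ratios, ratios$roi_id),
      function(rr) {
        res <- extrusion_assay(rr, unlist(events$load_window))
        res$roi_id <- rr$roi_id[1]
        res
      }))
  } else if (assay == "influx") {
    if (is.null(events$kcl_time)) stop("run has no kcl_time landmark")
    assay_out <- dplyr::bind_rows(lapply(split(ratios, ratios$roi_id),
      function(rr) {
        res <- kcc2_influx_assay(rr, events$kcl_time)
        res$roi_id <- rr$roi_id[1]
        res
      }))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(traces = file.path(out_dir, "traces.csv"),
                ratios = file.path(out_dir, "ratios.csv"),
                metrics = file.path(out_dir, "metrics.json"))
  readr::write_csv(
    dplyr::rename(traces, t_s = "time_s"), paths$traces)
  if (!is.null(ratios)) {
    readr::write_csv(dplyr::rename(ratios, t_s = "time_s"), paths$ratios)
  }
  jsonlite::write_json(
    list(metrics = metrics, assay = assay_out,
         n_dropped = attr(ratios, "n_dropped") %||% 0L),
    paths$metrics, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(list(traces = traces, ratios = ratios, metrics = metrics,
                 assay = assay_out, paths = paths))
}
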