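#' Scene specification
#'
#' Describes the imaged field: its pixel grid and the cells in it, each a
#' parametric disk with an expression level and a compartment reference.
#' Every pixel not covered by a cell is background. Cell masks must be
#' disjoint and at least one background pixel must remain.
#'
#' @param width,height Field size, pixels (on the unbinned grid).
#' @param pixel_size_um Pixel pitch, um.
#' @param cells A data frame with one row per cell and columns `cell_id`
#'   (integer label, >= 1), `cx`, `cy` (0-based pixel coordinates, origin
#'   top-left; disk centre or square top-left corner), `r` (disk radius or
#'   full square side, pixels), `expression` (relative units), and
#'   optionally `shape` (`"disk"`, the default, or `"square"`) and
#'   `compartment` (name matched against the simulated compartments).
#'   Square cells whose corner and side are multiples of the camera binning
#'   stay block-pure under binned acquisition, which keeps ROI extraction
#'   exact.
#' @return An object of class `scene_spec` with a precomputed integer label
#'   matrix (`$labels`, 0 = background).
#' @export
#' @examples
#' sc <- scene_spec(32, 32, cells = tibble::tibble(
#'   cell_id = 1L, cx = 15, cy = 15, r = 6, expression = 2000))
#' table(sc$labels)
scene_spec <- function(width, height, pixel_size_um = 1, cells) {
  cells <- tibble::as_tibble(cells)
  stopifnot(width >= 2, height >= 2, nrow(cells) >= 1,
            all(c("cell_id", "cx", "cy", "r", "expression") %in%
                  names(cells)))
  if (!"compartment" %in% names(cells)) cells$compartment <- "cell"
  if (!"shape" %in% names(cells)) cells$shape <- "disk"
  labels <- matrix(0L, nrow = height, ncol = width)
  # 0-based pixel centres, row-major, origin top-left
  px <- matrix(rep(seq_len(width) - 1L, each = height), nrow = height)
  py <- matrix(rep(seq_len(height) - 1L, times = width), nrow = height)
  for (i in seq_len(nrow(cells))) {
    inside <- if (cells$shape[i] == "square") {
      px >= cells$cx[i] & px < cells$cx[i] + cells$r[i] &
        py >= cells$cy[i] & py < cells$cy[i] + cells$r[i]
    } else {
      (px - cells$cx[i])^2 + (py - cells$cy[i])^2 <= cells$r[i]^2
    }
    if (any(labels[inside] != 0L)) stop("cell masks must be disjoint")
    labels[inside] <- as.integer(cells$cell_id[i])
  }
  if (!any(labels == 0L)) stop("scene must keep at least one background region")
  structure(list(width = width, height = height,
                 pixel_size_um = pixel_size_um,
                 cells = cells, labels = labels),
            class = "scene_spec")
}

#' Two-channel acquisition plan
#'
#' Builds the timed sequence of illumination/acquisition steps of a
#' ratiometric time-lapse: one cycle every `period_s` seconds, each cycle
#' exposing both excitation channels back-to-back (`gap_s` apart) in the
#' requested order.
#'
#' @param n_cycles Number of ratio cycles.
#' @param period_s Cycle period, seconds (0.05 Hz default).
#' @param order `"500_first"` (the drift-minimizing protocol) or
#'   `"430_first"`.
#' @param exposure_430_ms,exposure_500_ms Exposure times, ms.
#' @param binning_430,binning_500 Camera binning per channel (1, 2, 4 or 8;
#'   must divide the field size).
#' @param intensity_430,intensity_500 Lamp attenuation per channel in
#'   `(0, 1]` (0.05 models the 5% neutral density filter).
#' @param gain_430,gain_500 Detector gain, counts per second per expression
#'   unit at full intensity. By default `gain_430` is derived from
#'   `gain_500` so that the resting ratio equals `ratio_scale` (the
#'   gain-balancing step of the recording protocol).
#' @param ratio_scale Target resting ratio of the gain balancing (default 1).
#' @param background Camera background level, counts.
#' @param gap_s Delay between the two exposures of one cycle, seconds.
#' @param t0_s Time of the first exposure, seconds.
#' @return A tibble of steps with columns `time_s`, `channel`,
#'   `exposure_ms`, `binning`, `intensity_factor`, `gain`,
#'   `background_level`; strictly increasing in time.
#' @export
acquisition_plan <- function(n_cycles, period_s = 20,
                             order = c("500_first", "430_first"),
                             exposure_430_ms = 50, exposure_500_ms = 50,
                             binning_430 = 4, binning_500 = 2,
                             intensity_430 = 0.05, intensity_500 = 1,
                             gain_430 = NULL, gain_500 = NULL,
                             ratio_scale = 1,
                             background = 100, gap_s = 0.1, t0_s = 0) {
  order <- match.arg(order)
  stopifnot(n_cycles >= 1, period_s > 2 * gap_s)
  chans <- if (order == "500_first") c(500L, 430L) else c(430L, 500L)
  if (is.null(gain_500)) gain_500 <- 1e6
  if (is.null(gain_430)) {
    gain_430 <- ratio_scale * gain_500 * (exposure_500_ms * intensity_500) /
      (exposure_430_ms * intensity_430)
  }
  cyc <- tibble::tibble(
    cycle = rep(seq_len(n_cycles), each = 2),
    slot = rep(c(0, 1), times = n_cycles),
    channel = rep(chans, times = n_cycles)
  )
  dplyr::mutate(
    cyc,
    time_s = t0_s + (.data$cycle - 1) * period_s + .data$slot * gap_s,
    exposure_ms = ifelse(.data$channel == 430L, exposure_430_ms,
                         exposure_500_ms),
    binning = as.integer(ifelse(.data$channel == 430L, binning_430,
                                binning_500)),
    intensity_factor = ifelse(.data$channel == 430L, intensity_430,
                              intensity_500),
    gain = ifelse(.data$channel == 430L, gain_430, gain_500),
    background_level = background
  )[, c("time_s", "channel", "exposure_ms", "binning", "intensity_factor",
        "gain", "background_level")]
}

#' Single-channel acquisition plan
#'
#' Repetitive acquisition through one excitation filter, optionally with
#' extra "conditioning" illumination events inserted between acquisitions
#' (the paradigm used to probe use-dependent photoinactivation: extra pulses
#' perturb the sensor but do not produce frames).
#'
#' @param n_frames Number of acquisitions.
#' @param channel 430 or 500.
#' @param period_s Acquisition period, seconds.
#' @param exposure_ms Exposure, ms.
#' @param binning Camera binning.
#' @param intensity Lamp attenuation in `(0, 1]`.
#' @param gain Detector gain, counts/s per expression unit.
#' @param background Background level, counts.
#' @param extra_pulses Optional tibble with columns `time_s`, `channel`,
#'   `duration_s`, `intensity_factor`: non-acquired illumination events.
#' @return A tibble of steps as in [acquisition_plan()] plus a logical
#'   `acquire` column.
#' @export
single_channel_plan <- function(n_frames, channel, period_s = 10,
                                exposure_ms = 50, binning = 2,
                                intensity = 1, gain = 1e6,
                                background = 100, extra_pulses = NULL) {
  steps <- tibble::tibble(
    time_s = (seq_len(n_frames) - 1) * period_s,
    channel = as.integer(channel),
    exposure_ms = exposure_ms,
    binning = as.integer(binning),
    intensity_factor = intensity,
    gain = gain,
    background_level = background,
    acquire = TRUE
  )
  if (!is.null(extra_pulses)) {
    ep <- tibble::tibble(
      time_s = extra_pulses$time_s,
      channel = as.integer(extra_pulses$channel),
      exposure_ms = extra_pulses$duration_s * 1000,
      binning = as.integer(binning),
      intensity_factor = extra_pulses$intensity_factor,
      gain = gain,
      background_level = background,
      acquire = FALSE
    )
    # drop acquisitions that would fall inside a conditioning pulse
    for (i in seq_len(nrow(ep))) {
      inside <- steps$time_s >= ep$time_s[i] - 0.05 &
        steps$time_s <= ep$time_s[i] + ep$exposure_ms[i] / 1000 + 0.05
      steps <- steps[!inside, ]
    }
    steps <- dplyr::arrange(dplyr::bind_rows(steps, ep), .data$time_s)
  }
  if (is.unsorted(steps$time_s, strictly = TRUE)) {
    stop("plan times must be strictly increasing")
  }
  steps
}

#' Camera noise model
#'
#' @param enabled Master switch; when `FALSE` frames are exact forward-model
#'   predictions.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param shot_noise When `TRUE`, adds signal-dependent noise with variance
#'   proportional to the expected counts (Gaussian approximation of shot
#'   noise).
#' @param shot_scale Variance per expected count.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(enabled = FALSE, read_noise_sd = 2,
                        shot_noise = TRUE, shot_scale = 1) {
  stopifnot(read_noise_sd >= 0, shot_scale >= 0)
  structure(list(enabled = enabled, read_noise_sd = read_noise_sd,
                 shot_noise = shot_noise, shot_scale = shot_scale),
            class = "noise_model")
}

block_mean <- function(img, b) {
  if (b == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% b != 0 || nc %% b != 0) stop("binning must divide the field size")
  # mean over b x b blocks
  m <- matrix(img, nrow = b)
  m <- colMeans(m)                       # (nr/b) x nc values, column-major
  m <- matrix(m, nrow = nr %/% b)        # rows binned
  m <- t(matrix(colMeans(matrix(t(m), nrow = b)), nrow = nc %/% b))
  m
}

block_replicate <- function(img, b) {
  if (b == 1) return(img)
  img[rep(seq_len(nrow(img)), each = b), rep(seq_len(ncol(img)), each = b),
      drop = FALSE]
}

#' Render one camera frame
#'
#' Every pixel of a cell takes that cell's [emitted_signal()] for the step's
#' illumination event; background pixels take the step's background level.
#' The unbinned field is aggregated by block mean to the step's binning and
#' noise is added when enabled. Rendering itself does not advance dark
#' states; the simulation loop does that once per illumination event.
#'
#' @param scene A [scene_spec()].
#' @param cl Per-cell chloride, mM (in `scene$cells` order).
#' @param state A [sensor_state()] with per-cell vectors.
#' @param step One row of an acquisition plan (list or one-row tibble).
#' @param noise A [noise_model()].
#' @param p A [photophysics_params()] object.
#' @param q_ref Resting reference quench factor (see [emitted_signal()]).
#' @return A numeric matrix of counts, dimensions `height/binning` by
#'   `width/binning`.
#' @export
render_frame <- function(scene, cl, state, step, noise = noise_model(),
                         p = photophysics_params(), q_ref = 1) {
  ev <- illumination_event(step$channel, step$exposure_ms / 1000,
                           step$intensity_factor)
  ys <- if ("yfp_scale" %in% names(scene$cells)) scene$cells$yfp_scale else 1
  vals <- emitted_signal(step$channel, cl, state, ev, step$gain,
                         background = 0, p = p, q_ref = q_ref,
                         yfp_scale = ys)
  idx <- match(scene$labels, scene$cells$cell_id)
  img <- vals[idx]
  img[is.na(img)] <- 0
  img <- img + step$background_level
  dim(img) <- dim(scene$labels)
  img <- block_mean(img, step$binning)
  if (noise$enabled) {
    n <- length(img)
    eps <- stats::rnorm(n, 0, noise$read_noise_sd)
    if (noise$shot_noise) {
      eps <- eps + stats::rnorm(n, 0, sqrt(pmax(img, 0) * noise$shot_scale))
    }
    img <- pmax(img + eps, 0)
  }
  img
}

#' Run a full synthetic imaging experiment
#'
#' Couples the three forward models: the bath/voltage protocol drives
#' per-cell chloride via [simulate_cli()], every illumination event darkens
#' the sensor via [dark_increment()] (with [dark_recovery()] in between),
#' and each acquiring step is rendered into a camera frame. All randomness
#' (camera noise) is governed by `seed`; identical calls are identical.
#'
#' @param config An experiment configuration as built by [canned_config()]
#'   or assembled manually: a list with elements `scene`, `plan`,
#'   `protocol`, `params` ([photophysics_params()]), `transport`
#'   ([transport_params()]), `membrane` ([membrane_model()]), `comps` (one
#'   [compartment_spec()] per cell, or a single one shared), `noise`
#'   ([noise_model()]), optional `q_ref_cl` (reference chloride for the
#'   430 nm channel normalization, default: each cell's initial chloride)
#'   and optional `dt` (integration step, s).
#' @param seed Integer seed for camera noise. Mandatory when noise is
#'   enabled.
#' @return An object of class `frame_stack`: a list with `frames` (list of
#'   count matrices), `meta` (per-frame tibble: `frame`, `time_s`,
#'   `channel`, `exposure_ms`, `binning`, `intensity_factor`), `truth`
#'   (tibble `time_s`, `cell_id`, `cl_mM`, `dark_430`, `dark_500`,
#'   `expression`), `roi` (integer label matrix), `scene` and `config`.
#' @export
generate_experiment <- function(config, seed = NULL) {
  noise <- config$noise %||% noise_model()
  if (noise$enabled && is.null(seed)) {
    stop("a seed is mandatory when camera noise is enabled")
  }
  scene <- config$scene
  plan <- config$plan
  if (!"acquire" %in% names(plan)) plan$acquire <- TRUE
  p <- config$params
  n_cells <- nrow(scene$cells)
  comps <- config$comps
  if (inherits(comps, "compartment_spec")) {
    comps <- rep(list(comps), n_cells)
  }
  stopifnot(length(comps) == n_cells)
  for (i in seq_len(n_cells)) comps[[i]]$name <- paste0("cell", i)
  dt <- config$dt %||% 0.1

  # dense chloride ground truth, one column per cell
  t_end <- if (nrow(plan) > 0) max(plan$time_s) + dt else dt
  dyn <- simulate_cli(config$protocol, config$transport, comps,
                      dt = dt, t_end = t_end,
                      mm = config$membrane %||% membrane_model())
  cl_mat <- matrix(dyn$cl_mM, ncol = n_cells)
  t_grid <- dyn$time_s[seq_len(nrow(cl_mat))]
  cl_at <- function(tt) {
    cl_mat[pmin(pmax(round(tt / dt) + 1, 1), nrow(cl_mat)), , drop = TRUE]
  }

  q_ref <- if (!is.null(config$q_ref_cl)) {
    yfp_quench_factor(config$q_ref_cl, p)
  } else {
    yfp_quench_factor(cl_mat[1, ], p)
  }

  state <- sensor_state(rep(0, n_cells), rep(0, n_cells),
                        scene$cells$expression, p)
  frames <- vector("list", sum(plan$acquire))
  meta <- plan[plan$acquire, , drop = FALSE]
  truth <- vector("list", nrow(plan))
  if (noise$enabled) {
    rng_state <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  t_prev <- if (nrow(plan) > 0) plan$time_s[1] else 0
  f_i <- 0L
  for (si in seq_len(nrow(plan))) {
    step <- plan[si, ]
    # recovery runs from the end of the previous exposure to this one
    state <- dark_recovery(state, max(step$time_s - t_prev, 0), p)
    t_prev <- step$time_s + step$exposure_ms / 1000
    cl_now <- cl_at(step$time_s)
    truth[[si]] <- tibble::tibble(
      time_s = step$time_s, cell_id = scene$cells$cell_id,
      cl_mM = cl_now, dark_430 = state$dark_430,
      dark_500 = state$dark_500, expression = scene$cells$expression
    )
    if (step$acquire) {
      f_i <- f_i + 1L
      frames[[f_i]] <- render_frame(scene, cl_now, state, step, noise, p,
                                    q_ref = q_ref)
    }
    ev <- illumination_event(step$channel, step$exposure_ms / 1000,
                             step$intensity_factor)
    state <- dark_increment(state, ev, p)
  }
  meta <- tibble::tibble(frame = seq_len(nrow(meta)),
                         time_s = meta$time_s, channel = meta$channel,
                         exposure_ms = meta$exposure_ms,
                         binning = meta$binning,
                         intensity_factor = meta$intensity_factor)
  structure(list(
    frames = frames, meta = meta,
    truth = if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(),
    roi = scene$labels, scene = scene, config = config, seed = seed,
    dynamics = dyn
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %d cells, %.0f s\n",
              length(x$frames), nrow(x$scene$cells),
              if (nrow(x$meta)) max(x$meta$time_s) else 0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
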