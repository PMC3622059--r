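#' Sensor photophysics parameters
#'
#' Bundles every constant of the Cl-Sensor forward model: the chloride
#' quenching curve of the YFP component, the channel composition of the
#' 430 nm-excited signal, and the kinetics of the two light-induced dark
#' (photoinactivated) pools.
#'
#' The default dark-pool constants are solved from two measured inhibition
#' points per excitation wavelength (see [derive_inactivation_params()]):
#' for 430 nm light, 2.8% inhibition of the YFP signal after a 20 ms
#' full-intensity pulse and 30% after 1 s; for 500 nm light, 0.34% after
#' 1 s and 3.0% after 10 s. Recovery time constants are set so that the
#' 430 nm pool recovers fully within a 5 min inter-pulse interval and the
#' 500 nm pool within about 3 min.
#'
#' @param ec50 Apparent chloride half-quench concentration of the YFP
#'   component, mM. The in vitro value is 30-50 mM; the apparent in-cell
#'   value fitted from calibration experiments is lower
#'   (see [solve_calibration_scale()]).
#' @param hill Hill exponent of the quenching curve (dimensionless).
#' @param residual_q Unquenchable YFP fraction, in `[0, 1)`.
#' @param alpha_rest Share of the 430 nm-excited signal contributed by the
#'   YFP component at the resting reference state, in `[0, 1]`. The CFP
#'   remainder is chloride- and light-insensitive. Default 0.287, the ratio
#'   of the fractional chloride responses of the two channels (6.2/21.6).
#' @param fmax_430,fmax_500 Maximal darkenable fraction of the YFP signal
#'   per excitation wavelength, in `[0, 1]`.
#' @param tau_inact_430,tau_inact_500 Darkening time constants at full lamp
#'   intensity, seconds of cumulative exposure.
#' @param tau_rec_430,tau_rec_500 Recovery time constants of the two dark
#'   pools, seconds.
#' @param slow_pool_weight Optional weight of a slowly recovering dark
#'   sub-pool, in `[0, 1]`. Default 0 (single-exponential recovery).
#'
#' @return An object of class `photophysics_params` (a named list).
#' @export
#' @examples
#' p <- photophysics_params()
#' yfp_quench_factor(c(0, 30, 150), p)
photophysics_params <- function(ec50 = 30,
                                hill = 1,
                                residual_q = 0,
                                alpha_rest = 0.287,
                                fmax_430 = 0.3023454,
                                tau_inact_430 = 0.2057991,
                                fmax_500 = 0.1207503,
                                tau_inact_500 = 35.01243,
                                tau_rec_430 = 50,
                                tau_rec_500 = 60,
                                slow_pool_weight = 0) {
  p <- list(
    ec50 = ec50, hill = hill, residual_q = residual_q,
    alpha_rest = alpha_rest,
    fmax_430 = fmax_430, tau_inact_430 = tau_inact_430,
    fmax_500 = fmax_500, tau_inact_500 = tau_inact_500,
    tau_rec_430 = tau_rec_430, tau_rec_500 = tau_rec_500,
    slow_pool_weight = slow_pool_weight
  )
  stopifnot(
    ec50 > 0, hill > 0,
    residual_q >= 0, residual_q < 1,
    alpha_rest >= 0, alpha_rest <= 1,
    fmax_430 >= 0, fmax_430 <= 1, fmax_500 >= 0, fmax_500 <= 1,
    tau_inact_430 > 0, tau_inact_500 > 0,
    tau_rec_430 > 0, tau_rec_500 > 0,
    slow_pool_weight >= 0, slow_pool_weight <= 1
  )
  structure(p, class = "photophysics_params")
}

#' @export
print.photophysics_params <- function(x, ...) {
  cat("<photophysics_params>\n")
  cat(sprintf("  quenching: ec50 = %.4g mM, hill = %.3g, residual_q = %.3g\n",
              x$ec50, x$hill, x$residual_q))
  cat(sprintf("  composition: alpha_rest = %.4g\n", x$alpha_rest))
  cat(sprintf("  430 nm pool: fmax = %.4g, tau_inact = %.4g s, tau_rec = %.4g s\n",
              x$fmax_430, x$tau_inact_430, x$tau_rec_430))
  cat(sprintf("  500 nm pool: fmax = %.4g, tau_inact = %.4g s, tau_rec = %.4g s\n",
              x$fmax_500, x$tau_inact_500, x$tau_rec_500))
  invisible(x)
}

#' Sensor dark-state / expression state
#'
#' Tracks the fraction of the YFP component held in each light-induced dark
#' pool and the relative expression level of the sensor. All fields may be
#' vectors (one element per cell).
#'
#' @param dark_430,dark_500 Dark fractions of the 430 nm- and 500 nm-induced
#'   pools. Each must lie in `[0, fmax]` for its pool.
#' @param expression Relative expression level (>= 0).
#' @param p A [photophysics_params()] object used to validate bounds.
#' @return An object of class `sensor_state`.
#' @export
sensor_state <- function(dark_430 = 0, dark_500 = 0, expression = 1,
                         p = photophysics_params()) {
  stopifnot(
    all(dark_430 >= 0), all(dark_430 <= p$fmax_430 + 1e-12),
    all(dark_500 >= 0), all(dark_500 <= p$fmax_500 + 1e-12),
    all(expression >= 0)
  )
  structure(list(dark_430 = dark_430, dark_500 = dark_500,
                 expression = expression),
            class = "sensor_state")
}

#' Illumination event
#'
#' One timed excitation episode at a single wavelength.
#'
#' @param wavelength Excitation channel, 430 or 500 (nm).
#' @param duration Exposure duration, seconds (>= 0).
#' @param intensity_factor Lamp attenuation in `(0, 1]`; 0.05 corresponds to
#'   the 5% transmission neutral density filter, 1 to the full lamp.
#' @return An object of class `illumination_event`.
#' @export
illumination_event <- function(wavelength, duration, intensity_factor = 1) {
  wavelength <- match.arg(as.character(wavelength), c("430", "500"))
  stopifnot(duration >= 0, intensity_factor > 0, intensity_factor <= 1)
  structure(list(wavelength = as.integer(wavelength), duration = duration,
                 intensity_factor = intensity_factor),
            class = "illumination_event")
}

#' Chloride quenching factor of the YFP component
#'
#' Single-site quenching curve
#' `Q(cl) = residual_q + (1 - residual_q) / (1 + (cl/ec50)^hill)`.
#' `Q` is 1 at zero chloride and decreases monotonically towards
#' `residual_q`.
#'
#' @param cl Intracellular chloride concentration, mM (vectorized, >= 0).
#' @param p A [photophysics_params()] object.
#' @return Quench factor in `(residual_q, 1]`.
#' @export
#' @examples
#' p <- photophysics_params(ec50 = 30, hill = 1, residual_q = 0)
#' yfp_quench_factor(30, p)  # 0.5 at the EC50
yfp_quench_factor <- function(cl, p) {
  if (any(cl < 0)) stop("chloride concentration must be non-negative")
  p$residual_q + (1 - p$residual_q) / (1 + (cl / p$ec50)^p$hill)
}

#' Light-induced darkening of the YFP component
#'
#' Advances the dark fraction of the pool matching the event's wavelength by
#' a saturating exponential in the delivered dose
#' (`dose = duration * intensity_factor`):
#' `d' = d + (fmax - d) * (1 - exp(-dose / tau_inact))`.
#' The other pool is untouched. Obeys reciprocity: only the product of
#' duration and intensity matters.
#'
#' @param state A [sensor_state()].
#' @param ev An [illumination_event()].
#' @param p A [photophysics_params()] object.
#' @return The updated `sensor_state`.
#' @export
dark_increment <- function(state, ev, p) {
  dose <- ev$duration * ev$intensity_factor
  if (ev$wavelength == 430L) {
    a <- 1 - exp(-dose / p$tau_inact_430)
    state$dark_430 <- state$dark_430 + (p$fmax_430 - state$dark_430) * a
  } else {
    a <- 1 - exp(-dose / p$tau_inact_500)
    state$dark_500 <- state$dark_500 + (p$fmax_500 - state$dark_500) * a
  }
  state
}

#' Recovery of the dark pools in darkness
#'
#' Each pool decays exponentially with its own recovery time constant:
#' `d(t + dt) = d(t) * exp(-dt / tau_rec)`.
#'
#' @param state A [sensor_state()].
#' @param dt Elapsed unilluminated time, seconds (>= 0).
#' @param p A [photophysics_params()] object.
#' @return The updated `sensor_state`.
#' @export
dark_recovery <- function(state, dt, p) {
  if (dt < 0) stop("dt must be non-negative")
  state$dark_430 <- state$dark_430 * exp(-dt / p$tau_rec_430)
  state$dark_500 <- state$dark_500 * exp(-dt / p$tau_rec_500)
  state
}

#' Steady-state dark fraction under repetitive pulsing
#'
#' Closed-form fixed point of the pulse-then-recover recurrence, evaluated at
#' pulse onset: with `a = 1 - exp(-dose/tau_inact)` and
#' `rho = exp(-interval/tau_rec)`,
#' `d* = fmax * a * rho / (1 - rho * (1 - a))`.
#'
#' @param pulse An [illumination_event()] repeated every `interval` seconds.
#' @param interval Pulse period, seconds (must exceed the pulse duration).
#' @param p A [photophysics_params()] object.
#' @return The steady-state dark fraction of the pulsed pool.
#' @export
steady_state_dark <- function(pulse, interval, p) {
  stopifnot(interval > pulse$duration)
  dose <- pulse$duration * pulse$intensity_factor
  if (pulse$wavelength == 430L) {
    a <- 1 - exp(-dose / p$tau_inact_430)
    rho <- exp(-interval / p$tau_rec_430)
    fmax <- p$fmax_430
  } else {
    a <- 1 - exp(-dose / p$tau_inact_500)
    rho <- exp(-interval / p$tau_rec_500)
    fmax <- p$fmax_500
  }
  fmax * a * rho / (1 - rho * (1 - a))
}

#' Emitted fluorescence signal of one channel
#'
#' Camera counts collected during one illumination event. The 500 nm channel
#' sees only the YFP component and is fully chloride- and dark-state
#' sensitive; the 430 nm channel mixes a photostable, chloride-insensitive
#' CFP portion with a YFP portion weighted by `alpha_rest`:
#'
#' * `F500 = gain * expression * dose * Qr * (1 - d430) * (1 - d500) + background`
#' * `F430 = gain * expression * dose * ((1 - alpha_rest) +
#'    alpha_rest * Qr * (1 - d430) * (1 - d500)) + background`
#'
#' where `dose = duration * intensity_factor` and
#' `Qr = yfp_quench_factor(cl, p) / q_ref` is the quench factor relative to
#' the configuration's resting reference state (`q_ref = 1` references zero
#' chloride).
#'
#' @param channel 430 or 500.
#' @param cl Intracellular chloride, mM (vectorized together with `state`).
#' @param state A [sensor_state()] (fields may be vectors, one per cell).
#' @param ev The [illumination_event()] of the acquisition.
#' @param gain Counts per second per expression unit at full lamp intensity.
#' @param background Camera background offset, counts.
#' @param p A [photophysics_params()] object.
#' @param q_ref Quench factor of the resting reference state used to
#'   normalize the YFP share of the 430 nm channel (default 1).
#' @param yfp_scale Per-cell multiplicative offset on the YFP component
#'   (default 1). This is the hook for cell-to-cell differences in the
#'   intracellular milieu (pH, organic anions) that quench YFP
#'   independently of chloride; it rescales the YFP portion of both
#'   channels and thereby shifts the cell's absolute ratio without
#'   affecting its chloride response kinetics.
#' @return Expected counts (no noise).
#' @export
emitted_signal <- function(channel, cl, state, ev, gain, background, p,
                           q_ref = 1, yfp_scale = 1) {
  channel <- as.integer(as.character(channel))
  dose <- ev$duration * ev$intensity_factor
  qr <- yfp_scale * yfp_quench_factor(cl, p) / q_ref
  live <- (1 - state$dark_430) * (1 - state$dark_500)
  comp <- if (channel == 430L) {
    (1 - p$alpha_rest) + p$alpha_rest * qr * live
  } else {
    qr * live
  }
  gain * state$expression * dose * comp + background
}

#' Derive dark-pool constants from two inhibition measurements
#'
#' Solves the two-equation system
#' `fmax * (1 - exp(-dose1/tau)) = frac1` and
#' `fmax * (1 - exp(-dose2/tau)) = frac2`
#' for `(fmax, tau)` by root-finding on the dose ratio. This is how the
#' package defaults were obtained from the two printed inhibition fractions
#' per excitation wavelength.
#'
#' @param frac1,dose1 Inhibition fraction after the shorter exposure and its
#'   dose in seconds at full intensity.
#' @param frac2,dose2 Same for the longer exposure (`dose2 > dose1`,
#'   `frac2 > frac1`).
#' @return A list with elements `fmax` and `tau_inact`.
#' @export
#' @examples
#' derive_inactivation_params(0.028, 0.02, 0.30, 1)   # 430 nm pool
#' derive_inactivation_params(0.0034, 1, 0.030, 10)   # 500 nm pool
derive_inactivation_params <- function(frac1, dose1, frac2, dose2) {
  stopifnot(dose2 > dose1, frac2 > frac1, frac1 > 0, frac2 < 1)
  g <- function(tau) {
    (1 - exp(-dose1 / tau)) / (1 - exp(-dose2 / tau)) - frac1 / frac2
  }
  tau <- stats::uniroot(g, c(1e-4 * dose2, 1e4 * dose2), tol = 1e-14)$root
  list(fmax = frac2 / (1 - exp(-dose2 / tau)), tau_inact = tau)
}

#' Solve the in-cell calibration scale from the ratio dynamic range
#'
#' Under the channel-composition model with `hill = 1`, `residual_q = 0` and
#' a zero-chloride reference state, the fluorescence ratio is linear in
#' chloride: `R(cl) = r0 * (1 + (1 - alpha_rest) * cl / ec50)`. Given the
#' ratio at two chloride concentrations this 2x2 system has the closed-form
#' solution implemented here; with the default dynamic range (0.7 ratio
#' units at 5 mM, 4.0 at 150 mM) it yields an apparent in-cell EC50 of about
#' 18.4 mM and a zero-chloride ratio `r0` of about 0.586.
#'
#' @param r_low,cl_low Ratio and chloride (mM) at the low anchor point.
#' @param r_high,cl_high Ratio and chloride (mM) at the high anchor point.
#' @param alpha_rest YFP share of the 430 nm channel (see
#'   [photophysics_params()]).
#' @return A list with elements `ec50` (mM) and `r0` (ratio units at zero
#'   chloride).
#' @export
#' @examples
#' solve_calibration_scale()
solve_calibration_scale <- function(r_low = 0.7, cl_low = 5,
                                    r_high = 4.0, cl_high = 150,
                                    alpha_rest = 0.287) {
  ratio <- r_high / r_low
  w <- (ratio - 1) / (cl_high - cl_low * ratio)
  stopifnot(w > 0)
  list(ec50 = (1 - alpha_rest) / w, r0 = r_low / (1 + cl_low * w))
}

#' Read photophysics parameters from a configuration list
#'
#' Builds a [photophysics_params()] object from the `photophysics:` block of
#' a parsed YAML/JSON configuration (e.g. the `config.yaml` echo written by
#' [run_simulate()]). Field names match the constructor arguments exactly;
#' unknown fields are rejected.
#'
#' @param block A named list (typically `yaml::read_yaml(...)$photophysics`).
#' @return A `photophysics_params` object.
#' @export
photophysics_from_config <- function(block) {
  known <- names(formals(photophysics_params))
  extra <- setdiff(names(block), known)
  if (length(extra)) {
    stop("unknown photophysics field(s): ", paste(extra, collapse = ", "))
  }
  do.call(photophysics_params, block)
}
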