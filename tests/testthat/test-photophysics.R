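test_that("quench factor is 1 at zero chloride, half at EC50, and strictly decreasing", {
  p <- photophysics_params(ec50 = 30, hill = 1, residual_q = 0)
  expect_identical(yfp_quench_factor(0, p), 1)
  expect_equal(yfp_quench_factor(30, p), 0.5)
  cl <- seq(0, 300, by = 0.5)
  q <- yfp_quench_factor(cl, p)
  expect_true(all(diff(q) < 0))
  expect_true(all(q > 0 & q <= 1))
  # bounded below by the unquenchable fraction
  p2 <- photophysics_params(residual_q = 0.2)
  expect_true(all(yfp_quench_factor(cl, p2) > 0.2))
  expect_error(yfp_quench_factor(-1, p), "non-negative")
})

test_that("dark-pool constants are re-derived from the two measured points per wavelength", {
  d430 <- derive_inactivation_params(0.028, 0.02, 0.30, 1)
  expect_equal(d430$fmax, 0.3023454, tolerance = 1e-6)
  expect_equal(d430$tau_inact, 0.2057991, tolerance = 1e-6)
  d500 <- derive_inactivation_params(0.0034, 1, 0.030, 10)
  expect_equal(d500$fmax, 0.1207503, tolerance = 1e-6)
  expect_equal(d500$tau_inact, 35.01243, tolerance = 1e-6)
  # the derived pair reproduces both anchor points exactly
  p <- photophysics_params()
  s <- sensor_state(p = p)
  d1 <- dark_increment(s, illumination_event(430, 0.02), p)$dark_430
  d2 <- dark_increment(s, illumination_event(430, 1), p)$dark_430
  expect_equal(d1, 0.028, tolerance = 1e-6)
  expect_equal(d2, 0.30, tolerance = 1e-6)
})

test_that("darkening saturates at fmax, leaves the other pool untouched, and obeys reciprocity", {
  p <- photophysics_params()
  s <- sensor_state(p = p)
  expect_identical(dark_increment(s, illumination_event(430, 0), p), s)
  long <- dark_increment(s, illumination_event(430, 1e5), p)
  expect_equal(long$dark_430, p$fmax_430, tolerance = 1e-12)
  expect_identical(long$dark_500, 0)
  # reciprocity: (t, i) and (t * i, 1) deliver the same dose
  set.seed(11)
  for (i in 1:20) {
    dur <- runif(1, 0.01, 5)
    int <- runif(1, 0.01, 1)
    a <- dark_increment(s, illumination_event(500, dur, int), p)
    b <- dark_increment(s, illumination_event(500, dur * int, 1), p)
    expect_equal(a$dark_500, b$dark_500, tolerance = 1e-12)
  }
})

test_that("dark recovery is exponential and complete within a 5 min interval", {
  p <- photophysics_params()
  s <- sensor_state(dark_430 = 0.1, dark_500 = 0.05, p = p)
  expect_identical(dark_recovery(s, 0, p), s)
  r <- dark_recovery(s, p$tau_rec_430, p)
  expect_equal(r$dark_430, 0.1 / exp(1), tolerance = 1e-12)
  r300 <- dark_recovery(s, 300, p)
  expect_lt(r300$dark_430 / 0.1, 0.003)  # e^-6 with tau_rec = 50 s
  expect_error(dark_recovery(s, -1, p), "non-negative")
})

test_that("steady-state dark fraction matches brute-force iteration on random parameter sets", {
  brute <- function(pulse, interval, p, n = 500) {
    s <- sensor_state(p = p)
    d_pre <- 0
    for (i in seq_len(n)) {
      d_pre <- if (pulse$wavelength == 430L) s$dark_430 else s$dark_500
      s <- dark_increment(s, pulse, p)
      s <- dark_recovery(s, interval, p)
    }
    d_pre
  }
  set.seed(21)
  for (i in 1:20) {
    p <- photophysics_params(
      fmax_430 = runif(1, 0.05, 0.6), tau_inact_430 = runif(1, 0.05, 2),
      fmax_500 = runif(1, 0.05, 0.6), tau_inact_500 = runif(1, 1, 60),
      tau_rec_430 = runif(1, 10, 120), tau_rec_500 = runif(1, 10, 120)
    )
    wl <- sample(c(430, 500), 1)
    pulse <- illumination_event(wl, runif(1, 0.005, 1), runif(1, 0.05, 1))
    interval <- runif(1, 2, 30)
    expect_lt(abs(steady_state_dark(pulse, interval, p) -
                    brute(pulse, interval, p)), 1e-8)
  }
  expect_equal(steady_state_dark(illumination_event(430, 1e-12), 10,
                                 photophysics_params()), 0,
               tolerance = 1e-10)
})

test_that("routine 50 ms/10 s acquisition at 500 nm depresses the YFP signal by < 0.5%", {
  p <- photophysics_params()
  d <- steady_state_dark(illumination_event(500, 0.05), 10, p)
  expect_lt(d, 0.005)
})

test_that("emitted signal composition: background floor, dark-state linearity, channel coupling", {
  p <- photophysics_params()
  ev <- illumination_event(500, 0.05)
  s0 <- sensor_state(expression = 0, p = p)
  expect_identical(emitted_signal(500, 10, s0, ev, gain = 100,
                                  background = 7, p = p), 7)
  # F500 scales exactly by (1 - d500)
  s <- sensor_state(expression = 2, p = p)
  sd <- sensor_state(dark_500 = 0.05, expression = 2, p = p)
  f <- function(st) emitted_signal(500, 10, st, ev, 100, 0, p)
  expect_equal(f(sd) / f(s), 1 - 0.05, tolerance = 1e-12)
  # a -21.6% YFP change maps to a -6.2% 430 nm change through alpha_rest
  alpha <- 0.062 / 0.216
  pa <- photophysics_params(alpha_rest = alpha)
  f430 <- function(qr) (1 - alpha) + alpha * qr
  expect_equal(1 - f430(1 - 0.216) / f430(1), 0.062, tolerance = 1e-12)
  expect_equal(alpha, 0.287, tolerance = 1e-3)
})

test_that("calibration scale solves the printed dynamic range exactly", {
  cal <- solve_calibration_scale()
  r_of <- function(cl) cal$r0 * (1 + (1 - 0.287) * cl / cal$ec50)
  expect_equal(r_of(5), 0.7, tolerance = 1e-12)
  expect_equal(r_of(150), 4.0, tolerance = 1e-12)
  expect_equal(cal$ec50, 18.365, tolerance = 1e-4)
  expect_equal(cal$r0, 0.5862, tolerance = 1e-4)
})

test_that("parameter and state invariants are enforced", {
  expect_error(photophysics_params(ec50 = -1))
  expect_error(photophysics_params(residual_q = 1))
  expect_error(sensor_state(dark_430 = 0.9))  # above fmax_430
  expect_error(illumination_event(430, 1, 0))
  expect_error(illumination_event(450, 1))
})
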