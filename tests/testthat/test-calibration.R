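test_that("reversal potential is recovered from a voltage-current line", {
  vcr <- tibble::tibble(vh_mv = c(-107, -95, -60, -45))
  vcr$i_pa <- 0.5 * (vcr$vh_mv + 84)
  expect_equal(estimate_reversal(vcr), -84, tolerance = 1e-12)
  # +-2 pA current noise keeps the estimate within 2 mV (Monte Carlo)
  set.seed(14)
  errs <- replicate(200, {
    noisy <- vcr
    noisy$i_pa <- noisy$i_pa + rnorm(4, 0, 2)
    estimate_reversal(noisy) + 84
  })
  expect_lt(stats::median(abs(errs)), 2)
  flat <- tibble::tibble(vh_mv = c(-80, -60), i_pa = c(1, 1))
  expect_error(estimate_reversal(flat), "zero-slope")
  expect_error(estimate_reversal(tibble::tibble(vh_mv = -80, i_pa = 1)),
               "distinct")
})

test_that("simulated perforated-patch data give the expected resting reversal", {
  vcr <- simulate_vcr(cl_i = 5.7, cl_o = 150)
  expect_equal(estimate_reversal(vcr), nernst_ecl(150, 5.7),
               tolerance = 1e-9)
  expect_equal(invert_nernst(estimate_reversal(vcr), 150), 5.7,
               tolerance = 1e-9)
})

test_that("the 4PL fit exactly recovers its own model and round-trips through the inverse", {
  true <- list(r_min = 0.55, r_max = 4.6, log_ec50 = log10(22), slope_h = 0.9)
  cl <- c(1, 3, 8, 20, 55, 150)
  r <- true$r_min + (true$r_max - true$r_min) /
    (1 + 10^(true$slope_h * (true$log_ec50 - log10(cl))))
  fit <- fit_dose_response(tibble::tibble(cl_mM = cl, r = r))
  expect_lt(max(abs(predict(fit, cl) - r)), 1e-8)
  expect_equal(fit$r_max, true$r_max, tolerance = 1e-6)
  # closed-form inverse round-trips to 1e-10 relative
  probe <- c(2, 5, 30, 120)
  expect_equal(cl_from_ratio(predict(fit, probe), fit) / probe,
               rep(1, 4), tolerance = 1e-10)
  # midpoint ratio maps to the apparent EC50
  mid <- (fit$r_min + fit$r_max) / 2
  expect_equal(cl_from_ratio(mid, fit), 10^fit$log_ec50, tolerance = 1e-9)
  expect_error(cl_from_ratio(fit$r_min - 0.1, fit), "floor")
  expect_error(cl_from_ratio(fit$r_max + 0.1, fit), "ceiling")
  expect_error(fit_dose_response(tibble::tibble(cl_mM = c(1, 2), r = c(1, 2))),
               "at least 4")
  expect_error(fit_dose_response(tibble::tibble(cl_mM = c(10, 12, 14, 16),
                                                r = 1:4)), "decade")
})

test_that("dose-response tidiers expose the fitted parameters", {
  cl <- c(2, 5, 10, 20, 50, 150)
  r <- 0.6 + (5 - 0.6) / (1 + 10^(1.1 * (log10(25) - log10(cl))))
  fit <- fit_dose_response(tibble::tibble(cl_mM = cl, r = r))
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("r_min", "r_max", "log_ec50", "slope_h"))
  gl <- generics::glance(fit)
  expect_equal(gl$ec50_app_mM, 25, tolerance = 1e-4)
  expect_equal(gl$n, 6)
})

test_that("influx assay takes the nearest samples at -30 s and +5 min", {
  rt <- tibble::tibble(roi_id = 1L, time_s = 0:40 * 20, r = 1)
  expect_equal(kcc2_influx_assay(rt, 360)$value, 0)
  rt2 <- rt
  rt2$r[rt2$time_s >= 360] <- 1 + (rt2$time_s[rt2$time_s >= 360] - 360) / 100
  expect_equal(kcc2_influx_assay(rt2, 360)$value, 3)
  expect_error(kcc2_influx_assay(rt[1:3, ], 360), "window")
})

test_that("extrusion assay reports tau*ln2 on synthetic exponentials", {
  tt <- 0:60 * 20
  load <- tt >= 100 & tt < 300
  r <- ifelse(tt < 300, ifelse(load, 3, 1), 1 + 2 * exp(-(tt - 300) / 200))
  rt <- tibble::tibble(roi_id = 1L, time_s = tt, r = r)
  res <- extrusion_assay(rt, c(100, 310))
  expect_equal(res$value * 60, 200 * log(2), tolerance = 0.05)
  expect_error(extrusion_assay(tibble::tibble(roi_id = 1, time_s = tt,
                                              r = rep(1, 61)), c(100, 310)),
               "peak")
})

test_that("KS statistic equals the brute-force maximum ECDF gap", {
  brute_d <- function(a, b) {
    grid <- sort(c(a, b))
    max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  }
  set.seed(77)
  for (i in 1:15) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$d, brute_d(a, b), tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(ks_two_sample(x, x)$d, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$d, 1)
  expect_error(ks_two_sample(1:3, 1:10), "at least 5")
})
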