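test_that("Nernst potential and its inverse round-trip at 59.16 mV/decade", {
  expect_identical(nernst_ecl(150, 150), 0)
  expect_equal(nernst_ecl(150, 15), -59.16, tolerance = 1e-12)
  expect_equal(nernst_ecl(150, 5.7), -84.0, tolerance = 1e-3)
  expect_equal(invert_nernst(0, 150), 150)
  expect_equal(invert_nernst(-59.16, 150), 15, tolerance = 1e-12)
  expect_equal(invert_nernst(-84, 150), 5.70, tolerance = 1e-3)
  set.seed(5)
  for (i in 1:25) {
    cl_i <- runif(1, 0.5, 150)
    cl_o <- runif(1, 50, 200)
    e <- nernst_ecl(cl_o, cl_i)
    expect_equal(invert_nernst(e, cl_o) / cl_i, 1, tolerance = 1e-12)
  }
  expect_error(nernst_ecl(150, 0), "positive")
})

test_that("channel flux sign follows the driving force", {
  comp <- compartment_spec()
  expect_identical(channel_flux(1e-3, 0.5, -84, -84, comp), 0)
  expect_gt(channel_flux(1e-3, 0.5, -45, -84, comp), 0)   # influx
  expect_lt(channel_flux(1e-3, 0.5, -107, -84, comp), 0)  # efflux
})

test_that("KCC2 flux vanishes at product equilibrium and follows the summed gradient", {
  comp <- compartment_spec()
  expect_equal(kcc2_flux(2.5, 150, 140, 2.5 * 150 / 140, u = 0.05,
                         comp = comp), 0, tolerance = 1e-12)
  expect_lt(kcc2_flux(2.5, 150, 140, 20, u = 0.05, comp = comp), 0)
  expect_gt(kcc2_flux(140, 150, 140, 7, u = 0.05, comp = comp), 0)
  # sign equals sign of the product difference on random states
  set.seed(6)
  for (i in 1:20) {
    k_o <- runif(1, 2, 140); cl_i <- runif(1, 0.5, 60)
    fl <- kcc2_flux(k_o, 150, 140, cl_i, u = 0.05, comp = comp)
    expect_identical(sign(fl), sign(k_o * 150 - 140 * cl_i))
  }
  # furosemide at the default block removes 85% of the flux
  full <- kcc2_flux(140, 150, 140, 7, u = 0.05, comp = comp)
  blocked <- kcc2_flux(140, 150, 140, 7, u = 0.05, furosemide_factor = 1,
                       comp = comp)
  expect_equal(blocked / full, 0.15, tolerance = 1e-12)
})

test_that("membrane potential model: clamp, full depolarization, resting value", {
  expect_identical(membrane_potential(bath_solution(),
                                      membrane_model(clamp = -80)), -80)
  sol140 <- bath_solution(na = 2.5, k = 140)
  expect_equal(membrane_potential(sol140, membrane_model()), 0,
               tolerance = 1e-12)
  vm <- membrane_potential(bath_solution(), membrane_model())
  expect_equal(vm, -72.4, tolerance = 1e-2)
  # monotone increasing in bath potassium
  vms <- sapply(c(2.5, 10, 25, 100, 140), function(k)
    membrane_potential(bath_solution(na = 142.5 - k, k = k),
                       membrane_model()))
  expect_true(all(diff(vms) > 0))
})

test_that("bath chloride is computed from the salts", {
  expect_equal(bath_solution()$cl_o, 150.5)
  expect_equal(bath_solution(na = 42.5, k = 100)$cl_o, 150.5)
  lib <- solution_library()
  expect_equal(lib$kcl140$cl_o, lib$control$cl_o)
})

test_that("chloride simulation holds steady with zero fluxes and is step-size converged", {
  prot <- list(protocol_event(0, bath_solution()))
  tp0 <- transport_params(cl_leak = 9)
  out <- simulate_cli(prot, tp0, compartment_spec(), dt = 0.1, t_end = 50)
  expect_true(all(out$cl_mM == 9))

  cfg <- canned_config("fig5_glycine_kcl")
  run <- function(dt) {
    simulate_cli(cfg$protocol, cfg$transport, compartment_spec(), dt = dt,
                 t_end = 1200, record_every = round(20 / dt))$cl_mM
  }
  a <- run(0.1)
  b <- run(0.05)
  expect_lt(max(abs(a - b) / pmax(abs(a), 0.1)), 0.005)
})

test_that("simulation rejects malformed protocols", {
  tp <- transport_params(cl_leak = 9)
  bad <- list(protocol_event(10, bath_solution()),
              protocol_event(0, bath_solution()))
  expect_error(simulate_cli(bad, tp, compartment_spec(), t_end = 20),
               "time-ordered")
  expect_error(simulate_cli(list(protocol_event(0, bath_solution())),
                            tp, compartment_spec(), dt = 0, t_end = 20),
               "positive")
  expect_error(simulate_cli(list(protocol_event(5, bath_solution())),
                            tp, compartment_spec(), t_end = 20),
               "t = 0")
})

test_that("chloride is floored at 0.1 mM", {
  # strong efflux: clamp far below the reversal potential
  prot <- list(protocol_event(0, bath_solution(), clamp_mv = -150))
  tp <- transport_params(g_glyr = 1, p_tonic = 1, cl_leak = 9)
  out <- simulate_cli(prot, tp, compartment_spec(), dt = 0.1, t_end = 60)
  expect_true(all(out$cl_mM >= 0.1))
  expect_equal(min(out$cl_mM), 0.1)
})
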