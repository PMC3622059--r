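make_scene <- function(expr = c(2000, 4000)) {
  grid_scene(length(expr), expression = expr)
}

flat_config <- function(scene, plan, noise = noise_model(), cl_rest = 9) {
  list(scene = scene, plan = plan,
       protocol = list(protocol_event(0, bath_solution())),
       params = photophysics_params(),
       transport = transport_params(cl_leak = cl_rest),
       membrane = membrane_model(), comps = compartment_spec(),
       noise = noise, q_ref_cl = cl_rest)
}

test_that("block mean and replication act as exact inverses on pure blocks", {
  m <- matrix(c(1, 5, 3, 7), 2)
  expect_equal(align_binning(m, 1, 2), matrix(4, 1, 1))
  expect_equal(align_binning(matrix(4), 2, 1), matrix(4, 2, 2))
  set.seed(3)
  img <- matrix(runif(64 * 48), 48, 64)
  down <- align_binning(img, 1, 4)
  expect_equal(mean(down), mean(img), tolerance = 1e-12)
  # down-then-up-then-down equals a single down
  expect_equal(align_binning(align_binning(down, 4, 1), 1, 4), down,
               tolerance = 1e-12)
  expect_error(align_binning(img, 2, 3), "integer")
})

test_that("binning conservation: rendering at binning b equals block-mean of binning 1", {
  scene <- make_scene()
  st <- sensor_state(expression = scene$cells$expression)
  p <- photophysics_params()
  step1 <- list(channel = 500L, exposure_ms = 50, binning = 1L,
                intensity_factor = 1, gain = 100, background_level = 50,
                time_s = 0)
  for (b in c(2L, 4L, 8L)) {
    stepb <- step1
    stepb$binning <- b
    f1 <- render_frame(scene, cl = c(10, 10), st, step1, p = p)
    fb <- render_frame(scene, cl = c(10, 10), st, stepb, p = p)
    expect_equal(fb, align_binning(f1, 1, b), tolerance = 1e-12)
  }
})

test_that("noise-free frames equal the forward model exactly; zero expression gives flat background", {
  scene <- make_scene()
  plan <- acquisition_plan(3, gain_500 = 100)
  cfg <- flat_config(scene, plan)
  stk <- generate_experiment(cfg)
  tr <- extract_traces(stk)
  # predicted counts from the forward model, using the recorded dark states
  p <- cfg$params
  q_ref <- yfp_quench_factor(9, p)
  for (i in seq_len(nrow(stk$meta))) {
    info <- stk$meta[i, ]
    truth <- stk$truth[stk$truth$time_s == info$time_s, ]
    ev <- illumination_event(info$channel, info$exposure_ms / 1000,
                             info$intensity_factor)
    gain <- plan$gain[plan$time_s == info$time_s]
    pred <- emitted_signal(info$channel, truth$cl_mM,
                           sensor_state(truth$dark_430, truth$dark_500,
                                        truth$expression, p),
                           ev, gain, background = 0, p = p, q_ref = q_ref)
    got <- tr$value[tr$time_s == info$time_s & tr$channel == info$channel]
    expect_equal(got, pred, tolerance = 1e-9)
  }

  scene0 <- make_scene(c(0, 0))
  stk0 <- generate_experiment(flat_config(scene0, plan[1, ]))
  expect_true(all(stk0$frames[[1]] == plan$background_level[1]))
})

test_that("same seed gives bit-identical stacks; different seeds differ", {
  scene <- make_scene()
  plan <- acquisition_plan(2, gain_500 = 100)
  cfg <- flat_config(scene, plan, noise_model(enabled = TRUE))
  a <- generate_experiment(cfg, seed = 9)
  b <- generate_experiment(cfg, seed = 9)
  cc <- generate_experiment(cfg, seed = 10)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, cc$frames))
  expect_error(generate_experiment(cfg), "seed is mandatory")
})

test_that("noise-free ratio is independent of expression to 1e-9", {
  exprs <- c(500, 1500, 3000, 6000, 12000)
  scene <- make_scene(exprs)
  plan <- acquisition_plan(2, gain_500 = 100)
  stk <- generate_experiment(flat_config(scene, plan))
  rt <- pair_ratio(extract_traces(stk))
  r_by_cell <- tapply(rt$r, rt$roi_id, mean)
  expect_lt(diff(range(r_by_cell)) / mean(r_by_cell), 1e-9)
})

test_that("an empty plan yields an empty stack but non-empty ground truth dynamics", {
  scene <- make_scene()
  plan <- acquisition_plan(1, gain_500 = 100)[0, ]
  cfg <- flat_config(scene, plan)
  stk <- generate_experiment(cfg)
  expect_length(stk$frames, 0)
  expect_gt(nrow(stk$dynamics), 0)
})

test_that("scene invariants: disjoint masks and a background region", {
  cells <- tibble::tibble(cell_id = 1:2, cx = c(5, 8), cy = c(5, 5),
                          r = c(4, 4), expression = 1)
  expect_error(scene_spec(16, 16, cells = cells), "disjoint")
  big <- tibble::tibble(cell_id = 1L, cx = 0, cy = 0, r = 16,
                        shape = "square", expression = 1)
  expect_error(scene_spec(16, 16, cells = big), "background")
})
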