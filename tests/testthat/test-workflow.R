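short_fig5 <- function() {
  cfg <- canned_config("fig5_glycine_kcl")
  cfg$plan <- cfg$plan[cfg$plan$time_s <= 201, ]
  cfg
}

test_that("run_simulate writes the full artifact set deterministically", {
  cfg <- short_fig5()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths <- run_simulate(cfg, d1)
  expect_true(all(file.exists(unlist(paths))))
  run_simulate(cfg, d2)
  for (f in c("stack.tiff", "meta.jsonl", "truth.csv", "roi.tiff")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # frame count matches the plan
  meta <- readLines(file.path(d1, "meta.jsonl"))
  expect_length(meta, nrow(cfg$plan))

  # noise requires a seed; with a seed, reruns are identical
  cfgn <- cfg
  cfgn$noise <- noise_model(enabled = TRUE)
  expect_error(run_simulate(cfgn, withr::local_tempdir()), "seed")
  d3 <- withr::local_tempdir(); d4 <- withr::local_tempdir()
  run_simulate(cfgn, d3, seed = 4)
  run_simulate(cfgn, d4, seed = 4)
  expect_identical(unname(tools::md5sum(file.path(d3, "stack.tiff"))),
                   unname(tools::md5sum(file.path(d4, "stack.tiff"))))
})

test_that("read_run round-trips frames, metadata and ROI mask", {
  cfg <- short_fig5()
  d <- withr::local_tempdir()
  run_simulate(cfg, d)
  run <- read_run(d)
  stk <- generate_experiment(cfg)
  expect_equal(length(run$frames), length(stk$frames))
  # 16-bit quantization at write time
  expect_equal(run$frames[[1]], round(stk$frames[[1]]), tolerance = 1e-12)
  expect_identical(dim(run$roi), dim(stk$roi))
  expect_identical(sort(unique(as.vector(run$roi))),
                   sort(unique(as.vector(stk$roi))))
  expect_error(read_run(withr::local_tempdir()), "missing run artifact")
})

test_that("run_analyze writes trace/ratio/metric reports and is idempotent", {
  cfg <- short_fig5()
  d <- withr::local_tempdir()
  run_simulate(cfg, d)
  out1 <- run_analyze(d)
  expect_true(all(file.exists(unlist(out1$paths))))
  # one ratio row per ROI per complete cycle
  n_cycles <- sum(cfg$plan$channel == 430L)
  expect_equal(nrow(out1$ratios), n_cycles * nrow(cfg$scene$cells))
  ratios1 <- readr::read_csv(out1$paths$ratios, show_col_types = FALSE)
  out2 <- run_analyze(d)
  ratios2 <- readr::read_csv(out2$paths$ratios, show_col_types = FALSE)
  expect_identical(ratios1, ratios2)

  bad <- matrix(0L, nrow(generate_experiment(cfg)$roi),
                ncol(generate_experiment(cfg)$roi))
  bad[1:2, 1:2] <- 99L
  expect_error(run_analyze(d, rois = bad), "99")
  expect_error(run_analyze(d, rois = matrix(1L, 2, 2)), "shape")
})

test_that("the extrusion assay runs end-to-end through the file interface", {
  cfg <- canned_config("fig7_extrusion")
  cfg$plan <- cfg$plan[cfg$plan$time_s <= 1101, ]
  d <- withr::local_tempdir()
  run_simulate(cfg, d)
  out <- run_analyze(d, assay = "extrusion")
  expect_equal(nrow(out$assay), nrow(cfg$scene$cells))
  expect_true(all(out$assay$kind == "extrusion_half_time"))
  expect_equal(out$assay$value, rep(2, 3), tolerance = 0.05)
})

test_that("photophysics parameters round-trip through the YAML config echo", {
  cfg <- short_fig5()
  cfg$params <- photophysics_params(ec50 = 42, residual_q = 0.1)
  d <- withr::local_tempdir()
  run_simulate(cfg, d)
  echo <- yaml::read_yaml(file.path(d, "config.yaml"))
  p2 <- photophysics_from_config(echo$photophysics)
  expect_equal(unclass(p2), unclass(cfg$params))
  expect_error(photophysics_from_config(list(ec50 = 1, bogus = 2)), "bogus")
})
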