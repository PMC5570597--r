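test_that("presets resolve, validate, and reject unknown names", {
  for (nm in c("trabecula_ve", "strength_interval", "polarity_volume",
               "vt_shocks", "energy_table")) {
    cfg <- preset_experiment(nm, scale = "smoke")
    expect_s3_class(cfg, "run_config")
    expect_silent(validate_run_config(cfg))
  }
  expect_error(preset_experiment("no_such_thing"), "available")
  cfg <- preset_experiment("energy_table")
  cfg$protocol$R <- NULL
  expect_error(validate_run_config(cfg), "lacks protocol fields")
  cfg2 <- preset_experiment("energy_table")
  cfg2$protocol$voltages <- "ten"
  expect_error(validate_run_config(cfg2), "numeric")
})

test_that("the energy preset computes the protocol energies and runs are reproducible", {
  d1 <- tempfile("runA_"); d2 <- tempfile("runB_")
  r1 <- run_experiment(preset_experiment("energy_table"), d1, quiet = TRUE)
  r2 <- run_experiment(preset_experiment("energy_table"), d2, quiet = TRUE)
  expect_equal(r1$summary$energy_J, c(1, 9, 25, 100) * 0.01 / 36.4,
               tolerance = 1e-12)
  s1 <- readLines(file.path(d1, "summary.csv"))
  s2 <- readLines(file.path(d2, "summary.csv"))
  expect_identical(s1, s2)            # byte-identical summaries
  m <- r1$manifest
  expect_true(all(c("config.yaml", "run.log", "summary.csv",
                    "summary.json") %in% m$file))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a smoke-scale shock preset runs end-to-end into a run directory", {
  d <- tempfile("run_")
  rec <- run_experiment(preset_experiment("trabecula_ve",
                                          scale = "smoke"), d, quiet = TRUE)
  s <- rec$summary
  expect_true(all(c("surface", "mean", "polarity") %in% names(s)))
  expect_identical(nrow(s), 8L)       # 4 surfaces x 2 polarities
  cfg_back <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_identical(cfg_back$experiment, "trabecula_ve")
  unlink(d, recursive = TRUE)
})

test_that("VTK snapshots carry the grid and fields in legacy ASCII", {
  g <- build_slab_with_trabecula(
    slab_config(dims = c(20, 14), wall = 3, trab_len = 8, trab_thick = 1,
                cleft = 1, electrode_drop = 2))
  f <- tempfile(fileext = ".vtk")
  write_vtk_image(f, g, cell_data = list(label = g$labels),
                  point_data = list(vm = rep(-85, n_nodes(g))))
  lines <- readLines(f)
  expect_identical(lines[4], "DATASET STRUCTURED_POINTS")
  expect_true(any(grepl("CELL_DATA 280", lines)))
  expect_true(any(grepl("POINT_DATA 315", lines)))
  expect_true(any(grepl("SCALARS label", lines)))
  unlink(f)
})
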