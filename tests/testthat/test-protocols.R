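test_that("pacing and shock specifications validate their inputs", {
  expect_error(pacing_spec(cis = 600), "exceeding")
  expect_error(pacing_spec(cis = -5), "positive")
  expect_error(shock_spec(-1), "V >= 0")
  sp <- shock_spec(5, polarity = "cathodal")
  expect_identical(sp$sign, -1)
})

test_that("uniform stimulation keeps the tissue spatially uniform and equal to the cell", {
  g <- build_tissue_sheet(c(10, 6), 250)
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conductivity_set(scale = 0.6375),
                         membrane_params())
  pac <- pacing_spec(n_beats = 2, bcl = 400, cis = c(150, 300))
  tissue <- precondition_and_checkpoint(ops, pac, uniform = FALSE)
  cell <- precondition_and_checkpoint(ops, pac, uniform = TRUE)
  for (key in c("ci150", "ci300")) {
    vt <- tissue$checkpoints[[key]]$Vm
    vc <- cell$checkpoints[[key]]$Vm
    expect_lt(max(vt) - min(vt), 0.1)          # no propagation by symmetry
    expect_lt(max(abs(vt - vc)), 0.5)          # equals the single cell
  }
})

test_that("CI 240 is relatively refractory and CI 340 recovered on a strand", {
  g <- build_tissue_sheet(c(40, 1), 250)
  fib <- structure(list(cells = tissue_cells(g),
                        vectors = matrix(rep(c(1, 0), 40), ncol = 2,
                                         byrow = TRUE),
                        depth = rep(0.5, 40)), class = "fiber_field")
  ops <- build_operators(g, fib, conductivity_set(scale = 0.6375),
                         membrane_params())
  pc <- precondition_and_checkpoint(ops, pacing_spec(cis = c(240, 340)))
  nij <- node_ijk(g, ops$tissue_nodes)
  stim <- ifelse(nij[, 1] <= 3, 80, 0)
  probe <- which(nij[, 1] == 35)[1]
  propagated <- vapply(c("ci240", "ci340"), function(key) {
    st <- pc$checkpoints[[key]]
    out <- step_monodomain(st, ops, duration = 80, dt = 0.02, stim = stim,
                           stim_window = c(0, 2), stride = 50)
    any(out$frames[probe, ] > 0)
  }, NA)
  expect_false(propagated[["ci240"]])
  expect_true(propagated[["ci340"]])
})

test_that("a zero-voltage shock is identical to the unshocked continuation", {
  ops <- slab_ops_detached()
  cp <- slab_checkpoints()$checkpoints[["ci340"]]
  run0 <- apply_shock(ops, cp, shock_spec(0), post_window = 5)
  ctrl <- shock_control(ops, cp, post_window = 5)
  expect_lt(max(abs(run0$frames - ctrl$frames)), 0.01)
})

test_that("shock bookkeeping: samples, Dirichlet polarity and node-set checks", {
  ops <- slab_ops_detached()
  cp <- slab_checkpoints()$checkpoints[["ci340"]]
  run <- apply_shock(ops, cp, shock_spec(1, polarity = "cathodal"),
                     post_window = 10)
  en <- ops$grid$node_sets$electrode_nodes
  expect_lt(max(abs(run$phie_shock[en] + 1000)), 1e-9)  # -V on the electrode
  expect_identical(ncol(run$frames), length(run$frame_times))
  expect_true(all(c(9, 20) %in% run$frame_times))
  orig <- ops$grid
  bad <- orig
  bad$node_sets$ground_boundary <- c(bad$node_sets$ground_boundary, en[1])
  ops$grid <- bad          # operators are an environment; restore below
  expect_error(apply_shock(ops, cp, shock_spec(1)), "overlap")
  ops$grid <- orig
})

test_that("checkpoints round-trip bit-exactly through files", {
  ops <- slab_ops_detached()
  cp <- slab_checkpoints()$checkpoints[["ci240"]]
  f <- tempfile(fileext = ".rds")
  save_checkpoint(f, cp, ops$grid, config = list(ci = 240))
  back <- load_checkpoint(f, expect_grid = ops$grid)
  expect_identical(back$state, cp)
  other <- build_tissue_sheet(c(4, 4), 250)
  expect_error(load_checkpoint(f, expect_grid = other), "different grid")
  unlink(f)
})

test_that("an S2 of zero amplitude leaves no reentrant activity", {
  p <- membrane_params_vt()
  g <- build_tissue_sheet(c(40, 40), 400)
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conductivity_set(scale = 0.6375), p)
  nij <- node_ijk(g, ops$tissue_nodes)
  st <- sim_state(ops)
  s1 <- ifelse(nij[, 1] <= 3, 80, 0)
  st1 <- step_monodomain(st, ops, duration = 120, dt = 0.05, stim = s1,
                         stim_window = c(0, 2), stride = 1e9)
  # S2 amplitude zero: activity extinguishes after the S1 beat passes
  obs <- step_monodomain(st1, ops, duration = 150, dt = 0.05, stride = 40)
  last <- obs$frames[, ncol(obs$frames)]
  prev <- obs$frames[, ncol(obs$frames) - 1]
  fil <- detect_filaments(last, prev, dt = 2, grid = g,
                          tissue_nodes = ops$tissue_nodes)
  expect_identical(fil$count, 0L)
  expect_true(all(last < -60))
})

test_that("runs are deterministic and resumable at checkpoints", {
  g <- build_tissue_sheet(c(16, 8), 250)
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conductivity_set(scale = 0.6375),
                         membrane_params())
  st <- sim_state(ops)
  nij <- node_ijk(g, ops$tissue_nodes)
  stim <- ifelse(nij[, 1] <= 2, 60, 0)
  one <- step_monodomain(st, ops, duration = 100, dt = 0.02, stim = stim,
                         stim_window = c(0, 2), stride = 1e9)
  # identical rerun is bit-identical
  two <- step_monodomain(st, ops, duration = 100, dt = 0.02, stim = stim,
                         stim_window = c(0, 2), stride = 1e9)
  expect_identical(one$Vm, two$Vm)
  expect_identical(one$state, two$state)
  # splitting at a mid-protocol checkpoint and resuming changes nothing
  half <- step_monodomain(st, ops, duration = 50, dt = 0.02, stim = stim,
                          stim_window = c(0, 2), stride = 1e9)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(f, half, g)
  resumed <- load_checkpoint(f, expect_grid = g)$state
  rest <- step_monodomain(resumed, ops, duration = 50, dt = 0.02,
                          stride = 1e9)
  expect_identical(rest$Vm, one$Vm)
  expect_identical(rest$state, one$state)
  unlink(f)
})
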