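test_that("fibre-aligned tensors reproduce the experimental conductivities", {
  fib <- matrix(c(1, 0), 1, 2)
  Di <- veshock:::tensor_components(fib, 0.174, 0.0193)
  expect_equal(unname(Di[1, ]), c(1.74, 0.193, 0), tolerance = 1e-12)
  # harmonic-mean eigenvalues of the monodomain tensor
  hm <- function(a, b) a * b / (a + b)
  expect_equal(hm(0.174, 0.625), 0.13611, tolerance = 2e-4)
  expect_equal(hm(0.0193, 0.236), 0.017841, tolerance = 2e-4)
  g <- build_tissue_sheet(c(4, 4), 250)
  f <- assign_fibers_rule_based(g)
  tens <- assemble_tensors(g, f, conductivity_set())
  along <- tens$Dm[, "xx"] + tens$Dm[, "yy"]   # trace is rotation invariant
  expect_equal(along, rep((0.13611 + 0.017841) * 10, length(along)),
               tolerance = 1e-3)
})

test_that("isotropic tensors are invariant under fibre rotation", {
  set.seed(1)
  th <- runif(50, 0, 2 * pi)
  fib <- cbind(cos(th), sin(th))
  D <- veshock:::tensor_components(fib, 0.3, 0.3)
  expect_lt(max(abs(D[, "xx"] - 3)), 1e-12)
  expect_lt(max(abs(D[, "yy"] - 3)), 1e-12)
  expect_lt(max(abs(D[, "xy"])), 1e-12)
})

test_that("the elliptic solve is exact for null sources and linear profiles", {
  b <- build_bath_slab(c(12, 20), 250)
  fb <- structure(list(cells = integer(0),
                       vectors = matrix(numeric(0), ncol = 2),
                       depth = numeric(0)), class = "fiber_field")
  ops <- build_operators(b, fb, conductivity_set(),
                         membrane_params("passive"))
  en <- b$node_sets$electrode_nodes
  gn <- b$node_sets$ground_boundary
  # null source, grounded everywhere relevant at 0
  phi0 <- solve_elliptic(ops, c(en, gn), rep(0, length(en) + length(gn)))
  expect_lt(max(abs(phi0)), 1e-10)
  # plate electrodes: linear profile between ground row and electrode nodes
  phi <- solve_elliptic(ops, c(en, gn),
                        c(rep(1000, length(en)), rep(0, length(gn))))
  nj <- node_ijk(b, seq_len(n_nodes(b)))[, 2]
  pred <- 1000 * (nj - 1) / (b$dims[2] - 1)
  sel <- nj <= b$dims[2]
  expect_lt(max(abs(phi[sel] - pred[sel])) / 1000, 1e-6)
  # discrete current conservation: electrode and ground currents match
  res <- compute_resistance(ops, phi, 1, en, gn)
  expect_lt(res$imbalance, 1e-8)
})

test_that("gauge consistency: shifting electrode potentials shifts phi_e only", {
  ops <- slab_ops_detached()
  en <- ops$grid$node_sets$electrode_nodes
  gn <- ops$grid$node_sets$ground_boundary
  rhs <- numeric(nrow(ops$A)); rhs[ops$tissue_nodes[5]] <- 3
  p1 <- solve_elliptic(ops, c(en, gn),
                       c(rep(500, length(en)), rep(0, length(gn))), rhs)
  p2 <- solve_elliptic(ops, c(en, gn),
                       c(rep(700, length(en)), rep(200, length(gn))), rhs)
  # shifting both Dirichlet sets by a constant shifts the whole field
  expect_lt(max(abs((p2 - p1) - 200)), 1e-8)
})

test_that("steady passive point source decays with the analytic cable constant", {
  Gm <- 0.05
  ops <- strand_ops_passive(n = 60, Gm = Gm)
  g <- ops$grid
  st <- sim_state(ops, init = list(Vm = -85.3,
                                   state = membrane_initial_state(1, ops$memb)))
  nij <- node_ijk(g, ops$tissue_nodes)
  stim <- ifelse(nij[, 1] == 1, 2, 0)
  out <- step_monodomain(st, ops, duration = 400, dt = 0.05, stim = stim,
                         stim_window = c(0, 400), stride = 1e9)
  dV <- out$Vm - (-85.3)
  x <- (nij[, 1] - 1) * g$h
  sel <- x >= 0.15 & x <= 0.9 & nij[, 2] == 1
  fit <- stats::lm(log(dV[sel]) ~ x[sel])
  lambda_fit <- -1 / stats::coef(fit)[2]
  sm <- 10 * (0.174 * 0.625 / 0.799)    # mS/cm along the strand
  lambda <- sqrt(sm / (1400 * Gm))
  expect_lt(abs(lambda_fit - lambda) / lambda, 0.02)
})

test_that("zero stimulus preserves equilibrium and bidomain matches monodomain", {
  # equilibrium preservation
  g <- build_tissue_sheet(c(10, 10), 250)
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conductivity_set(), membrane_params())
  st <- sim_state(ops)
  out <- step_monodomain(st, ops, duration = 50, dt = 0.02, stride = 1e9)
  expect_lt(max(abs(out$Vm - st$Vm)), 0.01)
})

test_that("equal anisotropy ratios make bidomain and monodomain agree", {
  # sigma_e = 2 sigma_i: harmonic tensor is (2/3) sigma_i
  conds <- conductivity_set(si_l = 0.174, si_t = 0.0193,
                            se_l = 0.348, se_t = 0.0386)
  g <- build_tissue_sheet(c(24, 24), 250)
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conds, membrane_params())
  st <- sim_state(ops)
  nij <- node_ijk(g, ops$tissue_nodes)
  stim <- ifelse(nij[, 1] <= 3 & nij[, 2] <= 3, 60, 0)
  mono <- step_monodomain(st, ops, duration = 60, dt = 0.02, stim = stim,
                          stim_window = c(0, 2), stride = 1e9)
  bi <- step_bidomain(st, ops, duration = 60, dt_ode = 0.02, stim = stim,
                      stim_window = c(0, 2))
  expect_lt(max(abs(bi$Vm - mono$Vm)), 0.5)
})

test_that("the decoupled-cells limit reproduces the single-cell trace", {
  conds <- conductivity_set(scale = 1e-8)
  g <- build_tissue_sheet(c(8, 2), 250)
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conds, membrane_params())
  st <- sim_state(ops)
  out <- step_monodomain(st, ops, duration = 300, dt = 0.02, stim = 30,
                         stim_window = c(0, 2), stride = 50)
  cell <- run_single_cell(membrane_params(), n_beats = 1, t_end = 300,
                          init = equilibrated_default(), record_dt = 1)
  for (tm in c(50, 150, 250)) {
    i <- which.min(abs(out$frame_times - tm))
    j <- which.min(abs(cell$t - tm))
    expect_lt(max(abs(out$frames[, i] - cell$Vm[j])), 0.1)
  }
})

test_that("planar conduction velocity is refinement-stable", {
  cv1 <- measure_cv(conductivity_set(), n_cells = 40, spacing = 250)
  cv2 <- measure_cv(conductivity_set(), n_cells = 80, spacing = 125)
  expect_true(is.finite(cv1) && cv1 > 0)
  expect_lt(abs(cv2 - cv1) / cv2, 0.1)
})

test_that("cv scale calibration short-circuits and validates input", {
  expect_identical(calibrate_cv_scale(1)$scale, 1)
  expect_error(calibrate_cv_scale(0), "target_fraction")
  expect_error(calibrate_cv_scale(-2), "target_fraction")
  expect_error(conductivity_set(sb = -1), "positive")
})

test_that("instability is detected and reported", {
  g <- build_tissue_sheet(c(8, 2), 2000)  # very coarse, huge dt below
  fib <- assign_fibers_rule_based(g)
  ops <- build_operators(g, fib, conductivity_set(),
                         membrane_params("passive", Gm = 1e-4))
  st <- sim_state(ops, init = list(Vm = -85.3,
                                   state = membrane_initial_state(1, ops$memb)))
  expect_error(
    step_monodomain(st, ops, duration = 2000, dt = 1, stim = 800,
                    stim_window = c(0, 2000), stride = 1e9),
    "500 mV")
})
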