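test_that("threshold fractions count strictly beyond the threshold", {
  expect_identical(threshold_fraction(rep(-86, 50), 1:50, -20, "above"), 0)
  expect_identical(threshold_fraction(rep(0, 50), 1:50, -20, "above"), 100)
  v <- rep(-50, 100); v[sample(100, 37)] <- 0
  expect_identical(threshold_fraction(v, 1:100, -20, "above"), 37)
  expect_error(threshold_fraction(v, integer(0)), "empty region")
})

test_that("the activated fraction is monotone in the threshold", {
  set.seed(42)
  v <- runif(500, -100, 40)
  th <- sort(runif(20, -90, 30))
  fr <- vapply(th, function(x) threshold_fraction(v, 1:500, x, "above"), 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("filament counts match the phase-winding oracle on extruded spirals", {
  g <- build_tissue_sheet(c(40, 40, 10), 250)
  all_nodes <- seq_len(n_nodes(g))
  L <- 40 * 0.025
  # resting field: no isosurface, no filaments
  vr <- rep(-85, n_nodes(g))
  expect_identical(detect_filaments(vr, vr, 1, g, all_nodes)$count, 0L)
  # single spiral -> 1 filament spanning all layers; figure-of-eight -> 2
  cases <- list(list(ctr = matrix(c(0.5, 0.45), 1), chir = 1, n = 1L),
                list(ctr = matrix(c(0.3, 0.5, 0.72, 0.5), 2, byrow = TRUE),
                     chir = c(1, -1), n = 2L))
  for (cs in cases) {
    v1 <- spiral_vm(g, cs$ctr, cs$chir, phase = 0.3)
    v0 <- spiral_vm(g, cs$ctr, cs$chir, phase = 0.24)
    det <- detect_filaments(v1, v0, dt = 1, g, all_nodes)
    expect_identical(det$count, cs$n)
    for (layer in c(1, 5, 10))
      expect_identical(winding_count_layer(v1, v0, g, layer), as.integer(cs$n))
    # the filament spans all layers
    kk <- cell_ijk(g, det$cells)[, 3]
    expect_identical(sort(unique(kk)), 1:10)
  }
  expect_error(detect_filaments(vr[-1], vr, 1, g, all_nodes), "mismatch")
})

test_that("filament counting agrees with the oracle over random spiral suites", {
  g <- build_tissue_sheet(c(36, 36, 4), 300)
  all_nodes <- seq_len(n_nodes(g))
  L <- 36 * 0.03
  set.seed(7)
  for (case in 1:20) {
    n_sp <- sample(0:2, 1)
    cfg <- random_spiral_config(L, n_sp, min_sep = 0.45 * L)
    v1 <- spiral_vm(g, cfg$centres, cfg$chir, phase = 0.4)
    v0 <- spiral_vm(g, cfg$centres, cfg$chir, phase = 0.33)
    det <- detect_filaments(v1, v0, dt = 1, g, all_nodes)
    expect_identical(det$count, as.integer(n_sp))
    expect_identical(winding_count_layer(v1, v0, g, 2), as.integer(n_sp))
  }
})

test_that("polarity summaries are zero against an identical control", {
  ops <- slab_ops_detached()
  z <- ve_polarity_summary(rep(0, length(ops$tissue_nodes)), ops$grid,
                           ops$tissue_nodes)
  expect_true(all(z$mean == 0))
  expect_true(all(z$n > 0))
})

test_that("slab resistance matches L/(sigma A) and scales with conductivity", {
  # 2-D slab 1 cm x 1 cm at unit depth: R = L / (sigma A) = 100 Ohm cm
  mk <- function(sb) {
    b <- build_bath_slab(c(40, 41), 250)  # 41 rows: electrode row on top
    fb <- structure(list(cells = integer(0),
                         vectors = matrix(numeric(0), ncol = 2),
                         depth = numeric(0)), class = "fiber_field")
    ops <- build_operators(b, fb, conductivity_set(sb = sb),
                           membrane_params("passive"))
    r <- resistance_of(ops, V = 1)
    # conductor length: ground nodes row 1 to electrode bottom nodes row 41
    list(R = r$R_ohm_cm, ops = ops, r = r)
  }
  a <- mk(1.0)
  expect_lt(abs(a$R - 100) / 100, 0.01)
  b <- mk(2.0)
  expect_lt(abs(b$R - a$R / 2) / (a$R / 2), 1e-10)
  # resistance is invariant to the applied test voltage
  r5 <- resistance_of(a$ops, V = 5)$R_ohm_cm
  expect_lt(abs(r5 - a$R) / a$R, 0.01)
})

test_that("annulus resistance approaches ln(b/a)/(2 pi sigma) per unit depth", {
  cfg <- annulus_config(n = 150, r_elec = 20, r_in = 30, wall = 3,
                        r_out = 70, n_trabeculae = 0)
  g <- build_annulus_cavity(cfg)
  g$labels[g$labels %in% c(GRID_LABELS[["TISSUE"]])] <- GRID_LABELS[["BATH"]]
  g$node_sets$endocardium <- integer(0); g$node_sets$epicardium <- integer(0)
  fb <- structure(list(cells = integer(0),
                       vectors = matrix(numeric(0), ncol = 2),
                       depth = numeric(0)), class = "fiber_field")
  ops <- build_operators(g, fb, conductivity_set(), membrane_params("passive"))
  en <- g$node_sets$electrode_nodes
  gn <- nodes_of_cells(g, cells_of(g, GRID_LABELS["GROUND"]))
  phie <- solve_elliptic(ops, c(en, gn),
                         c(rep(1000, length(en)), rep(0, length(gn))))
  res <- compute_resistance(ops, phie, 1, en, gn)
  a_cm <- cfg$r_elec * g$h; b_cm <- cfg$r_out * g$h
  R_pred <- log(b_cm / a_cm) / (2 * pi * 0.01)   # sigma = 1 S/m = 0.01 S/cm
  expect_lt(abs(res$R_ohm_cm - R_pred) / R_pred, 0.02)
  expect_lt(res$imbalance, 1e-8)
})

test_that("shock energy follows V^2 T / R and rejects bad resistance", {
  expect_identical(shock_energy(0, 10, 36.4), 0)
  expect_error(shock_energy(5, 10, 0), "positive")
  # sampled square waveform reproduces the closed form
  tt <- seq(0, 10, by = 0.1)
  expect_equal(shock_energy(rep(5, length(tt)), tt, 36.4),
               shock_energy(5, 10, 36.4), tolerance = 1e-12)
})

test_that("field strength fractions match the analytic plate-electrode field", {
  b <- build_bath_slab(c(20, 41), 250)
  fb <- structure(list(cells = integer(0),
                       vectors = matrix(numeric(0), ncol = 2),
                       depth = numeric(0)), class = "fiber_field")
  ops <- build_operators(b, fb, conductivity_set(), membrane_params("passive"))
  en <- b$node_sets$electrode_nodes; gn <- b$node_sets$ground_boundary
  phie <- solve_elliptic(ops, c(en, gn),
                         c(rep(1000, length(en)), rep(0, length(gn))))
  cells <- cells_of(b, GRID_LABELS["BATH"])
  e <- field_strength(ops, phie, cells)
  expect_lt(max(abs(e - 1)), 0.01)                   # 1 V over 1 cm
  expect_identical(field_strength_fraction(ops, phie, 0.5, cells), 100)
  expect_identical(field_strength_fraction(ops, phie, 2, cells), 0)
})
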