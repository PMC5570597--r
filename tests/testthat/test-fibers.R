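test_that("transmural depth matches the analytic Laplace profile on a slab", {
  g <- build_tissue_sheet(c(20, 16), 250)
  fib <- assign_fibers_rule_based(g)
  # parallel flat faces: depth is linear in y; cell centres at (j - 0.5)/ny
  ny <- g$dims[2]
  jc <- cell_ijk(g, fib$cells)[, 2]
  expect_lt(max(abs(fib$depth - (jc - 0.5) / ny)), 1e-8)
  expect_true(all(fib$depth >= 0 & fib$depth <= 1))
})

test_that("inclination interpolates +60 to -60 degrees across the wall", {
  g <- build_tissue_sheet(c(20, 16), 250)
  fib <- assign_fibers_rule_based(g)
  ang <- atan2(fib$vectors[, 2], fib$vectors[, 1]) * 180 / pi
  expect_equal(ang[which.min(fib$depth)],
               60 * (1 - 2 * min(fib$depth)), tolerance = 1e-6)
  expect_equal(ang[which.max(fib$depth)],
               60 * (1 - 2 * max(fib$depth)), tolerance = 1e-6)
  mid <- which.min(abs(fib$depth - 0.5))
  expect_lt(abs(ang[mid] - 60 * (1 - 2 * fib$depth[mid])), 1e-6)
  # unit norm everywhere
  expect_lt(max(abs(sqrt(rowSums(fib$vectors^2)) - 1)), 1e-10)
})

test_that("trabecular cells carry the structure axis and assignment is deterministic", {
  g <- build_slab_with_trabecula(slab_config())
  f1 <- assign_fibers_rule_based(g)
  f2 <- assign_fibers_rule_based(g)
  expect_identical(f1, f2)
  is_trab <- g$labels[f1$cells] == GRID_LABELS[["TISSUE_TRABECULA"]]
  expect_true(any(is_trab))
  expect_lt(max(abs(f1$vectors[is_trab, 1] - 1)), 1e-6)
  expect_lt(max(abs(f1$vectors[is_trab, 2])), 1e-6)
})

test_that("azimuthal trabecular fibres are tangential on the annulus", {
  g <- build_annulus_cavity(annulus_config(n = 80, r_in = 20, wall = 8,
                                           n_trabeculae = 2,
                                           trab_arc_deg = 40))
  fib <- assign_fibers_rule_based(g)
  is_trab <- g$labels[fib$cells] == GRID_LABELS[["TISSUE_TRABECULA"]]
  cc <- cell_ijk(g, fib$cells[is_trab]) - 0.5
  radial <- cbind(cc[, 1] - 40, cc[, 2] - 40)
  radial <- radial / sqrt(rowSums(radial^2))
  dot <- abs(rowSums(radial * fib$vectors[is_trab, ]))
  expect_lt(max(dot), 1e-6)
})

test_that("a tissue island with no boundary contact is reported", {
  g <- build_tissue_sheet(c(12, 10), 250)
  # carve an isolated island: relabel a floating block as tissue inside bath
  lab <- matrix(g$labels, 12, 10)
  lab[, 5:6] <- GRID_LABELS[["BATH"]]       # split the sheet
  g$labels <- as.integer(lab)
  g$node_sets$endocardium <- intersect(boundary_nodes(g, "ymin"),
                                       nodes_of_cells(g, tissue_cells(g)))
  g$node_sets$epicardium <- integer(0)
  expect_error(assign_fibers_rule_based(g), "endocardium and epicardium")
  # give the lower slab both boundaries; the upper island still touches none
  low <- node_ijk(g, nodes_of_cells(g, tissue_cells(g)))
  nodes <- nodes_of_cells(g, tissue_cells(g))
  g$node_sets$endocardium <- nodes[low[, 2] == 1]
  g$node_sets$epicardium <- nodes[low[, 2] == 5]
  expect_error(assign_fibers_rule_based(g), "component")
})

test_that("3-D fibres stay unit norm and orthogonalise against the wall normal", {
  g <- build_slab_with_trabecula(
    slab_config(dims = c(24, 16, 6), wall = 6, trab_len = 8, trab_thick = 2,
                cleft = 1))
  fib <- assign_fibers_rule_based(g)
  expect_lt(max(abs(sqrt(rowSums(fib$vectors^2)) - 1)), 1e-10)
  # wall fibres are nearly orthogonal to the transmural (y) direction at
  # mid-depth, where the inclination is 0
  wall <- g$labels[fib$cells] == GRID_LABELS[["TISSUE"]]
  mid <- wall & abs(fib$depth - 0.5) < 0.12
  expect_true(any(mid))
  expect_lt(max(abs(fib$vectors[mid, 2])), 0.2)
})
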