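test_that("detached slab has the configured label counts and cleft structure", {
  cfg <- slab_config(dims = c(60, 30), wall = 10, trabecula = "detached",
                     trab_len = 20, trab_thick = 3, cleft = 2)
  g <- build_slab_with_trabecula(cfg)
  # exhaustive label count: bar 20x3 plus two 1x2 end attachments;
  # cleft is the 2-row gap under the mid-span (18 columns)
  expect_identical(sum(g$labels == GRID_LABELS[["TISSUE_TRABECULA"]]),
                   20L * 3L + 2L * 2L)
  expect_identical(sum(g$labels == GRID_LABELS[["CLEFT_BATH"]]), 18L * 2L)
  expect_identical(sum(g$labels == GRID_LABELS[["TISSUE"]]), 60L * 10L)

  # every mid-span trabecular cell on the wall side has a cleft neighbour
  trab <- cells_of(g, GRID_LABELS["TISSUE_TRABECULA"])
  ijk <- cell_ijk(g, trab)
  bar_bottom <- trab[ijk[, 2] == min(ijk[ijk[, 2] > 15, 2])]
  expect_true(is_detached(g))

  # removing the two end attachments disconnects the trabecula from the wall
  xs <- range(ijk[, 1])
  keep <- trab[ijk[, 1] != xs[1] & ijk[, 1] != xs[2]]
  tissue_all <- c(cells_of(g, GRID_LABELS["TISSUE"]), keep)
  comps <- veshock:::cell_components(g, tissue_all)
  expect_identical(length(comps), 2L)
})

test_that("node sets are disjoint and lie on tissue/bath interfaces", {
  g <- build_slab_with_trabecula(slab_config())
  ns <- g$node_sets
  surf <- c(ns$endocardium, ns$epicardium, ns$trabecula_proximal_face,
            ns$trabecula_distal_face)
  expect_identical(anyDuplicated(surf), 0L)
  tissue_nodes <- nodes_of_cells(g, tissue_cells(g))
  bath_nodes <- nodes_of_cells(g, veshock:::bathlike_cells(g))
  expect_true(all(surf %in% intersect(tissue_nodes, bath_nodes)))
  # electrode cells are entirely inside bath, ground cells on the boundary
  elec <- cells_of(g, GRID_LABELS["ELECTRODE"])
  nb <- veshock:::cell_neighbours(g, elec)
  for (x in nb)
    expect_true(all(g$labels[x[!is.na(x)]] %in%
                    c(GRID_LABELS[["BATH"]], GRID_LABELS[["ELECTRODE"]])))
})

test_that("degenerate and invalid slab configurations are rejected", {
  g0 <- build_slab_with_trabecula(slab_config(trabecula = "none"))
  expect_identical(length(g0$node_sets$trabecula_proximal_face), 0L)
  expect_identical(length(g0$node_sets$trabecula_distal_face), 0L)
  comps <- veshock:::cell_components(g0, tissue_cells(g0))
  expect_identical(length(comps), 1L)    # simply connected wall
  # planar endocardium: all endo nodes on one row
  expect_identical(length(unique(node_ijk(g0, g0$node_sets$endocardium)[, 2])), 1L)

  expect_error(slab_config(trabecula = "detached", cleft = 0),
               "attached ridge")
  expect_error(slab_config(dims = c(60, 18), wall = 10, trab_thick = 6),
               "clearance")
})

test_that("attached ridge has no distal (wall-facing) surface", {
  g <- build_slab_with_trabecula(slab_config(trabecula = "attached"))
  expect_identical(length(g$node_sets$trabecula_distal_face), 0L)
  expect_gt(length(g$node_sets$trabecula_proximal_face), 0L)
  expect_false(is_detached(g))
})

test_that("annulus builder is rotationally symmetric and places trabeculae", {
  g0 <- build_annulus_cavity(annulus_config(n = 60, r_in = 14, wall = 6,
                                            n_trabeculae = 0))
  lab <- matrix(g0$labels, 60, 60)
  rot <- t(lab)[60:1, , drop = FALSE]     # 90-degree rotation
  expect_identical(as.integer(rot), as.integer(lab))

  g4 <- build_annulus_cavity(annulus_config(n = 80, r_in = 20, wall = 8,
                                            n_trabeculae = 4,
                                            trab_arc_deg = 30))
  trab <- cells_of(g4, GRID_LABELS["TISSUE_TRABECULA"])
  comps <- veshock:::cell_components(g4, trab)
  expect_identical(length(comps), 4L)
  for (cc in comps) expect_true(is_detached(g4, cc))

  expect_error(annulus_config(r_elec = 0), "positive")
  expect_error(annulus_config(wall = 2), "transmural")
})

test_that("random detached placements stay detached across seeds", {
  for (seed in 1:5) {
    g <- build_slab_with_trabecula(
      slab_config(dims = c(60, 10, 60), wall = 2, bath_epi = 2,
                  trab_len = 10, trab_thick = 1, cleft = 1,
                  n_trabeculae = 3, seed = seed))
    trab <- cells_of(g, GRID_LABELS["TISSUE_TRABECULA"])
    comps <- veshock:::cell_components(g, trab)
    expect_identical(length(comps), 3L)
    for (cc in comps) expect_true(is_detached(g, cc))
  }
})
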