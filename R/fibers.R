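# Rule-based fibre orientation: smooth potential fields satisfying Laplace's
# equation with Dirichlet boundaries on the endo-/epicardial surfaces give a
# normalised transmural depth d and local transmural direction; the default
# circumferential vector is inclined by an angle interpolated linearly from
# +60 deg at the endocardium to -60 deg at the epicardium.  Trabecular cells
# get fibres along the axis of the structure.

#' Assign rule-based fibres on a labelled grid
#'
#' Solves Laplace's equation over the tissue with depth 0 on the endocardium
#' (including trabecular surfaces) and 1 on the epicardium.  In 3-D a second
#' solve between apex and base gives the apico-basal direction; the default
#' circumferential vector is their cross product, then inclined towards the
#' apico-basal axis by the transmural inclination angle.  In 2-D the
#' circumferential vector is the in-plane perpendicular of the transmural
#' direction and the inclination rotates the fibre within the plane (the 2-D
#' reduction of the rule).
#'
#' @param grid a `labeled_grid` with `endocardium`/`epicardium` node sets
#'   (and `apex`/`base` in 3-D).
#' @param inclination angle pair (degrees) at endocardium and epicardium.
#' @return a `fiber_field`: list with `cells` (tissue cell ids), `vectors`
#'   (unit fibre vector per cell), `depth` (normalised transmural depth per
#'   cell) and `depth_nodes` (nodal depth field).
#' @export
assign_fibers_rule_based <- function(grid, inclination = c(60, -60)) {
  tc <- tissue_cells(grid)
  endo <- union(grid$node_sets$endocardium,
                union(grid$node_sets$trabecula_proximal_face,
                      grid$node_sets$trabecula_distal_face))
  epi <- grid$node_sets$epicardium
  if (!length(endo) || !length(epi))
    stop("grid must provide endocardium and epicardium node sets")

  # every tissue component must touch the boundary sets, else the Laplace
  # problem is underdetermined there
  comps <- cell_components(grid, tc)
  bn <- union(endo, epi)
  for (ci in seq_along(comps)) {
    cn <- nodes_of_cells(grid, comps[[ci]])
    if (!length(intersect(cn, bn)))
      stop("tissue component ", ci, " touches neither endocardium nor epicardium")
  }

  dir_nodes <- c(endo, epi)
  dir_vals <- c(rep(0, length(endo)), rep(1, length(epi)))
  dn <- solve_laplace(grid, tc, dir_nodes, dir_vals)
  depth <- rowMeans(matrix(dn[cell_corner_nodes(grid, tc)], nrow = length(tc)))
  depth <- pmin(pmax(depth, 0), 1)

  gt <- cell_gradient(grid, tc, ifelse(is.na(dn), 0, dn))
  tnorm <- sqrt(rowSums(gt^2))
  tnorm[tnorm < 1e-12] <- 1
  that <- gt / tnorm                       # transmural unit vector

  alpha <- (inclination[1] + (inclination[2] - inclination[1]) * depth) *
           pi / 180
  nd <- grid$dim
  if (nd == 2L) {
    chat <- cbind(that[, 2], -that[, 1])   # in-plane circumferential
    vec <- chat * cos(alpha) + that * sin(alpha)
  } else {
    if (is.null(grid$node_sets$apex) || is.null(grid$node_sets$base))
      stop("3-D fibre assignment needs apex and base node sets")
    an <- solve_laplace(grid, tc, c(grid$node_sets$apex, grid$node_sets$base),
                        c(rep(0, length(grid$node_sets$apex)),
                          rep(1, length(grid$node_sets$base))))
    ga <- cell_gradient(grid, tc, ifelse(is.na(an), 0, an))
    # orthonormalise apico-basal against transmural
    proj <- rowSums(ga * that)
    ahat <- ga - that * proj
    anorm <- sqrt(rowSums(ahat^2)); anorm[anorm < 1e-12] <- 1
    ahat <- ahat / anorm
    chat <- cbind(that[, 2] * ahat[, 3] - that[, 3] * ahat[, 2],
                  that[, 3] * ahat[, 1] - that[, 1] * ahat[, 3],
                  that[, 1] * ahat[, 2] - that[, 2] * ahat[, 1])
    vec <- chat * cos(alpha) + ahat * sin(alpha)
  }

  # trabecular cells: fibre along the axis of the structure
  is_trab <- grid$labels[tc] == GRID_LABELS[["TISSUE_TRABECULA"]]
  if (any(is_trab)) {
    ax <- grid$meta$trab_axis
    if (identical(ax, "azimuthal")) {
      ctr <- grid$meta$elec_point
      cc <- cell_ijk(grid, tc[is_trab]) - 0.5
      tx <- cc[, 1] - ctr[1]; ty <- cc[, 2] - ctr[2]
      rn <- sqrt(tx^2 + ty^2); rn[rn < 1e-12] <- 1
      vec[is_trab, ] <- cbind(-ty / rn, tx / rn)
    } else {
      vec[is_trab, ] <- matrix(rep(ax / sqrt(sum(ax^2)), sum(is_trab)),
                               ncol = nd, byrow = TRUE)
    }
  }

  vn <- sqrt(rowSums(vec^2)); vn[vn < 1e-12] <- 1
  vec <- vec / vn
  structure(list(cells = tc, vectors = vec, depth = depth, depth_nodes = dn),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("fiber_field over %d tissue cells; depth range [%.3f, %.3f]\n",
              length(x$cells), min(x$depth), max(x$depth)))
  invisible(x)
}
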