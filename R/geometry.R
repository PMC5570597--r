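# Synthetic labelled domains emulating endocardial anatomy: a tissue wall
# bathed in conductive blood, an intracavitary line/plate electrode, a
# grounded outer boundary, and trabeculae that are either attached ridges or
# detached bridges separated from the wall by a bath-filled cleft.

run_with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Geometry configuration for the trabeculated-slab domain
#'
#' All lengths in cells unless noted; `spacing` is the cell edge in um.
#' @param dims cell counts, length 2 or 3 (x, transmural y, optional z).
#' @param spacing cell edge length (um).
#' @param wall wall thickness (cells, along y).
#' @param bath_epi bath rows below the epicardium (the lowest row is ground).
#' @param trabecula `"none"`, `"attached"` or `"detached"`.
#' @param trab_len,trab_thick trabecular bar length (x) and thickness (y).
#' @param cleft cleft height (cells) between wall and a detached trabecula.
#' @param n_trabeculae number of trabeculae (3-D; placed with `seed`).
#' @param seed RNG seed for random trabecula placement (`NULL` = single
#'   centred trabecula).
#' @param electrode_len electrode length in cells (default a third of `nx`).
#' @param electrode_drop electrode row placed this many rows below the top.
#' @return a validated config list.
#' @export
slab_config <- function(dims = c(60, 30), spacing = 250, wall = 10,
                        bath_epi = 3, trabecula = c("detached", "attached",
                                                    "none"),
                        trab_len = 20, trab_thick = 3, cleft = 2,
                        n_trabeculae = 1, seed = NULL,
                        electrode_len = NULL, electrode_drop = 3) {
  trabecula <- match.arg(trabecula)
  nd <- length(dims)
  stopifnot(nd %in% c(2, 3), all(dims >= 4), spacing > 0, wall >= 2,
            bath_epi >= 2, electrode_drop >= 2)
  if (trabecula == "detached" && cleft < 1)
    stop("detached trabecula with cleft height 0 would silently produce an attached ridge")
  if (trabecula == "attached") cleft <- 0
  if (is.null(electrode_len)) electrode_len <- max(2L, floor(dims[1] / 3))
  top_of_structures <- bath_epi + wall +
    if (trabecula == "none") 0 else cleft + trab_thick
  if (top_of_structures > dims[2] - electrode_drop - 1)
    stop("trabecula does not fit between wall and electrode (thicker than the clearance)")
  if (trabecula != "none" && trab_len + 2 > dims[1])
    stop("trabecula longer than the domain")
  list(dims = as.integer(dims), spacing = spacing, wall = as.integer(wall),
       bath_epi = as.integer(bath_epi), trabecula = trabecula,
       trab_len = as.integer(trab_len), trab_thick = as.integer(trab_thick),
       cleft = as.integer(cleft), n_trabeculae = as.integer(n_trabeculae),
       seed = seed, electrode_len = as.integer(electrode_len),
       electrode_drop = as.integer(electrode_drop))
}

# sample non-overlapping (x0, z0) placements for n trabeculae
place_trabeculae <- function(cfg) {
  nd <- length(cfg$dims)
  nx <- cfg$dims[1]
  nz <- if (nd == 3L) cfg$dims[3] else 1L
  len <- cfg$trab_len
  zlen <- if (nd == 3L) max(2L, min(3L, nz)) else 1L
  if (cfg$n_trabeculae == 1 && is.null(cfg$seed)) {
    x0 <- max(1L, (nx - len) %/% 2L + 1L)
    z0 <- max(1L, (nz - zlen) %/% 2L + 1L)
    return(data.frame(x0 = x0, len = len, z0 = z0, zlen = zlen))
  }
  run_with_seed(cfg$seed, {
    placed <- data.frame(x0 = integer(0), len = integer(0),
                         z0 = integer(0), zlen = integer(0))
    tries <- 0L
    while (nrow(placed) < cfg$n_trabeculae && tries < 2000L) {
      tries <- tries + 1L
      x0 <- sample.int(nx - len, 1L)
      z0 <- if (nz > zlen) sample.int(nz - zlen, 1L) else 1L
      clash <- nrow(placed) > 0 &&
        any(x0 < placed$x0 + placed$len + 2L & placed$x0 < x0 + len + 2L &
            z0 < placed$z0 + placed$zlen + 2L & placed$z0 < z0 + zlen + 2L)
      if (!clash)
        placed <- rbind(placed, data.frame(x0 = x0, len = len,
                                           z0 = z0, zlen = zlen))
    }
    if (nrow(placed) < cfg$n_trabeculae)
      stop("could not place ", cfg$n_trabeculae, " non-overlapping trabeculae")
    placed
  })
}

#' Build a slab domain with an endocardial trabecula
#'
#' A planar tissue wall with bath on both sides: a thin epicardial bath whose
#' lowest row is the grounded boundary, and a deep endocardial bath (the
#' cavity) holding a line/plate electrode.  A trabecular bar runs parallel to
#' the wall; in the `"detached"` configuration it is connected to the wall
#' only through its two end attachments, with a bath-filled cleft under its
#' mid-span, while `"attached"` produces a ridge continuous with the wall.
#'
#' @param cfg a [slab_config()] list.
#' @return a `labeled_grid` with node sets `endocardium`, `epicardium`,
#'   `trabecula_proximal_face`, `trabecula_distal_face`, `ground_boundary`,
#'   `electrode_nodes` (and `apex`/`base` tissue faces in 3-D).
#' @export
build_slab_with_trabecula <- function(cfg = slab_config()) {
  nd <- length(cfg$dims)
  d <- cfg$dims
  nz <- if (nd == 3L) d[3] else 1L
  lab <- array(GRID_LABELS[["BATH"]], dim = c(d[1], d[2], nz))
  lab[, 1, ] <- GRID_LABELS[["GROUND"]]
  wall_rows <- (cfg$bath_epi + 1L):(cfg$bath_epi + cfg$wall)
  lab[, wall_rows, ] <- GRID_LABELS[["TISSUE"]]
  wall_top <- cfg$bath_epi + cfg$wall

  trabs <- NULL
  if (cfg$trabecula != "none") {
    trabs <- place_trabeculae(cfg)
    for (r in seq_len(nrow(trabs))) {
      xs <- trabs$x0[r]:(trabs$x0[r] + trabs$len[r] - 1L)
      zs <- trabs$z0[r]:(trabs$z0[r] + trabs$zlen[r] - 1L)
      if (cfg$trabecula == "detached") {
        cleft_rows <- (wall_top + 1L):(wall_top + cfg$cleft)
        bar_rows <- (wall_top + cfg$cleft + 1L):
                    (wall_top + cfg$cleft + cfg$trab_thick)
        lab[xs, cleft_rows, zs] <- GRID_LABELS[["CLEFT_BATH"]]
        lab[xs, bar_rows, zs] <- GRID_LABELS[["TISSUE_TRABECULA"]]
        # end attachments: the two x-extremes bridge the cleft
        lab[c(xs[1], xs[length(xs)]), cleft_rows, zs] <-
          GRID_LABELS[["TISSUE_TRABECULA"]]
      } else {
        bar_rows <- (wall_top + 1L):(wall_top + cfg$trab_thick)
        lab[xs, bar_rows, zs] <- GRID_LABELS[["TISSUE_TRABECULA"]]
      }
    }
  }

  # electrode: a line (3-D) / plate segment (2-D) inside the cavity bath
  er <- d[2] - cfg$electrode_drop
  ex <- seq.int(max(1L, (d[1] - cfg$electrode_len) %/% 2L + 1L),
                length.out = cfg$electrode_len)
  ez <- if (nd == 3L) max(1L, (nz + 1L) %/% 2L) else 1L
  if (any(lab[ex, er, ez] != GRID_LABELS[["BATH"]]))
    stop("electrode region is not free bath")
  lab[ex, er, ez] <- GRID_LABELS[["ELECTRODE"]]

  grid <- new_labeled_grid(d, cfg$spacing, lab,
                           meta = list(kind = "slab", config = cfg,
                                       wall_rows = range(wall_rows),
                                       trabs = trabs))
  elec_point <- c(mean(ex) - 0.5, er - 0.5, ez - 0.5)[seq_len(nd)]
  grid$meta$elec_point <- elec_point
  grid$meta$trab_axis <- c(1, 0, 0)[seq_len(nd)]

  # the electrode is a plate/line parallel to the wall, so faces are
  # classified against the (vertical) direction towards the electrode plane
  tf <- trabecula_faces(grid, c(elec_point[1], 1e9,
                                elec_point[3])[seq_len(nd)])
  tissue <- cells_of(grid, GRID_LABELS["TISSUE"])
  iface <- interface_nodes(grid, GRID_LABELS["TISSUE"], .bathlike_labels)
  jj <- node_ijk(grid, iface)[, 2]
  endo <- iface[jj >= wall_top + 1L]
  epi  <- iface[jj <= cfg$bath_epi + 1L]
  trab_nodes <- union(tf$proximal, tf$distal)
  endo <- setdiff(endo, trab_nodes)
  epi <- setdiff(epi, trab_nodes)
  ground <- intersect(nodes_of_cells(grid, cells_of(grid, GRID_LABELS["GROUND"])),
                      boundary_nodes(grid, "ymin"))
  grid$node_sets <- list(
    endocardium = endo, epicardium = epi,
    trabecula_proximal_face = tf$proximal,
    trabecula_distal_face = tf$distal,
    ground_boundary = ground,
    electrode_nodes = nodes_of_cells(grid, cells_of(grid, GRID_LABELS["ELECTRODE"])))
  if (nd == 3L) {
    tn <- nodes_of_cells(grid, tissue_cells(grid))
    grid$node_sets$apex <- intersect(tn, boundary_nodes(grid, "xmin"))
    grid$node_sets$base <- intersect(tn, boundary_nodes(grid, "xmax"))
  }
  grid
}

#' Annular cavity configuration
#' @param n grid side (cells); the domain is an `n x n` square.
#' @param spacing cell edge (um).
#' @param r_elec,r_in,wall,r_out electrode / inner cavity / wall / ground
#'   radii and thickness in cells.
#' @param n_trabeculae detached trabeculae placed azimuthally.
#' @param trab_arc_deg azimuthal extent of each trabecula (degrees).
#' @param trab_thick,cleft radial thickness of bar and cleft (cells).
#' @param seed RNG seed for azimuthal placement (`NULL`: evenly spaced).
#' @export
annulus_config <- function(n = 80, spacing = 250, r_elec = 3, r_in = 20,
                           wall = 8, r_out = NULL, n_trabeculae = 0,
                           trab_arc_deg = 40, trab_thick = 2, cleft = 2,
                           seed = NULL) {
  if (r_elec <= 0) stop("inner (electrode) radius must be positive")
  if (wall < 3) stop("wall thinner than 3 cells has no transmural resolution")
  if (is.null(r_out)) r_out <- n / 2 - 1
  if (r_in + wall >= r_out) stop("wall reaches the grounded rim")
  if (r_elec >= r_in) stop("electrode radius must be inside the cavity")
  if (n_trabeculae > 0 && r_in - cleft - trab_thick <= r_elec + 1)
    stop("trabeculae would overlap the electrode")
  list(n = as.integer(n), spacing = spacing, r_elec = r_elec, r_in = r_in,
       wall = wall, r_out = r_out, n_trabeculae = as.integer(n_trabeculae),
       trab_arc_deg = trab_arc_deg, trab_thick = trab_thick, cleft = cleft,
       seed = seed)
}

#' Build an annular wall around a conductive cavity
#'
#' Radial-field analogue of a ventricular cavity: a central electrode, blood
#' bath, an annular tissue wall, outer bath and a grounded rim, so the field
#' is stronger on the endocardium than on the epicardium.  Detached
#' trabeculae are azimuthal arcs inside the cavity attached to the wall at
#' their two angular ends.
#' @param cfg an [annulus_config()] list.
#' @export
build_annulus_cavity <- function(cfg = annulus_config()) {
  n <- cfg$n
  ctr <- n / 2
  ij <- cell_ijk(new_labeled_grid(c(n, n), cfg$spacing,
                                  rep(GRID_LABELS[["BATH"]], n * n)),
                 seq_len(n * n))
  x <- ij[, 1] - 0.5 - ctr
  y <- ij[, 2] - 0.5 - ctr
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  lab <- rep(GRID_LABELS[["BATH"]], n * n)
  lab[r <= cfg$r_elec] <- GRID_LABELS[["ELECTRODE"]]
  lab[r > cfg$r_in & r <= cfg$r_in + cfg$wall] <- GRID_LABELS[["TISSUE"]]
  lab[r > cfg$r_out] <- GRID_LABELS[["GROUND"]]

  if (cfg$n_trabeculae > 0) {
    arc <- cfg$trab_arc_deg * pi / 180
    th0 <- if (is.null(cfg$seed)) {
      seq(0, 2 * pi, length.out = cfg$n_trabeculae + 1)[seq_len(cfg$n_trabeculae)]
    } else {
      run_with_seed(cfg$seed, sort(runif(cfg$n_trabeculae, 0, 2 * pi)))
    }
    if (cfg$n_trabeculae > 1) {
      gaps <- diff(c(sort(th0 %% (2 * pi)), sort(th0 %% (2 * pi))[1] + 2 * pi))
      if (any(gaps < arc + 0.15))
        stop("trabecular arcs overlap; fewer or narrower arcs needed")
    }
    r_bar_in <- cfg$r_in - cfg$cleft - cfg$trab_thick
    ang_of <- function(t0) ((th - t0) %% (2 * pi))
    leg_w <- 2.5 / cfg$r_in   # ~2-3 cells of azimuthal leg width
    for (t0 in th0) {
      a <- ang_of(t0)
      in_arc <- a <= arc
      bar <- in_arc & r > r_bar_in & r <= r_bar_in + cfg$trab_thick
      lab[bar] <- GRID_LABELS[["TISSUE_TRABECULA"]]
      cleft_sel <- in_arc & r > r_bar_in + cfg$trab_thick & r <= cfg$r_in
      lab[cleft_sel] <- GRID_LABELS[["CLEFT_BATH"]]
      legs <- (a <= leg_w | (a <= arc & a >= arc - leg_w)) &
              r > r_bar_in + cfg$trab_thick & r <= cfg$r_in
      lab[legs] <- GRID_LABELS[["TISSUE_TRABECULA"]]
    }
  }

  grid <- new_labeled_grid(c(n, n), cfg$spacing, lab,
                           meta = list(kind = "annulus", config = cfg,
                                       elec_point = c(ctr, ctr),
                                       trab_axis = "azimuthal"))
  tf <- trabecula_faces(grid, c(ctr, ctr))
  iface <- interface_nodes(grid, GRID_LABELS["TISSUE"], .bathlike_labels)
  nij <- node_ijk(grid, iface)
  nr <- sqrt((nij[, 1] - 1 - ctr)^2 + (nij[, 2] - 1 - ctr)^2)
  trab_nodes <- union(tf$proximal, tf$distal)
  endo <- setdiff(iface[nr <= cfg$r_in + cfg$wall / 2], trab_nodes)
  epi <- setdiff(iface[nr > cfg$r_in + cfg$wall / 2], trab_nodes)
  ground <- nodes_of_cells(grid, cells_of(grid, GRID_LABELS["GROUND"]))
  grid$node_sets <- list(
    endocardium = endo, epicardium = epi,
    trabecula_proximal_face = tf$proximal,
    trabecula_distal_face = tf$distal,
    ground_boundary = ground,
    electrode_nodes = nodes_of_cells(grid, cells_of(grid, GRID_LABELS["ELECTRODE"])))
  grid
}

#' Build an all-tissue sheet or strand (no bath)
#'
#' Used for conduction-velocity measurement, cable tests and
#' bidomain/monodomain comparisons.
#' @param dims cell counts (use `c(n, 1)` for a strand).
#' @param spacing cell edge (um).
#' @export
build_tissue_sheet <- function(dims = c(40, 40), spacing = 250) {
  nd <- length(dims)
  lab <- rep(GRID_LABELS[["TISSUE"]], prod(dims))
  grid <- new_labeled_grid(dims, spacing, lab,
                          meta = list(kind = "sheet",
                                      trab_axis = c(1, 0, 0)[seq_len(nd)]))
  grid$node_sets <- list(endocardium = boundary_nodes(grid, "ymin"),
                         epicardium = boundary_nodes(grid, "ymax"),
                         ground_boundary = integer(0),
                         electrode_nodes = integer(0),
                         trabecula_proximal_face = integer(0),
                         trabecula_distal_face = integer(0))
  if (nd == 3L) {
    grid$node_sets$apex <- boundary_nodes(grid, "xmin")
    grid$node_sets$base <- boundary_nodes(grid, "xmax")
  }
  grid
}

#' Build an all-bath block with plate electrode and ground
#'
#' A uniform conductive slab between a plate electrode (top cell row) and a
#' grounded bottom boundary; used for analytic resistance checks.
#' @param dims cell counts.
#' @param spacing cell edge (um).
#' @export
build_bath_slab <- function(dims = c(40, 40), spacing = 250) {
  nd <- length(dims)
  d <- dims
  nz <- if (nd == 3L) d[3] else 1L
  lab <- array(GRID_LABELS[["BATH"]], dim = c(d[1], d[2], nz))
  lab[, d[2], ] <- GRID_LABELS[["ELECTRODE"]]
  lab[, 1, ] <- GRID_LABELS[["GROUND"]]
  grid <- new_labeled_grid(d, spacing, lab, meta = list(kind = "bath_slab"))
  grid$node_sets <- list(
    endocardium = integer(0), epicardium = integer(0),
    trabecula_proximal_face = integer(0), trabecula_distal_face = integer(0),
    ground_boundary = intersect(
      nodes_of_cells(grid, cells_of(grid, GRID_LABELS["GROUND"])),
      boundary_nodes(grid, "ymin")),
    electrode_nodes = nodes_of_cells(grid, cells_of(grid, GRID_LABELS["ELECTRODE"])))
  grid
}
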