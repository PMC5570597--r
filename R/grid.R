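#' @useDynLib veshock, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix Cholesky solve t crossprod Diagonal
#' @importFrom stats setNames runif
NULL

#' Cell-label codes for labelled grids
#'
#' Structured domains carry one region label per cell: myocardial wall tissue,
#' trabecular tissue, cavity/surrounding bath, the bath-filled cleft beneath a
#' detached trabecula, intracavitary electrode cells, and grounded boundary
#' cells.
#' @export
GRID_LABELS <- c(TISSUE = 1L, TISSUE_TRABECULA = 2L, BATH = 3L,
                 CLEFT_BATH = 4L, ELECTRODE = 5L, GROUND = 6L)

.tissue_labels <- c(1L, 2L)
.bathlike_labels <- c(3L, 4L, 5L, 6L)

new_labeled_grid <- function(dims, spacing, labels, node_sets = list(),
                             meta = list()) {
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L), length(labels) == prod(dims))
  g <- list(dim = nd, dims = as.integer(dims),
            ndims = as.integer(dims) + 1L,
            spacing = spacing,          # um per cell edge
            h = spacing * 1e-4,         # cm
            labels = as.integer(labels),
            node_sets = node_sets, meta = meta)
  class(g) <- "labeled_grid"
  g
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat(sprintf("labeled_grid: %s cells at %g um\n",
              paste(x$dims, collapse = " x "), x$spacing))
  tab <- table(factor(x$labels, levels = GRID_LABELS,
                      labels = names(GRID_LABELS)))
  print(tab)
  cat("node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                  lengths(x$node_sets)), collapse = ", "),
      "\n")
  invisible(x)
}

# -- index helpers: cells and nodes are 1-based, x fastest ------------------

#' Cell / node indexing helpers
#'
#' Structured-grid index arithmetic: ids are 1-based with x fastest.
#' @param grid a labelled grid.
#' @param i,j,k integer coordinates.
#' @rdname grid-index
#' @export
cell_id <- function(grid, i, j, k = NULL) {
  d <- grid$dims
  if (grid$dim == 2L) i + d[1] * (j - 1L)
  else i + d[1] * ((j - 1L) + d[2] * (k - 1L))
}

#' @rdname grid-index
#' @export
node_id <- function(grid, i, j, k = NULL) {
  n <- grid$ndims
  if (grid$dim == 2L) i + n[1] * (j - 1L)
  else i + n[1] * ((j - 1L) + n[2] * (k - 1L))
}

#' @rdname grid-index
#' @export
n_nodes <- function(grid) prod(grid$ndims)

#' @rdname grid-index
#' @param id cell or node ids.
#' @export
cell_ijk <- function(grid, id) {
  d <- grid$dims
  id <- id - 1L
  i <- id %% d[1]
  j <- (id %/% d[1]) %% d[2]
  k <- if (grid$dim == 3L) id %/% (d[1] * d[2]) else NULL
  cbind(i = i + 1L, j = j + 1L, k = if (is.null(k)) NULL else k + 1L)
}

#' @rdname grid-index
#' @export
node_ijk <- function(grid, id) {
  n <- grid$ndims
  id <- id - 1L
  i <- id %% n[1]
  j <- (id %/% n[1]) %% n[2]
  k <- if (grid$dim == 3L) id %/% (n[1] * n[2]) else NULL
  cbind(i = i + 1L, j = j + 1L, k = if (is.null(k)) NULL else k + 1L)
}

# corner nodes of each cell: matrix n_cells x 2^dim
cell_corner_nodes <- function(grid, cells) {
  ijk <- cell_ijk(grid, cells)
  if (grid$dim == 2L) {
    i <- ijk[, 1]; j <- ijk[, 2]
    cbind(node_id(grid, i, j),     node_id(grid, i + 1L, j),
          node_id(grid, i, j + 1L), node_id(grid, i + 1L, j + 1L))
  } else {
    i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
    cbind(node_id(grid, i, j, k),           node_id(grid, i + 1L, j, k),
          node_id(grid, i, j + 1L, k),      node_id(grid, i + 1L, j + 1L, k),
          node_id(grid, i, j, k + 1L),      node_id(grid, i + 1L, j, k + 1L),
          node_id(grid, i, j + 1L, k + 1L), node_id(grid, i + 1L, j + 1L, k + 1L))
  }
}

#' Cells carrying a given set of labels
#' @param grid a labelled grid.
#' @param labels integer label codes (see [GRID_LABELS]).
#' @export
cells_of <- function(grid, labels) which(grid$labels %in% labels)

#' @rdname cells_of
#' @export
tissue_cells <- function(grid) cells_of(grid, .tissue_labels)
bathlike_cells <- function(grid) cells_of(grid, .bathlike_labels)

#' Nodes touched by a set of cells
#' @param grid a labelled grid.
#' @param cells cell ids.
#' @export
nodes_of_cells <- function(grid, cells) {
  if (!length(cells)) return(integer(0))
  sort(unique(as.vector(cell_corner_nodes(grid, cells))))
}

# nodes shared between a cell labelled in `a` and a face-adjacent cell
# labelled in `b` (an interface node set)
interface_nodes <- function(grid, a, b) {
  ca <- cells_of(grid, a)
  cb <- cells_of(grid, b)
  if (!length(ca) || !length(cb)) return(integer(0))
  na <- nodes_of_cells(grid, ca)
  nb <- nodes_of_cells(grid, cb)
  intersect(na, nb)
}

# face-adjacent neighbour cells (same-size vector, NA outside domain)
cell_neighbours <- function(grid, cells) {
  ijk <- cell_ijk(grid, cells)
  d <- grid$dims
  shift <- function(di, dj, dk = 0L) {
    i <- ijk[, 1] + di; j <- ijk[, 2] + dj
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2]
    if (grid$dim == 3L) {
      k <- ijk[, 3] + dk
      ok <- ok & k >= 1L & k <= d[3]
      out <- rep(NA_integer_, length(cells))
      out[ok] <- cell_id(grid, i[ok], j[ok], k[ok])
    } else {
      out <- rep(NA_integer_, length(cells))
      out[ok] <- cell_id(grid, i[ok], j[ok])
    }
    out
  }
  nb <- list(shift(-1L, 0L), shift(1L, 0L), shift(0L, -1L), shift(0L, 1L))
  if (grid$dim == 3L) nb <- c(nb, list(shift(0L, 0L, -1L), shift(0L, 0L, 1L)))
  nb
}

# connected components of a cell subset (face adjacency)
cell_components <- function(grid, cells) {
  mask <- logical(prod(grid$dims))
  mask[cells] <- TRUE
  lab <- cpp_connected_components(mask, grid$dims)
  split(which(lab > 0L), lab[lab > 0L])
}

#' Verify that a trabecula is detached (end attachments only)
#'
#' Removes the trabecular cells that touch wall tissue (the end attachments)
#' and checks that the remainder of the trabecula has no wall contact, i.e.
#' the mid-span is separated from the wall by the bath-filled cleft.
#' @param grid a labelled grid.
#' @param trab_cells cells of one trabecular component (defaults to all).
#' @return TRUE if detached in this sense.
#' @export
is_detached <- function(grid, trab_cells = cells_of(grid, GRID_LABELS["TISSUE_TRABECULA"])) {
  if (!length(trab_cells)) return(FALSE)
  wall <- cells_of(grid, GRID_LABELS["TISSUE"])
  wall_mask <- logical(prod(grid$dims)); wall_mask[wall] <- TRUE
  nb <- cell_neighbours(grid, trab_cells)
  touches_wall <- Reduce(`|`, lapply(nb, function(x) {
    out <- logical(length(x)); ok <- !is.na(x); out[ok] <- wall_mask[x[ok]]; out
  }))
  attachments <- trab_cells[touches_wall]
  if (!length(attachments)) return(FALSE)     # floating, not attached at all
  rest <- setdiff(trab_cells, attachments)
  if (!length(rest)) return(FALSE)            # nothing but attachment: a ridge
  # the wall contact must consist of exactly the two end attachments
  att_comps <- cell_components(grid, attachments)
  if (length(att_comps) != 2L) return(FALSE)
  # and the mid-span must not touch the wall anywhere
  nb2 <- cell_neighbours(grid, rest)
  rest_touch <- Reduce(`|`, lapply(nb2, function(x) {
    out <- logical(length(x)); ok <- !is.na(x); out[ok] <- wall_mask[x[ok]]; out
  }))
  !any(rest_touch)
}

# classify trabecular surface nodes into proximal (electrode-facing) and
# distal (wall-facing) faces: the outward normal of each trabecula/bath
# interface face is compared against the direction from the face towards the
# electrode location (the faces are defined only pictorially in sketches of
# this anatomy, so the normal test is the operational definition here)
trabecula_faces <- function(grid, elec_point) {
  trab <- cells_of(grid, GRID_LABELS["TISSUE_TRABECULA"])
  if (!length(trab)) return(list(proximal = integer(0), distal = integer(0)))
  nb <- cell_neighbours(grid, trab)
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  bath_mask <- logical(prod(grid$dims))
  bath_mask[bathlike_cells(grid)] <- TRUE
  ctr <- cell_ijk(grid, trab) - 0.5  # cell centres in cell units
  prox <- integer(0); dist <- integer(0)
  nd <- grid$dim
  for (q in seq_along(nb)) {
    x <- nb[[q]]
    sel <- !is.na(x) & bath_mask[x]
    if (!any(sel)) next
    to_elec <- matrix(rep(elec_point[seq_len(nd)], each = sum(sel)),
                      ncol = nd) - ctr[sel, , drop = FALSE]
    to_elec <- to_elec / pmax(sqrt(rowSums(to_elec^2)), 1e-12)
    d <- as.vector(to_elec %*% dirs[q, seq_len(nd)])
    cells_q <- trab[sel]
    # faces whose normal points mostly towards/away from the electrode;
    # side faces (|cos| < 0.5) belong to neither set
    if (any(d > 0.5))
      prox <- c(prox, face_nodes_of(grid, cells_q[d > 0.5], q))
    if (any(d < -0.5))
      dist <- c(dist, face_nodes_of(grid, cells_q[d < -0.5], q))
  }
  prox <- sort(unique(prox)); dist <- sort(unique(dist))
  shared <- intersect(prox, dist)   # edge nodes between faces: ambiguous
  list(proximal = setdiff(prox, shared), distal = setdiff(dist, shared))
}

# nodes of face q (ordering as in cell_neighbours) of the given cells
face_nodes_of <- function(grid, cells, q) {
  if (!length(cells)) return(integer(0))
  cn <- cell_corner_nodes(grid, cells)
  idx2 <- list(c(1, 3), c(2, 4), c(1, 2), c(3, 4))
  idx3 <- list(c(1, 3, 5, 7), c(2, 4, 6, 8), c(1, 2, 5, 6), c(3, 4, 7, 8),
               c(1, 2, 3, 4), c(5, 6, 7, 8))
  sel <- if (grid$dim == 2L) idx2[[q]] else idx3[[q]]
  unique(as.vector(cn[, sel, drop = FALSE]))
}

# nodes on the outer boundary of the domain
#' Nodes on the outer boundary of the domain
#' @param grid a labelled grid.
#' @param side which face (or `"all"`).
#' @export
boundary_nodes <- function(grid, side = c("all", "xmin", "xmax", "ymin",
                                          "ymax", "zmin", "zmax")) {
  side <- match.arg(side)
  n <- grid$ndims
  ijk <- node_ijk(grid, seq_len(n_nodes(grid)))
  sel <- switch(side,
    all = ijk[, 1] == 1L | ijk[, 1] == n[1] | ijk[, 2] == 1L |
          ijk[, 2] == n[2] |
          (grid$dim == 3L & (ijk[, 3] == 1L | ijk[, 3] == n[3])),
    xmin = ijk[, 1] == 1L, xmax = ijk[, 1] == n[1],
    ymin = ijk[, 2] == 1L, ymax = ijk[, 2] == n[2],
    zmin = ijk[, 3] == 1L, zmax = ijk[, 3] == n[3])
  which(sel)
}
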