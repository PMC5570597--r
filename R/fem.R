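# Bilinear (2-D) / trilinear (3-D) finite elements on the structured grid.
# Every element is an axis-aligned square/cube of edge h, so the element
# stiffness is a fixed linear combination of per-tensor-component reference
# matrices: K_e = sum_ab D_ab * M_ab, with the M_ab computed once by Gauss
# quadrature.  Conductivities enter in mS/cm, potentials in mV, giving
# stiffness-times-potential in uA (3-D) or uA per cm depth (2-D).

element_ref_matrices <- function(nd, h) {
  gp <- c(-1, 1) / sqrt(3) / 2 + 0.5     # 2-point Gauss on [0,1]
  if (nd == 2L) {
    corners <- expand.grid(a = 0:1, b = 0:1)   # x fastest
    nloc <- 4L
    pts <- expand.grid(x = gp, y = gp)
    w <- rep(0.25, nrow(pts))
  } else {
    corners <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
    nloc <- 8L
    pts <- expand.grid(x = gp, y = gp, z = gp)
    w <- rep(0.125, nrow(pts))
  }
  shape_grad <- function(p) {
    # gradient of each trilinear shape function at unit-cube point p (per h)
    g <- matrix(0, nloc, nd)
    for (i in seq_len(nloc)) {
      cr <- as.numeric(corners[i, ])
      for (a in seq_len(nd)) {
        term <- 1
        for (b in seq_len(nd)) {
          xb <- p[b]
          fb <- if (cr[b] == 1) xb else 1 - xb
          dfb <- if (cr[b] == 1) 1 else -1
          term <- term * if (a == b) dfb else fb
        }
        g[i, a] <- term
      }
    }
    g / h
  }
  comps <- if (nd == 2L) list(c(1, 1), c(2, 2), c(1, 2))
           else list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  M <- lapply(comps, function(ab) matrix(0, nloc, nloc))
  vol <- h^nd
  for (q in seq_len(nrow(pts))) {
    G <- shape_grad(as.numeric(pts[q, ]))
    for (ci in seq_along(comps)) {
      a <- comps[[ci]][1]; b <- comps[[ci]][2]
      Mq <- outer(G[, a], G[, b])
      if (a != b) Mq <- Mq + outer(G[, b], G[, a])  # symmetric tensor
      M[[ci]] <- M[[ci]] + w[q] * vol * Mq
    }
  }
  names(M) <- vapply(comps, function(ab)
    paste0(c("x", "y", "z")[ab], collapse = ""), "")
  M
}

# Assemble the stiffness matrix for given cells with per-cell tensor
# components Dcomp (n_cells x n_comp, columns xx,yy[,zz],xy[,xz,yz]).
# Returns a symmetric sparse matrix over ALL grid nodes.
assemble_stiffness <- function(grid, cells, Dcomp) {
  nd <- grid$dim
  if (is.vector(Dcomp)) {
    iso <- Dcomp
    Dcomp <- matrix(0, length(cells), if (nd == 2L) 3 else 6)
    Dcomp[, seq_len(nd)] <- iso
  }
  M <- element_ref_matrices(nd, grid$h)
  cn <- cell_corner_nodes(grid, cells)
  nloc <- ncol(cn)
  nn <- n_nodes(grid)
  trip_i <- vector("list", nloc * nloc)
  trip_j <- vector("list", nloc * nloc)
  trip_x <- vector("list", nloc * nloc)
  q <- 0L
  for (a in seq_len(nloc)) for (b in seq_len(nloc)) {
    val <- numeric(length(cells))
    for (ci in seq_along(M)) val <- val + Dcomp[, ci] * M[[ci]][a, b]
    q <- q + 1L
    trip_i[[q]] <- cn[, a]
    trip_j[[q]] <- cn[, b]
    trip_x[[q]] <- val
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(nn, nn))
}

# Lumped mass: each cell contributes h^d / 2^d to each corner node.
lumped_mass <- function(grid, cells) {
  cn <- cell_corner_nodes(grid, cells)
  m <- numeric(n_nodes(grid))
  add <- grid$h^grid$dim / ncol(cn)
  tab <- tabulate(as.vector(cn), nbins = n_nodes(grid))
  m + tab * add
}

# per-cell gradient of a nodal field (mV/cm), cells x dim
cell_gradient <- function(grid, cells, phi) {
  cn <- cell_corner_nodes(grid, cells)
  h <- grid$h
  if (grid$dim == 2L) {
    gx <- (phi[cn[, 2]] + phi[cn[, 4]] - phi[cn[, 1]] - phi[cn[, 3]]) / (2 * h)
    gy <- (phi[cn[, 3]] + phi[cn[, 4]] - phi[cn[, 1]] - phi[cn[, 2]]) / (2 * h)
    cbind(gx, gy)
  } else {
    gx <- (phi[cn[, 2]] + phi[cn[, 4]] + phi[cn[, 6]] + phi[cn[, 8]] -
           phi[cn[, 1]] - phi[cn[, 3]] - phi[cn[, 5]] - phi[cn[, 7]]) / (4 * h)
    gy <- (phi[cn[, 3]] + phi[cn[, 4]] + phi[cn[, 7]] + phi[cn[, 8]] -
           phi[cn[, 1]] - phi[cn[, 2]] - phi[cn[, 5]] - phi[cn[, 6]]) / (4 * h)
    gz <- (phi[cn[, 5]] + phi[cn[, 6]] + phi[cn[, 7]] + phi[cn[, 8]] -
           phi[cn[, 1]] - phi[cn[, 2]] - phi[cn[, 3]] - phi[cn[, 4]]) / (4 * h)
    cbind(gx, gy, gz)
  }
}

# Laplace solve on a cell subset with Dirichlet node sets; returns nodal
# values (NA off the subset).  Used for transmural depth and similar fields.
solve_laplace <- function(grid, cells, dir_nodes, dir_vals) {
  K <- assemble_stiffness(grid, cells, 1)
  nodes <- nodes_of_cells(grid, cells)
  dir_nodes <- as.integer(dir_nodes)
  if (!all(dir_nodes %in% nodes))
    stop("Dirichlet nodes outside the solve domain")
  free <- setdiff(nodes, dir_nodes)
  phi <- rep(NA_real_, n_nodes(grid))
  phi[dir_nodes] <- dir_vals
  if (length(free)) {
    rhs <- -(K[free, dir_nodes, drop = FALSE] %*% phi[dir_nodes])
    fac <- Matrix::Cholesky(methods::as(K[free, free], "symmetricMatrix"),
                            LDL = FALSE)
    phi[free] <- as.numeric(Matrix::solve(fac, rhs))
  }
  phi
}
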