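# Analytic rotating-spiral voltage fields with a known number of phase
# singularities, plus an independent phase-winding oracle used to validate
# the voxel-marking filament detector.

# phase field with singularities at `centres` (cm) of chirality `chir`
spiral_phase <- function(x, y, centres, chir, k = 2 * pi / 1.5) {
  chi <- rep(0, length(x))
  if (!nrow(centres)) return(chi)
  rmin <- rep(Inf, length(x))
  for (q in seq_len(nrow(centres))) {
    dx <- x - centres[q, 1]; dy <- y - centres[q, 2]
    chi <- chi + chir[q] * atan2(dy, dx)
    rmin <- pmin(rmin, sqrt(dx^2 + dy^2))
  }
  chi - k * rmin
}

# nodal Vm for a (possibly extruded 3-D) grid at rotation phase `phase`
spiral_vm <- function(grid, centres, chir, phase = 0, amp = 60, offset = -20) {
  nij <- node_ijk(grid, seq_len(n_nodes(grid)))
  x <- (nij[, 1] - 1) * grid$h
  y <- (nij[, 2] - 1) * grid$h
  if (!nrow(centres)) return(rep(-85, n_nodes(grid)))
  offset + amp * cos(spiral_phase(x, y, centres, chir) - phase)
}

# oracle: per-layer phase-singularity count by winding number of the
# time-embedded phase around each node plaquette
winding_count_layer <- function(v_now, v_prev, grid, layer = 1, c0 = -20) {
  nx <- grid$ndims[1]; ny <- grid$ndims[2]
  off <- (layer - 1) * nx * ny
  idx <- off + seq_len(nx * ny)
  P <- matrix(atan2(v_now[idx] - c0, v_prev[idx] - c0), nx, ny)
  wrap <- function(a) (a + pi) %% (2 * pi) - pi
  w <- wrap(P[-1, -ncol(P)] - P[-nrow(P), -ncol(P)]) +
       wrap(P[-1, -1] - P[-1, -ncol(P)]) +
       wrap(P[-nrow(P), -1] - P[-1, -1]) +
       wrap(P[-nrow(P), -ncol(P)] - P[-nrow(P), -1])
  sum(abs(w) > 5)
}

# random non-overlapping spiral configuration on [0, L]^2
random_spiral_config <- function(L, n_spirals, min_sep = 1.0) {
  if (n_spirals == 0)
    return(list(centres = matrix(numeric(0), 0, 2), chir = numeric(0)))
  repeat {
    centres <- cbind(runif(n_spirals, 0.25 * L, 0.75 * L),
                     runif(n_spirals, 0.25 * L, 0.75 * L))
    if (n_spirals == 1) break
    d <- as.matrix(dist(centres))
    if (min(d[upper.tri(d)]) >= min_sep) break
  }
  list(centres = centres, chir = sample(c(-1, 1), n_spirals, replace = TRUE))
}
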