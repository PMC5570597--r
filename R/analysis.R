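# Quantitative outputs: activation/hyperpolarisation fractions, filament
# detection and counting, virtual-electrode polarity summaries, electrode
# resistance and shock energy.

#' Percentage of region nodes beyond a voltage threshold
#'
#' @param Vm nodal voltages for the whole indexing space the region refers
#'   to (e.g. tissue nodes).
#' @param region integer indices into `Vm`.
#' @param threshold mV.
#' @param direction `"above"` (strictly greater; activation convention
#'   Vm > -20 mV) or `"below"` (strictly less; hyperpolarisation
#'   Vm < -80 mV).
#' @return percentage in [0, 100].
#' @export
threshold_fraction <- function(Vm, region, threshold = -20,
                               direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!length(region)) stop("empty region")
  v <- Vm[region]
  if (any(is.na(v))) stop("region indexes nodes without Vm values")
  100 * mean(if (direction == "above") v > threshold else v < threshold)
}

# embed a tissue-node field into the full node grid (NA elsewhere)
embed_nodal <- function(grid, tissue_nodes, v) {
  out <- rep(NA_real_, n_nodes(grid))
  out[tissue_nodes] <- v
  out
}

#' Detect scroll-wave filaments / phase singularities
#'
#' Marks tissue cells where the Vm isosurface at `v_iso` (-20 mV) intersects
#' the zero level of the finite-difference dVm/dt between two consecutive
#' frames: a cell is marked when its corner voltages straddle `v_iso` and
#' its corner dVm/dt values straddle 0.  Marked cells are linked by face
#' adjacency (4-neighbour in 2-D, 6-neighbour in 3-D) into connected
#' components; the component count is the filament count.
#'
#' @param Vm_now,Vm_prev tissue-node voltages of two consecutive frames.
#' @param dt frame separation (ms).
#' @param grid labelled grid.
#' @param tissue_nodes node ids carrying `Vm` (from `ops$tissue_nodes`).
#' @param v_iso isosurface level (mV).
#' @return list with `count`, the marked `cells`, and component `labels`.
#' @export
detect_filaments <- function(Vm_now, Vm_prev, dt, grid, tissue_nodes,
                             v_iso = -20) {
  if (length(Vm_now) != length(Vm_prev))
    stop("mismatched frames")
  v <- embed_nodal(grid, tissue_nodes, Vm_now)
  dv <- embed_nodal(grid, tissue_nodes, (Vm_now - Vm_prev) / dt)
  tc <- tissue_cells(grid)
  cn <- cell_corner_nodes(grid, tc)
  cols <- function(M) lapply(seq_len(ncol(M)), function(j) M[, j])
  vs <- cols(matrix(v[cn], nrow = length(tc)))
  ds <- cols(matrix(dv[cn], nrow = length(tc)))
  crosses_iso <- (Reduce(pmin, vs) <= v_iso) & (Reduce(pmax, vs) > v_iso)
  crosses_dv <- (Reduce(pmin, ds) <= 0) & (Reduce(pmax, ds) > 0)
  marked <- tc[crosses_iso & crosses_dv]
  mask <- logical(prod(grid$dims)); mask[marked] <- TRUE
  lab <- cpp_connected_components(mask, grid$dims)
  list(count = attr(lab, "count"), cells = marked, labels = lab)
}

#' Signed virtual-electrode polarity summary per surface
#'
#' Means (and ranges) of the shock-induced polarisation
#' `dVm = Vm(shock) - Vm(matched control)` over named node sets.
#' @param dVm tissue-node polarisation field (mV).
#' @param grid labelled grid (its node sets are summarised).
#' @param tissue_nodes node ids carrying `dVm`.
#' @param sets names of node sets to summarise.
#' @return data.frame with surface, n, mean, min, max.
#' @export
ve_polarity_summary <- function(dVm, grid, tissue_nodes,
                                sets = c("endocardium", "epicardium",
                                         "trabecula_proximal_face",
                                         "trabecula_distal_face")) {
  full <- embed_nodal(grid, tissue_nodes, dVm)
  rows <- lapply(sets, function(s) {
    idx <- grid$node_sets[[s]]
    v <- full[idx]
    v <- v[!is.na(v)]
    data.frame(surface = s, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Electrode-circuit resistance from an elliptic solution
#'
#' Total current into the ground electrode evaluated by the discrete flux
#' (stiffness-row) sum over the ground nodes, `I = sum_S sigma grad(phi_e).n`,
#' and `R = V / I`.  By symmetry of the discrete operator the electrode-side
#' current matches to round-off; the relative imbalance is returned as a
#' conservation check.
#'
#' @param ops operators (for the assembled conductance matrix).
#' @param phie nodal solution (mV) from [solve_elliptic()].
#' @param V applied electrode voltage (V).
#' @param electrode_nodes,ground_nodes Dirichlet node sets used in the solve.
#' @return list with `R_ohm` (3-D) or `R_ohm_cm` (2-D, per cm depth),
#'   currents and `imbalance`.
#' @export
compute_resistance <- function(ops, phie, V,
                               electrode_nodes = ops$grid$node_sets$electrode_nodes,
                               ground_nodes = ops$grid$node_sets$ground_boundary) {
  flux <- as.numeric(ops$A %*% phie)      # uA (3-D) / uA per cm (2-D)
  I_elec <- sum(flux[electrode_nodes])
  I_gnd <- -sum(flux[ground_nodes])
  if (abs(I_gnd) < 1e-12) stop("zero current through the ground electrode")
  imbalance <- abs(I_elec - I_gnd) / max(abs(I_gnd), 1e-300)
  R <- (V * 1000) / I_gnd * 1000          # mV / uA -> kOhm -> Ohm
  out <- list(I_electrode_uA = I_elec, I_ground_uA = I_gnd,
              imbalance = imbalance)
  if (ops$grid$dim == 3L) out$R_ohm <- R else out$R_ohm_cm <- R
  out
}

#' Shock energy of a monophasic pulse
#'
#' `E = (1/R) * integral V(t)^2 dt`; evaluated in closed form `V^2 T / R`
#' for the square pulse, or by the trapezoid rule for a sampled waveform.
#' @param V applied voltage (V) -- a scalar (square pulse) or a sampled
#'   waveform.
#' @param T_ms pulse duration (ms) for the square pulse, or sample times
#'   (ms) matching a waveform `V`.
#' @param R circuit resistance (Ohm).
#' @return energy in joules.
#' @export
shock_energy <- function(V, T_ms, R) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (length(V) == 1L) {
    stopifnot(T_ms > 0)
    return(V^2 * (T_ms / 1000) / R)
  }
  stopifnot(length(V) == length(T_ms))
  tt <- T_ms / 1000
  sum(diff(tt) * (V[-1]^2 + V[-length(V)]^2) / 2) / R
}

#' Fraction of tissue cells above a field-strength threshold
#'
#' Per-cell |grad phi_e| assuming a piecewise-constant field per cell
#' volume.
#' @param ops operators.
#' @param phie nodal extracellular potential (mV).
#' @param threshold V/cm.
#' @param cells cells to evaluate (default: all tissue cells).
#' @return percentage of cells strictly above the threshold.
#' @export
field_strength_fraction <- function(ops, phie, threshold,
                                    cells = tissue_cells(ops$grid)) {
  g <- cell_gradient(ops$grid, cells, phie) / 1000  # mV/cm -> V/cm
  e <- sqrt(rowSums(g^2))
  100 * mean(e > threshold)
}

#' Per-cell field strength (V/cm)
#' @inheritParams field_strength_fraction
#' @export
field_strength <- function(ops, phie, cells = tissue_cells(ops$grid)) {
  g <- cell_gradient(ops$grid, cells, phie) / 1000
  sqrt(rowSums(g^2))
}
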