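# Bidomain / monodomain solver on labelled structured grids.
#
# Governing system (tissue): div(si grad phi_i) = beta Im,
# div(se grad phi_e) = -beta Im - Iei, Im = Cm dVm/dt + Iion(Vm, eta) - Is,
# and in the bath div(sb grad phi_e) = -Ieb, with Vm = phi_i - phi_e.
# Operator-split update: explicit parabolic step of Vm with the intracellular
# operator applied to (Vm + phi_e), membrane ODEs by Rush-Larsen, and an
# elliptic solve for phi_e over tissue + bath with Dirichlet electrode /
# ground nodes.  The monodomain reduction uses the harmonic-mean tensor
# sm = si*se/(si+se) per principal direction.
#
# Internal units: mV, ms, uF/cm2, mS/cm (S/m x 10), uA/cm2, cm.

#' Conductivity set
#'
#' Longitudinal/transverse intracellular and extracellular conductivities,
#' isotropic bath conductivity (all S/m), and a dimensionless uniform scale
#' applied to the two tissue domains (not the bath) -- the mechanism used to
#' model the conduction-velocity reduction of failing myocardium.
#' @param si_l,si_t intracellular conductivities (S/m).
#' @param se_l,se_t extracellular conductivities (S/m).
#' @param sb bath conductivity (S/m).
#' @param scale uniform scale on the intra- and extracellular tensors.
#' @export
conductivity_set <- function(si_l = 0.174, si_t = 0.0193,
                             se_l = 0.625, se_t = 0.236,
                             sb = 1.0, scale = 1.0) {
  vals <- c(si_l, si_t, se_l, se_t, sb, scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all conductivities and the scale must be positive")
  structure(list(si_l = si_l, si_t = si_t, se_l = se_l, se_t = se_t,
                 sb = sb, scale = scale), class = "conductivity_set")
}

# tensor components (mS/cm) for sigma_t I + (sigma_l - sigma_t) f f^T
tensor_components <- function(fib_vec, s_l, s_t) {
  nd <- ncol(fib_vec)
  dS <- (s_l - s_t) * 10   # S/m -> mS/cm
  sT <- s_t * 10
  if (nd == 2L) {
    cbind(xx = sT + dS * fib_vec[, 1]^2,
          yy = sT + dS * fib_vec[, 2]^2,
          xy = dS * fib_vec[, 1] * fib_vec[, 2])
  } else {
    cbind(xx = sT + dS * fib_vec[, 1]^2,
          yy = sT + dS * fib_vec[, 2]^2,
          zz = sT + dS * fib_vec[, 3]^2,
          xy = dS * fib_vec[, 1] * fib_vec[, 2],
          xz = dS * fib_vec[, 1] * fib_vec[, 3],
          yz = dS * fib_vec[, 2] * fib_vec[, 3])
  }
}

#' Per-cell conductivity tensors
#'
#' Builds intracellular, extracellular, bath and harmonic-mean (monodomain)
#' tensor components from a fibre field: each tissue tensor is
#' `R diag(s_l, s_t) R^T` with `R` given by the unit fibre vector; the
#' monodomain eigenvalues are `si*se/(si+se)` per direction; the uniform
#' scale multiplies the intra- and extracellular tensors but not the bath.
#' @param grid labelled grid.
#' @param fibers a `fiber_field` covering every tissue cell.
#' @param conds a [conductivity_set()].
#' @return list with component matrices `Di`, `De`, `Dm` (tissue cells) and
#'   scalar `sb` (mS/cm).
#' @export
assemble_tensors <- function(grid, fibers, conds) {
  tc <- tissue_cells(grid)
  if (length(fibers$cells) != length(tc) || !all(fibers$cells == tc))
    stop("fibre field does not cover the tissue cells of this grid")
  s <- conds$scale
  hm <- function(a, b) a * b / (a + b)
  list(Di = tensor_components(fibers$vectors, s * conds$si_l, s * conds$si_t),
       De = tensor_components(fibers$vectors, s * conds$se_l, s * conds$se_t),
       Dm = tensor_components(fibers$vectors,
                              hm(s * conds$si_l, s * conds$se_l),
                              hm(s * conds$si_t, s * conds$se_t)),
       sb = conds$sb * 10, conds = conds)
}

#' Assemble discrete operators for a labelled grid
#'
#' @param grid labelled grid.
#' @param fibers fibre field (from [assign_fibers_rule_based()]).
#' @param conds a [conductivity_set()].
#' @param memb a [membrane_params()] list (supplies Cm, beta).
#' @return an environment of class `domain_ops` holding stiffness matrices,
#'   node partitions and cached elliptic factorizations.
#' @export
build_operators <- function(grid, fibers, conds, memb = membrane_params()) {
  tens <- assemble_tensors(grid, fibers, conds)
  tc <- tissue_cells(grid)
  bc <- bathlike_cells(grid)
  tn <- nodes_of_cells(grid, tc)

  Ki_full <- assemble_stiffness(grid, tc, tens$Di)
  Ke_full <- assemble_stiffness(grid, tc, tens$De)
  Kb_full <- if (length(bc)) assemble_stiffness(grid, bc, tens$sb) else NULL
  A <- Ki_full + Ke_full
  if (!is.null(Kb_full)) A <- A + Kb_full
  Km_tt <- assemble_stiffness(grid, tc, tens$Dm)[tn, tn]
  Ki_tt <- Ki_full[tn, tn]
  mass <- lumped_mass(grid, tc)[tn]

  ops <- new.env(parent = emptyenv())
  ops$grid <- grid
  ops$fibers <- fibers
  ops$tensors <- tens
  ops$memb <- memb
  ops$tissue_nodes <- tn
  ops$Ki_full <- Ki_full
  ops$A <- A
  ops$Km_tt <- as_csr(Km_tt)
  ops$Ki_tt <- as_csr(Ki_tt)
  ops$invM <- 1 / (memb$beta * memb$Cm * mass)
  ops$fact_cache <- list()
  class(ops) <- "domain_ops"
  ops
}

as_csr <- function(K) {
  Kt <- methods::as(Matrix::t(K), "generalMatrix")
  Kt <- methods::as(Kt, "CsparseMatrix")
  list(rp = Kt@p, ci = Kt@i, vx = Kt@x, n = nrow(K), mat = K)
}

# elliptic factorization with Dirichlet nodes, cached per Dirichlet set
elliptic_fact <- function(ops, dir_nodes) {
  key <- paste0("d", length(dir_nodes), "_",
                if (length(dir_nodes)) dir_nodes[1] else 0, "_",
                if (length(dir_nodes)) dir_nodes[length(dir_nodes)] else 0)
  f <- ops$fact_cache[[key]]
  if (!is.null(f) && identical(f$dir, dir_nodes)) return(f)
  nn <- nrow(ops$A)
  gauge <- length(dir_nodes) == 0L
  if (gauge) dir_nodes <- 1L   # pin one node: pure Neumann gauge fix
  free <- setdiff(seq_len(nn), dir_nodes)
  Aff <- methods::as(ops$A[free, free], "symmetricMatrix")
  f <- list(dir = if (gauge) integer(0) else dir_nodes,
            pin = gauge, free = free, dnodes = dir_nodes,
            Afd = ops$A[free, dir_nodes, drop = FALSE],
            fac = Matrix::Cholesky(Aff, LDL = FALSE, super = TRUE, perm = TRUE))
  ops$fact_cache[[key]] <- f
  f
}

#' Solve the elliptic (extracellular/bath) problem
#'
#' Solves `A phi_e = rhs` with Dirichlet values on electrode/ground nodes.
#' With no Dirichlet nodes a zero-mean gauge is applied (pure-Neumann
#' problem; an error is raised unless `gauge = TRUE`).
#' @param ops a `domain_ops` environment.
#' @param dir_nodes,dir_vals Dirichlet node indices and values (mV).
#' @param rhs right-hand side (uA scale), length = number of nodes.
#' @param gauge allow the pure-Neumann gauge when no Dirichlet nodes.
#' @return nodal `phi_e` (mV).
#' @export
solve_elliptic <- function(ops, dir_nodes = integer(0), dir_vals = numeric(0),
                           rhs = NULL, gauge = FALSE) {
  nn <- nrow(ops$A)
  if (is.null(rhs)) rhs <- numeric(nn)
  if (!length(dir_nodes) && !gauge)
    stop("singular elliptic system: no Dirichlet node and no gauge requested")
  f <- elliptic_fact(ops, as.integer(dir_nodes))
  phi <- numeric(nn)
  dvals <- if (f$pin) 0 else as.numeric(dir_vals)
  phi[f$dnodes] <- dvals
  b <- rhs[f$free] - as.numeric(f$Afd %*% phi[f$dnodes])
  phi[f$free] <- as.numeric(Matrix::solve(f$fac, b))
  if (f$pin) phi <- phi - mean(phi)
  phi
}

#' Initialise a simulation state on a grid
#' @param ops operators from [build_operators()].
#' @param init optional list with `Vm` and `state` (single-cell values are
#'   broadcast); defaults to the equilibrated membrane.
#' @export
sim_state <- function(ops, init = NULL) {
  nt <- length(ops$tissue_nodes)
  if (is.null(init)) init <- equilibrate_membrane(ops$memb)
  Vm <- if (length(init$Vm) == 1L) rep(init$Vm, nt) else init$Vm
  S <- if (ncol(init$state) == 1L)
         matrix(init$state, 19, nt, dimnames = list(rownames(init$state), NULL))
       else init$state
  stopifnot(length(Vm) == nt, ncol(S) == nt)
  list(Vm = Vm, state = S, phie = numeric(nrow(ops$A)), t = 0)
}

#' Advance the monodomain model
#'
#' Explicit finite-element step of the monodomain equation with the
#' harmonic-mean tensor; inner loop in compiled code.
#' @param state from [sim_state()].
#' @param ops operators.
#' @param duration ms.
#' @param dt ODE/PDE step (ms); the parabolic update shares it.
#' @param stim per-tissue-node transmembrane current density (uA/cm2), or a
#'   single value broadcast to all nodes.
#' @param stim_window c(on, off) in ms relative to `state$t`.
#' @param stride frame recording stride in steps.
#' @return updated state with `frames` (Vm per recorded time) attached.
#' @export
step_monodomain <- function(state, ops, duration, dt = 0.02, stim = 0,
                            stim_window = c(0, 0), stride = NULL) {
  nt <- length(state$Vm)
  if (length(stim) == 1L) stim <- rep(stim, nt)
  n_steps <- max(1L, round(duration / dt))
  if (is.null(stride)) stride <- max(1L, round(1 / dt))
  res <- cpp_run_monodomain(state$Vm, state$state, unclass(ops$memb),
                            ops$Km_tt$rp, ops$Km_tt$ci, ops$Km_tt$vx,
                            ops$invM, ops$memb$Cm, dt, n_steps, stim,
                            round(stim_window[1] / dt),
                            round(stim_window[2] / dt), stride)
  nf <- res$n_frames
  list(Vm = res$Vm, state = res$state, phie = state$phie,
       t = state$t + n_steps * dt,
       frames = res$frames[, seq_len(nf), drop = FALSE],
       frame_times = state$t + res$frame_times)
}

#' Advance the bidomain model
#'
#' Operator-split integration: per PDE step an elliptic solve for `phi_e`
#' (with optional Dirichlet electrode/ground sets) followed by
#' `dt_pde/dt_ode` explicit parabolic/membrane substeps with `phi_e` frozen.
#' @param state from [sim_state()].
#' @param ops operators.
#' @param duration ms.
#' @param dt_ode membrane/parabolic step (ms).
#' @param dt_pde elliptic update interval (ms), a multiple of `dt_ode`.
#' @param dir_nodes,dir_vals Dirichlet nodes (global ids) and values (mV)
#'   for the elliptic solve; empty uses the zero-mean gauge.
#' @param stim per-tissue-node transmembrane stimulus (uA/cm2).
#' @param stim_window c(on, off) ms relative to entry time.
#' @param Iei extracellular current injection per node (uA), optional.
#' @param record_dt frame interval (ms), default 1.
#' @export
step_bidomain <- function(state, ops, duration, dt_ode = 0.02,
                          dt_pde = dt_ode, dir_nodes = integer(0),
                          dir_vals = numeric(0), stim = 0,
                          stim_window = c(0, 0), Iei = NULL,
                          record_dt = 1) {
  if (dt_pde < dt_ode - 1e-12) stop("dt_pde must be >= dt_ode")
  n_sub <- max(1L, round(dt_pde / dt_ode))
  n_pde <- max(1L, round(duration / dt_pde))
  nt <- length(state$Vm)
  tn <- ops$tissue_nodes
  if (length(stim) == 1L) stim <- rep(stim, nt)
  Vm <- state$Vm + 0                    # fresh buffers mutated in place
  S <- state$state + 0
  rec_every <- max(1L, round(record_dt / dt_pde))
  frames <- list(); ftimes <- numeric(0); phie <- state$phie
  vg <- numeric(nrow(ops$A))
  for (ip in seq_len(n_pde)) {
    t_rel <- (ip - 1) * dt_pde
    vg[tn] <- Vm
    rhs <- -as.numeric(ops$Ki_full %*% vg)
    if (!is.null(Iei)) rhs <- rhs + Iei
    phie <- solve_elliptic(ops, dir_nodes, dir_vals, rhs,
                           gauge = length(dir_nodes) == 0L)
    stim_now <- t_rel >= stim_window[1] - 1e-9 && t_rel < stim_window[2] - 1e-9
    cpp_parabolic_substeps(Vm, S, unclass(ops$memb),
                           ops$Ki_tt$rp, ops$Ki_tt$ci, ops$Ki_tt$vx,
                           phie[tn], ops$invM, ops$memb$Cm, dt_ode, n_sub,
                           stim, stim_now)
    if (ip %% rec_every == 0L) {
      frames[[length(frames) + 1L]] <- Vm + 0
      ftimes <- c(ftimes, state$t + ip * dt_pde)
    }
  }
  list(Vm = Vm, state = S, phie = phie, t = state$t + n_pde * dt_pde,
       frames = if (length(frames)) do.call(cbind, frames) else NULL,
       frame_times = ftimes)
}

#' Measure planar conduction velocity on a strand
#'
#' Stimulates one end of an all-tissue strand and measures the activation
#' (Vm upward crossing of 0 mV) delay between 25% and 75% of its length.
#' @param conds conductivity set.
#' @param memb membrane parameters.
#' @param n_cells strand length in cells.
#' @param spacing um.
#' @param dt ms.
#' @return CV in cm/s (NA if the wave did not traverse).
#' @export
measure_cv <- function(conds, memb = membrane_params(), n_cells = 40,
                       spacing = 250, dt = 0.02) {
  grid <- build_tissue_sheet(c(n_cells, 1), spacing)
  fib <- list(cells = tissue_cells(grid),
              vectors = matrix(rep(c(1, 0), n_cells), ncol = 2, byrow = TRUE),
              depth = rep(0.5, n_cells))
  class(fib) <- "fiber_field"
  ops <- build_operators(grid, fib, conds, memb)
  st <- sim_state(ops)
  nij <- node_ijk(grid, ops$tissue_nodes)
  stim <- ifelse(nij[, 1] <= 3, 80, 0)
  out <- step_monodomain(st, ops, duration = 60, dt = dt, stim = stim,
                         stim_window = c(0, 2),
                         stride = max(1L, round(0.25 / dt)))
  x <- (nij[, 1] - 1) * grid$h
  L <- max(x)
  tt <- out$frame_times
  act <- apply(out$frames, 1, function(v) {
    i <- which(v[-1] > 0 & v[-length(v)] <= 0)[1]
    if (is.na(i)) return(NA_real_)
    tt[i] + (0 - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
  })
  sel <- x >= 0.25 * L & x <= 0.75 * L & !is.na(act)
  if (sum(sel) < 5) return(NA_real_)
  slope <- stats::coef(stats::lm(act[sel] ~ x[sel]))[2]
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  unname(1000 / slope)   # cm/s
}

#' Calibrate the uniform conductivity scale to a target CV fraction
#'
#' Bisection on the uniform scale `s`, measuring planar conduction velocity
#' on a standard strand, until `CV(s)/CV(1)` is within 1% of the target
#' fraction (continuous cable theory predicts CV proportional to sqrt(s)).
#' @param target_fraction target CV fraction in (0, 1].
#' @param conds base conductivity set.
#' @param memb membrane parameters.
#' @param tol relative tolerance on the achieved fraction.
#' @return list with `scale`, achieved `fraction`, baseline `cv0` (cm/s) and
#'   the updated conductivity set.
#' @export
calibrate_cv_scale <- function(target_fraction, conds = conductivity_set(),
                               memb = membrane_params(), tol = 0.01,
                               n_cells = 80, spacing = 125) {
  if (!is.finite(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  if (target_fraction == 1)
    return(list(scale = 1, fraction = 1, cv0 = NA_real_, conds = conds))
  cv0 <- measure_cv(conds, memb, n_cells = n_cells, spacing = spacing)
  if (is.na(cv0)) stop("baseline strand did not conduct")
  fr <- function(s) {
    cv <- measure_cv(conductivity_set(conds$si_l, conds$si_t, conds$se_l,
                                      conds$se_t, conds$sb, scale = s), memb,
                     n_cells = n_cells, spacing = spacing)
    if (is.na(cv)) 0 else cv / cv0
  }
  lo <- target_fraction^2 * 0.25; hi <- 1
  if (fr(lo) > target_fraction) stop("bisection bracket failure (low end)")
  for (it in 1:40) {
    mid <- 0.5 * (lo + hi)
    f <- fr(mid)
    if (abs(f - target_fraction) <= tol * target_fraction) {
      cset <- conductivity_set(conds$si_l, conds$si_t, conds$se_l,
                               conds$se_t, conds$sb, scale = mid)
      return(list(scale = mid, fraction = f, cv0 = cv0, conds = cset))
    }
    if (f > target_fraction) hi <- mid else lo <- mid
  }
  stop("CV calibration did not converge within 40 bisection steps")
}
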