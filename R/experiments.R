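# Desk-scale experiment drivers: these assemble the standard synthetic
# domains and run the protocols behind the numbered analysis scripts, the
# presets and the acceptance checks.

#' Build operators for the standard trabeculated slab
#'
#' @param trabecula `"detached"`, `"attached"` or `"none"`.
#' @param dims,wall,cleft,trab_len,trab_thick geometry overrides (cells).
#' @param spacing um.
#' @param conds conductivity set (default: experimental values with the
#'   conduction-velocity reduction scale 0.6375 obtained from
#'   [calibrate_cv_scale()] at target 0.75).
#' @param memb membrane parameters.
#' @param n_trabeculae,seed multiple/random trabecula placement (3-D runs).
#' @return `domain_ops` with grid, fibres and matrices assembled.
#' @export
standard_slab_ops <- function(trabecula = "detached", dims = c(60, 30),
                              wall = 10, cleft = 2, trab_len = 20,
                              trab_thick = 3, spacing = 250,
                              conds = NULL, memb = membrane_params(),
                              n_trabeculae = 1, seed = NULL) {
  if (is.null(conds)) conds <- conductivity_set(scale = 0.6375)
  cfg <- slab_config(dims = dims, spacing = spacing, wall = wall,
                     trabecula = trabecula, trab_len = trab_len,
                     trab_thick = trab_thick, cleft = cleft,
                     n_trabeculae = n_trabeculae, seed = seed)
  grid <- build_slab_with_trabecula(cfg)
  fib <- assign_fibers_rule_based(grid)
  build_operators(grid, fib, conds, memb)
}

#' Virtual-electrode polarity experiment
#'
#' Checkpoints the uniformly paced slab at a coupling interval, applies the
#' shock and a matched unshocked control, and summarises the polarisation
#' `dVm` per surface at the shock-end sample.
#' @param ops slab operators.
#' @param V shock strength (V).
#' @param polarity `"anodal"` or `"cathodal"`.
#' @param ci coupling interval (ms).
#' @param sample_ms sample time for the polarity summary (ms from onset).
#' @param post_window ms after shock end.
#' @param checkpoint optionally reuse a precomputed checkpoint.
#' @param control optionally reuse a precomputed control run.
#' @return list with the polarity `summary`, the shock `run`, `control`
#'   and the `checkpoint`.
#' @export
ve_experiment <- function(ops, V = 5, polarity = "anodal", ci = 320,
                          sample_ms = 9, post_window = 10,
                          checkpoint = NULL, control = NULL) {
  if (is.null(checkpoint)) {
    pc <- precondition_and_checkpoint(ops, pacing_spec(cis = ci))
    checkpoint <- pc$checkpoints[[1]]
  }
  run <- apply_shock(ops, checkpoint, shock_spec(V, polarity = polarity),
                     post_window = post_window)
  if (is.null(control))
    control <- shock_control(ops, checkpoint, post_window = post_window)
  i <- which.min(abs(run$frame_times - sample_ms))
  dVm <- run$frames[, i] - control$frames[, i]
  summ <- ve_polarity_summary(dVm, ops$grid, ops$tissue_nodes)
  list(summary = summ, dVm = dVm, run = run, control = control,
       checkpoint = checkpoint)
}

#' Strength-interval activation experiment
#'
#' Endocardial activated fraction (Vm > -20 mV) at shock-end (9 ms) and
#' 10 ms post-shock (20 ms), and hyperpolarised fraction (< -80 mV) at
#' shock-end, across shock strengths and coupling intervals.  The
#' "endocardial surface" here is the endocardium node set including the
#' trabecular faces.
#' @param ops slab operators.
#' @param voltages shock strengths (V).
#' @param cis coupling intervals (ms).
#' @param polarity shock polarity.
#' @param post_window ms simulated beyond shock end (>= 10).
#' @return data.frame with per-run fractions; attribute `runs` carries the
#'   shock runs keyed `"V<volts>_ci<ci>"`.
#' @export
strength_interval_experiment <- function(ops, voltages = c(1, 3, 5, 10),
                                         cis = c(240, 340),
                                         polarity = "anodal",
                                         post_window = 10) {
  pc <- precondition_and_checkpoint(ops, pacing_spec(cis = cis))
  endo <- endocardial_region(ops)
  rows <- list(); runs <- list()
  for (ci in cis) {
    cp <- pc$checkpoints[[paste0("ci", ci)]]
    for (V in voltages) {
      run <- apply_shock(ops, cp, shock_spec(V, polarity = polarity),
                         post_window = post_window)
      f9 <- threshold_fraction(run$vm_shock_end, endo, -20, "above")
      f20 <- threshold_fraction(run$vm_post, endo, -20, "above")
      h9 <- threshold_fraction(run$vm_shock_end, endo, -80, "below")
      rows[[length(rows) + 1L]] <-
        data.frame(V = V, ci = ci, polarity = polarity,
                   act_shock_end = f9, act_post = f20, hyp_shock_end = h9)
      runs[[paste0("V", V, "_ci", ci)]] <- run
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  attr(out, "checkpoints") <- pc$checkpoints
  out
}

# endocardial analysis region: endocardium plus trabecular faces, as indices
# into the tissue-node vector
endocardial_region <- function(ops) {
  ns <- ops$grid$node_sets
  nodes <- sort(unique(c(ns$endocardium, ns$trabecula_proximal_face,
                         ns$trabecula_distal_face)))
  match(nodes, ops$tissue_nodes)
}

#' Anodal vs cathodal myocardial activation comparison
#'
#' Fraction of all tissue nodes activated 10 ms after shock end for both
#' polarities across coupling intervals (the total-volume comparison).
#' @param ops slab operators.
#' @param V shock strength (V).
#' @param cis coupling intervals (ms).
#' @param post_window ms after shock end.
#' @export
polarity_volume_experiment <- function(ops, V = 10, cis = c(240, 280, 320, 340),
                                       post_window = 10) {
  pc <- precondition_and_checkpoint(ops, pacing_spec(cis = cis))
  all_nodes <- seq_along(ops$tissue_nodes)
  rows <- list()
  for (ci in cis) {
    cp <- pc$checkpoints[[paste0("ci", ci)]]
    for (pol in c("anodal", "cathodal")) {
      run <- apply_shock(ops, cp, shock_spec(V, polarity = pol),
                         post_window = post_window)
      rows[[length(rows) + 1L]] <-
        data.frame(V = V, ci = ci, polarity = pol,
                   act_post = threshold_fraction(run$vm_post, all_nodes,
                                                 -20, "above"))
    }
  }
  do.call(rbind, rows)
}

#' Shock energies of the low-energy protocol voltages
#' @param voltages applied voltages (V).
#' @param R circuit resistance (Ohm).
#' @param T_ms pulse duration (ms).
#' @export
energy_table <- function(voltages = c(1, 3, 5, 10), R = 36.4, T_ms = 10) {
  data.frame(V = voltages, T_ms = T_ms, R_ohm = R,
             energy_J = vapply(voltages, shock_energy, 0, T_ms = T_ms, R = R))
}

#' Electrode resistance of a domain at a test voltage
#' @param ops operators.
#' @param V test voltage (V).
#' @export
resistance_of <- function(ops, V = 1) {
  en <- ops$grid$node_sets$electrode_nodes
  gn <- ops$grid$node_sets$ground_boundary
  phie <- solve_elliptic(ops, c(en, gn),
                         c(rep(V * 1000, length(en)), rep(0, length(gn))))
  c(compute_resistance(ops, phie, V, en, gn), list(phie = phie))
}

#' Reentry/shock filament experiment on the trabeculated 3-D slab
#'
#' Builds a coarse 3-D slab with several randomly placed detached
#' trabeculae (geometry randomisation is the only use of the seed), induces
#' sustained reentry with the short-APD membrane variant, applies anodal
#' and cathodal shocks at several phases of the reentrant cycle, and counts
#' post-shock filaments.
#' @param seed geometry seed.
#' @param V shock strength (V).
#' @param phases shock phases (ms).
#' @param n_trabeculae trabeculae placed on the endocardium.
#' @param dims,spacing grid size (cells) and resolution (um).
#' @param post_window filament-count window after shock end (ms).
#' @return list with the per-phase filament data frames for both
#'   polarities, their paired means, and the induction record.
#' @export
vt_filament_experiment <- function(seed = 1, V = 10,
                                   phases = seq(0, 150, by = 50),
                                   n_trabeculae = 3,
                                   dims = c(80, 10, 80), spacing = 400,
                                   post_window = 90) {
  memb <- membrane_params_vt()
  conds <- conductivity_set(scale = 0.6375)
  cfg <- slab_config(dims = dims, spacing = spacing, wall = 2,
                     bath_epi = 2, trabecula = "detached", trab_len = 12,
                     trab_thick = 1, cleft = 1,
                     n_trabeculae = n_trabeculae, seed = seed,
                     electrode_drop = 3, electrode_len = max(8, dims[1] %/% 3))
  grid <- build_slab_with_trabecula(cfg)
  fib <- assign_fibers_rule_based(grid)
  ops <- build_operators(grid, fib, conds, memb)
  ind <- induce_reentry(ops)
  res <- lapply(c(anodal = "anodal", cathodal = "cathodal"), function(pol) {
    shock_during_vt(ops, ind$state, shock_spec(V, polarity = pol),
                    phases = phases, post_window = post_window,
                    dt_shock = 0.01, dt_pde = 0.1, dt_post = 0.05,
                    dt_pde_post = 1)
  })
  mean_by_phase <- function(df) tapply(df$filaments, df$phase, mean)
  paired <- mean_by_phase(res$anodal) - mean_by_phase(res$cathodal)
  list(anodal = res$anodal, cathodal = res$cathodal,
       paired_diff_by_phase = paired,
       mean_paired_diff = mean(paired), induction = ind, ops = ops)
}

#' Maximum Vm in the uniformly paced domain at a coupling interval
#'
#' Spatial uniformity of the conditioning protocol makes this a single-cell
#' computation: the maximum transmembrane voltage anywhere in the domain at
#' the given CI after the final conditioning beat.
#' @param ci coupling interval (ms).
#' @param pacing pacing specification.
#' @param memb membrane parameters.
#' @param dt ODE step (ms).
#' @export
max_vm_at_ci <- function(ci = 220, pacing = pacing_spec(cis = ci),
                         memb = membrane_params(), dt = 0.02) {
  t_snap <- (pacing$n_beats - 1) * pacing$bcl + ci
  tr <- run_single_cell(memb, n_beats = pacing$n_beats, bcl = pacing$bcl,
                        stim_amp = pacing$stim_strength,
                        stim_dur = pacing$stim_duration, dt = dt,
                        t_end = t_snap + 1, snapshot_times = t_snap)
  tr$snapshots[[1]]$Vm
}
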