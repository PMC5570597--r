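# Experimental protocols: uniform pacing with coupling-interval checkpoints,
# monophasic shock delivery of either polarity, reentry induction and shocks
# during reentry.

#' Pacing specification
#' @param n_beats number of conditioning stimuli.
#' @param bcl basic cycle length (ms).
#' @param stim_strength transmembrane stimulus current density (uA/cm2).
#' @param stim_duration stimulus duration (ms).
#' @param cis coupling intervals (ms after onset of the final beat) at which
#'   states are check-pointed.
#' @export
pacing_spec <- function(n_beats = 5, bcl = 500, stim_strength = 30,
                        stim_duration = 2, cis = c(240, 280, 320, 340)) {
  stopifnot(n_beats >= 1, bcl > 0, stim_strength > 0, stim_duration > 0)
  if (any(cis > bcl))
    stop("coupling interval exceeding the basic cycle length")
  if (any(cis <= 0)) stop("coupling intervals must be positive")
  structure(list(n_beats = n_beats, bcl = bcl,
                 stim_strength = stim_strength,
                 stim_duration = stim_duration, cis = cis),
            class = "pacing_spec")
}

#' Shock specification
#' @param V applied voltage (V, non-negative).
#' @param T_ms shock duration (ms).
#' @param polarity `"anodal"` (intracavitary electrode at +V, ground 0) or
#'   `"cathodal"` (electrode at -V).
#' @export
shock_spec <- function(V, T_ms = 10, polarity = c("anodal", "cathodal")) {
  polarity <- match.arg(polarity)
  stopifnot(is.finite(V), V >= 0, T_ms > 0)
  structure(list(V = V, T_ms = T_ms, polarity = polarity,
                 sign = if (polarity == "anodal") 1 else -1),
            class = "shock_spec")
}

#' Uniform pacing with coupling-interval checkpoints
#'
#' Applies the conditioning stimulus to all tissue nodes simultaneously.
#' Because the stimulated state is spatially uniform, the discrete diffusion
#' term vanishes identically and the tissue follows the space-clamped cell
#' exactly; the default fast path therefore integrates a single cell and
#' broadcasts the check-pointed states to the tissue (`uniform = FALSE`
#' forces the explicit tissue integration, used in tests of this
#' equivalence).
#'
#' @param ops operators from [build_operators()].
#' @param pacing a [pacing_spec()].
#' @param dt ODE step (ms).
#' @param uniform use the exact single-cell fast path.
#' @return list of checkpoints keyed by CI (`"ci240"` etc.), each a
#'   simulation state, plus the single-cell `trace`.
#' @export
precondition_and_checkpoint <- function(ops, pacing = pacing_spec(),
                                        dt = 0.02, uniform = TRUE) {
  nt <- length(ops$tissue_nodes)
  t_snap <- (pacing$n_beats - 1) * pacing$bcl + pacing$cis
  t_end <- max(t_snap) + 1
  if (uniform) {
    tr <- run_single_cell(ops$memb, n_beats = pacing$n_beats,
                          bcl = pacing$bcl,
                          stim_amp = pacing$stim_strength,
                          stim_dur = pacing$stim_duration, dt = dt,
                          t_end = t_end, snapshot_times = t_snap)
    cps <- lapply(seq_along(pacing$cis), function(q) {
      sn <- tr$snapshots[[q]]
      list(Vm = rep(sn$Vm, nt),
           state = matrix(sn$state, 19, nt,
                          dimnames = list(.state_names, NULL)),
           phie = numeric(nrow(ops$A)), t = sn$t, ci = pacing$cis[q])
    })
  } else {
    st <- sim_state(ops)
    cps <- vector("list", length(t_snap))
    ord <- order(t_snap)
    t_now <- 0
    stim_times <- pacing$bcl * (seq_len(pacing$n_beats) - 1)
    for (qi in seq_along(ord)) {
      q <- ord[qi]
      # advance in whole-beat segments so stimulus windows line up
      while (t_now < t_snap[q] - 1e-9) {
        seg_end <- min(t_snap[q], t_now + dt * 50)
        w <- c(Inf, -Inf)
        for (s0 in stim_times)
          if (s0 < seg_end - 1e-9 && s0 + pacing$stim_duration > t_now + 1e-9)
            w <- c(s0 - t_now, s0 + pacing$stim_duration - t_now)
        st <- step_monodomain(st, ops, duration = seg_end - t_now, dt = dt,
                              stim = pacing$stim_strength, stim_window = w,
                              stride = 1e9)
        t_now <- st$t
      }
      cps[[q]] <- c(st[c("Vm", "state", "phie", "t")], list(ci = pacing$cis[q]))
    }
    tr <- NULL
  }
  names(cps) <- paste0("ci", pacing$cis)
  list(checkpoints = cps, trace = if (uniform) tr else NULL,
       pacing = pacing)
}

#' Apply a monophasic shock from a check-pointed state
#'
#' Switches to the bidomain representation, holds the electrode node set at
#' +/-V (ground at 0) for the shock duration, then floats the electrode
#' (no-flux) keeping the ground and continues for `post_window` ms.  Vm
#' frames are recorded every `record_dt` ms from shock onset; samples at
#' 9 ms (shock-end) and 20 ms (10 ms post-shock) are returned explicitly.
#'
#' @param ops operators.
#' @param checkpoint state from [precondition_and_checkpoint()] (or any
#'   simulation state).
#' @param shock a [shock_spec()].
#' @param post_window ms simulated after shock end.
#' @param dt_shock ODE step during the shock (ms).
#' @param dt_post ODE step after the shock (ms).
#' @param dt_pde elliptic update interval during the shock (defaults to the
#'   ODE step).
#' @param dt_pde_post elliptic update interval after the shock (defaults to
#'   the post-shock ODE step).
#' @param record_dt frame interval (ms).
#' @return a `shock_run` list: `frames` (tissue-node Vm, one column per
#'   recorded ms), `frame_times` (ms from shock onset), `phie_shock` (the
#'   extracellular field during the shock), samples `vm_shock_end` (9 ms)
#'   and `vm_post` (20 ms), and the final state.
#' @export
apply_shock <- function(ops, checkpoint, shock, post_window = 10,
                        dt_shock = 0.005, dt_post = 0.02,
                        dt_pde = NULL, dt_pde_post = NULL, record_dt = 1) {
  grid <- ops$grid
  en <- grid$node_sets$electrode_nodes
  gn <- grid$node_sets$ground_boundary
  if (length(intersect(en, gn)))
    stop("electrode and ground node sets overlap")
  if (!length(en) || !length(gn))
    stop("grid must provide electrode and ground node sets")
  if (is.null(dt_pde)) dt_pde <- dt_shock
  if (is.null(dt_pde_post)) dt_pde_post <- dt_post
  st <- checkpoint
  st$t <- 0
  dirn <- c(en, gn)
  dirv <- c(rep(shock$sign * shock$V * 1000, length(en)), rep(0, length(gn)))
  sh <- step_bidomain(st, ops, duration = shock$T_ms, dt_ode = dt_shock,
                      dt_pde = dt_pde, dir_nodes = dirn, dir_vals = dirv,
                      record_dt = record_dt)
  phie_shock <- sh$phie
  post <- step_bidomain(sh, ops, duration = post_window, dt_ode = dt_post,
                        dt_pde = dt_pde_post, dir_nodes = gn,
                        dir_vals = rep(0, length(gn)), record_dt = record_dt)
  frames <- cbind(checkpoint$Vm, sh$frames, post$frames)
  ftimes <- c(0, sh$frame_times, post$frame_times)
  pick <- function(tm) {
    i <- which.min(abs(ftimes - tm))
    frames[, i]
  }
  structure(list(frames = frames, frame_times = ftimes,
                 phie_shock = phie_shock,
                 vm_shock_end = pick(9), vm_post = pick(20),
                 shock = shock, ci = checkpoint$ci,
                 state_end = post[c("Vm", "state", "phie", "t")]),
            class = "shock_run")
}

#' Matched unshocked control run
#'
#' Identical numerics to [apply_shock()] with zero applied voltage; used as
#' the reference for virtual-electrode polarisation fields.
#' @inheritParams apply_shock
#' @export
shock_control <- function(ops, checkpoint, T_ms = 10, post_window = 10,
                          dt_shock = 0.005, dt_post = 0.02, dt_pde = NULL,
                          record_dt = 1) {
  apply_shock(ops, checkpoint, shock_spec(0, T_ms, "anodal"),
              post_window = post_window, dt_shock = dt_shock,
              dt_post = dt_post, dt_pde = dt_pde, record_dt = record_dt)
}

#' Induce reentry by cross-field S1-S2 stimulation
#'
#' An S1 plane wave is launched from the apical (x = 0) side; an S2
#' transmembrane stimulus is applied to the half-domain y below the S1
#' wave's refractory tail at a timing scanned across the vulnerable window
#' until a sustained rotor results (at least `min_rotations` activations at
#' a probe away from the boundaries and a persistent phase
#' singularity/filament).
#'
#' @param ops operators (monodomain; use the short-APD membrane variant so
#'   the reentrant wavelength fits the domain).
#' @param s2_scan candidate S2 times (ms after S1 onset).
#' @param observe ms simulated after S2 to verify sustained reentry.
#' @param min_rotations required activations at the probe node.
#' @param s1_strength,s2_strength stimulus current densities (uA/cm2).
#' @param dt ODE step (ms).
#' @return list with the sustained `state`, the chosen `s2_time`, filament
#'   counts over the observation window and the probe trace.
#' @export
induce_reentry <- function(ops, s2_scan = seq(125, 170, by = 15),
                           observe = 450, min_rotations = 3,
                           s1_strength = 120, s2_strength = 120, dt = 0.05) {
  grid <- ops$grid
  nij <- node_ijk(grid, ops$tissue_nodes)
  nx <- grid$ndims[1]
  # reentry circulates in the plane of the wall: x-y for a 2-D sheet,
  # x-z for a 3-D slab whose wall is extruded in y
  tr_ax <- if (grid$dim == 3L) 3L else 2L
  nt_ax <- grid$ndims[tr_ax]
  s1_mask <- as.numeric(nij[, 1] <= 3) * s1_strength
  s2_mask <- as.numeric(nij[, tr_ax] <= ceiling(nt_ax / 2)) * s2_strength
  probe <- which(nij[, 1] == max(3, round(nx * 0.7)) &
                 nij[, tr_ax] == max(3, round(nt_ax * 0.7)))[1]
  s2_scan <- sort(s2_scan)
  base <- sim_state(ops)
  base <- step_monodomain(base, ops, duration = s2_scan[1], dt = dt,
                          stim = s1_mask, stim_window = c(0, 2), stride = 1e9)
  t_base <- s2_scan[1]
  tried <- numeric(0)
  for (s2t in s2_scan) {
    if (s2t > t_base) {
      base <- step_monodomain(base, ops, duration = s2t - t_base, dt = dt,
                              stride = 1e9)
      t_base <- s2t
    }
    tried <- c(tried, s2t)
    st <- step_monodomain(base, ops, duration = 2, dt = dt, stim = s2_mask,
                          stim_window = c(0, 2), stride = 1e9)
    obs <- step_monodomain(st, ops, duration = observe, dt = dt,
                           stride = round(2 / dt))
    v <- obs$frames[probe, ]
    ups <- sum(diff(v > -20) == 1)
    nfr <- ncol(obs$frames)
    fil <- vapply(seq(8, nfr, by = 8), function(i) {
      detect_filaments(obs$frames[, i], obs$frames[, i - 1],
                       dt = diff(obs$frame_times[1:2]), grid = grid,
                       tissue_nodes = ops$tissue_nodes)$count
    }, 0)
    tail_live <- mean(fil[seq(max(1, length(fil) - 10), length(fil))] > 0)
    if (ups >= min_rotations && tail_live >= 0.6) {
      return(list(state = c(obs[c("Vm", "state", "phie", "t")]),
                  s2_time = s2t, filaments = fil, probe_vm = v,
                  scanned = tried))
    }
  }
  stop("no sustained reentry for S2 timings {",
       paste(tried, collapse = ", "), "} ms")
}

#' Apply shocks at several phases of reentry and count filaments
#'
#' From a sustained reentrant state, advances to each requested phase
#' offset, applies the shock via the bidomain model, and counts filaments
#' over a post-shock window at a fixed stride.
#'
#' @param ops operators.
#' @param vt_state sustained state from [induce_reentry()].
#' @param shock a [shock_spec()].
#' @param phases ms offsets of shock delivery from `vt_state`.
#' @param post_window ms of the filament-count window after shock end.
#' @param count_dt filament-count stride (ms).
#' @param dt_shock,dt_pde,dt_post time steps (ms).
#' @return data.frame with columns `phase`, `time` (ms after shock end) and
#'   `filaments`.
#' @export
shock_during_vt <- function(ops, vt_state, shock, phases = seq(0, 300, by = 50),
                            post_window = 90, count_dt = 3,
                            dt_shock = 0.005, dt_pde = 0.05, dt_post = 0.02,
                            dt_pde_post = NULL) {
  grid <- ops$grid
  out <- list()
  st_cache <- vt_state
  t_done <- 0
  for (ph in sort(phases)) {
    if (ph > t_done) {
      st_cache <- step_monodomain(st_cache, ops, duration = ph - t_done,
                                  dt = dt_post, stride = 1e9)
      t_done <- ph
    }
    cp <- c(st_cache[c("Vm", "state", "phie", "t")], list(ci = NA))
    run <- apply_shock(ops, cp, shock, post_window = post_window,
                       dt_shock = dt_shock, dt_pde = dt_pde,
                       dt_post = dt_post, dt_pde_post = dt_pde_post,
                       record_dt = 1)
    tm <- run$frame_times
    counts <- vapply(seq(shock$T_ms + count_dt, max(tm), by = count_dt),
                     function(x) {
      i <- which.min(abs(tm - x))
      detect_filaments(run$frames[, i], run$frames[, i - 1],
                       dt = tm[i] - tm[i - 1], grid = grid,
                       tissue_nodes = ops$tissue_nodes)$count
    }, 0)
    out[[length(out) + 1L]] <-
      data.frame(phase = ph,
                 time = seq(shock$T_ms + count_dt, max(tm), by = count_dt) -
                        shock$T_ms,
                 filaments = counts)
  }
  do.call(rbind, out)
}
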