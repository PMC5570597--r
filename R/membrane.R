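#' Membrane model parameters
#'
#' Parameter set for the membrane kernels.  The default model is a human
#' ventricular ionic cell (epicardial parameter variant) augmented, when
#' `augmentation = TRUE`, with an electroporation current (pore-density ODE of
#' the DeBruin--Krassowska form, current proportional to pore density and
#' transmembrane voltage) and a hypothetical outward potassium current that is
#' negligible below `ka_Vth` (+160 mV by default) and grows sigmoidally above
#' it.  All augmentation constants live in this one list so they can be
#' swapped.
#'
#' @param model one of `"human_ventricular_augmented"` (the human ventricular
#'   cell), `"passive"` (linear leak, conductance `Gm`, reversal `Vrest`) or
#'   `"reduced_test"` (two-variable cubic excitable model used only in solver
#'   unit tests).
#' @param variant which published formulation of the human ventricular model:
#'   `"hv2004"` (default; its faster repolarisation matches the conditioning
#'   dynamics of the study design) or `"hv2006"`.
#' @param augmentation logical; enable the two shock-augmentation currents.
#' @param Cm membrane capacitance per unit area (uF/cm2).
#' @param beta membrane surface-to-volume ratio (1/cm).
#' @param gNa,gto,gKr,gKs,gCaL dimensionless conductance multipliers on the
#'   published values (used e.g. by the short-APD arrhythmia variant).
#' @param gK1 dimensionless multiplier on the inward rectifier.
#' @param tauf dimensionless multiplier on the L-type inactivation time
#'   constants.
#' @param ep_alpha pore creation rate (1/ms); `ep_q`, `ep_Vep` (mV) shape the
#'   voltage dependence; `ep_g` (mS/cm2 per unit normalised pore density) sets
#'   the electroporation conductance.
#' @param ka_g conductance (mS/cm2), `ka_Vth` activation threshold (mV) and
#'   `ka_k` slope (mV) of the large-polarisation potassium current.
#' @param Gm,Vrest passive-model leak conductance (mS/cm2) and reversal (mV).
#' @param ka_Vth,ka_k see `ka_g`.
#' @param ep_q,ep_Vep see `ep_alpha`.
#' @return a list of class `memb_params`.
#' @export
membrane_params <- function(model = c("human_ventricular_augmented",
                                      "passive", "reduced_test"),
                            variant = c("hv2004", "hv2006"),
                            augmentation = TRUE,
                            Cm = 1, beta = 1400,
                            gNa = 1, gto = 1, gKr = 1, gKs = 1, gCaL = 1,
                            gK1 = 1, tauf = 1,
                            ep_alpha = 0.02, ep_q = 2.46, ep_Vep = 258,
                            ep_g = 2e-5,
                            ka_g = 2, ka_Vth = 160, ka_k = 8,
                            Gm = 0.05, Vrest = -85.3) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  stopifnot(Cm > 0, beta > 0, ka_Vth > 0)
  id <- switch(model,
               human_ventricular_augmented = if (variant == "hv2004") 3L else 0L,
               passive = 1L,
               reduced_test = 2L)
  p <- list(model = id,
            model_name = model, variant = variant,
            aug_on = isTRUE(augmentation) && model == "human_ventricular_augmented",
            Cm = Cm, beta = beta,
            s_gNa = gNa, s_gto = gto, s_gKr = gKr, s_gKs = gKs,
            s_gCaL = gCaL, s_gK1 = gK1, s_tauf = tauf,
            ep_alpha = ep_alpha, ep_q = ep_q, ep_Vep = ep_Vep, ep_g = ep_g,
            ka_g = ka_g, ka_Vth = ka_Vth, ka_k = ka_k,
            Gm = Gm, Vrest = Vrest,
            rd_k = 8, rd_a = 0.15, rd_eps = 0.002, rd_amp = 100)
  class(p) <- "memb_params"
  p
}

#' Short-APD arrhythmia variant of the human ventricular membrane
#'
#' Same published cell model with repolarising conductances scaled up,
#' L-type inactivation accelerated, sodium conductance raised and the inward
#' rectifier reduced, so that the action potential shortens and wave tips
#' curl rather than retract: the reentrant wavelength then fits a
#' centimetre-scale domain at the working resolution.  Used by the reentry
#' protocols; the plain parameter set is used everywhere else.
#' @inheritParams membrane_params
#' @export
membrane_params_vt <- function(augmentation = TRUE) {
  membrane_params(model = "human_ventricular_augmented",
                  augmentation = augmentation,
                  gNa = 2, gK1 = 0.6, gKr = 8, gKs = 8, gCaL = 0.4,
                  tauf = 0.15)
}

.state_names <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
                  "f2", "fcass", "Rq", "Cai", "CaSR", "CaSS", "Nai", "Ki",
                  "pore")

#' Default (approximate resting) membrane state
#'
#' Published resting values for the human ventricular model; call
#' [equilibrate_membrane()] for a properly equilibrated state.
#' @param n number of nodes (columns).
#' @param params a [membrane_params()] list.
#' @return numeric matrix, one state vector per column, with `Vm` attribute.
#' @export
membrane_initial_state <- function(n = 1, params = membrane_params()) {
  s0 <- if (params$model == 0L) {
    c(m = 0.00172, h = 0.7444, j = 0.7045, xr1 = 0.00621, xr2 = 0.4712,
      xs = 0.0095, r = 2.42e-8, s = 0.999998, d = 3.373e-5, f = 0.7888,
      f2 = 0.9755, fcass = 0.9953, Rq = 0.9073, Cai = 0.000126,
      CaSR = 3.64, CaSS = 0.00036, Nai = 8.604, Ki = 136.89, pore = 0)
  } else if (params$model == 3L) {
    c(m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0, r = 0, s = 1,
      d = 0, f = 1, f2 = 1, fcass = 1, Rq = 1, Cai = 0.0002, CaSR = 0.2,
      CaSS = 0, Nai = 11.6, Ki = 138.3, pore = 0)
  } else {
    stats::setNames(numeric(19), .state_names)
  }
  S <- matrix(rep(s0, n), nrow = 19, dimnames = list(.state_names, NULL))
  v0 <- switch(as.character(params$model),
               "0" = -85.23, "3" = -86.2, "2" = params$Vrest, params$Vrest)
  attr(S, "Vm") <- rep(v0, n)
  S
}

.check_state <- function(S) {
  if (!is.matrix(S) || nrow(S) != 19)
    stop("membrane state must be a 19-row matrix")
  g <- S[1:13, , drop = FALSE]
  # the published L-type calcium gate steady state slightly exceeds 1 at low
  # calcium (max ~1.05), so the upper bound allows for it
  if (any(g < -1e-12 | g > 1.05 + 1e-12))
    stop("gating variable outside [0, 1]")
  invisible(S)
}

#' Total ionic current density and state derivatives
#'
#' Evaluates the membrane model right-hand side: the total ionic current
#' density (uA/cm2, outward positive) and the time derivative of every state
#' variable, at the given transmembrane voltage(s).
#'
#' @param Vm transmembrane voltage(s), mV.
#' @param state 19-row state matrix (one column per node).
#' @param params a [membrane_params()] list.
#' @return list with `I_ion` (uA/cm2) and `dstate` (per ms).
#' @export
ionic_current <- function(Vm, state, params = membrane_params()) {
  if (any(!is.finite(Vm))) stop("non-finite Vm")
  .check_state(state)
  out <- cpp_ionic_eval(as.numeric(Vm), state, unclass(params))
  rownames(out$dstate) <- .state_names
  out
}

#' Shock augmentation currents
#'
#' Sum of the electroporation current and the large-polarisation potassium
#' current at the given voltage and state (uA/cm2).  Identically zero when
#' augmentation is disabled in `params`.
#' @inheritParams ionic_current
#' @export
augmentation_currents <- function(Vm, state, params = membrane_params()) {
  if (any(!is.finite(Vm))) stop("non-finite Vm")
  if (!isTRUE(params$aug_on)) return(numeric(length(Vm)))
  cpp_aug_currents(as.numeric(Vm), state, unclass(params))
}

#' Advance membrane state by one ODE step
#'
#' Gates advance by exponential (Rush--Larsen) updates and are therefore
#' unconditionally confined to `[0, 1]`; concentrations and the pore density
#' advance explicitly.  `Vm` itself is advanced by the caller (tissue solver)
#' or, for a space-clamped patch, from the returned current.
#'
#' @inheritParams ionic_current
#' @param dt time step, ms.
#' @param Istim transmembrane stimulus current density (uA/cm2).
#' @return list with updated `state` and space-clamped `Vm`.
#' @export
step_membrane <- function(state, Vm, dt, params = membrane_params(),
                          Istim = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(Vm))) stop("non-finite Vm")
  .check_state(state)
  n <- length(Vm)
  S <- state
  Vm <- as.numeric(Vm)
  for (k in seq_len(n)) {
    r1 <- cpp_run_cell(Vm[k], state[, k], unclass(params), dt, dt,
                       Istim, dt, 0, dt, numeric(0))
    S[, k] <- r1$state_end
    Vm[k] <- r1$Vm_end
  }
  list(state = S, Vm = Vm)
}

#' Equilibrate the membrane model at rest
#'
#' Integrates the space-clamped cell without stimulation.
#' @param params a [membrane_params()] list.
#' @param t_end quiescent duration (ms).
#' @param dt ODE step (ms).
#' @return list with `Vm` and `state` (19 x 1 matrix).
#' @export
equilibrate_membrane <- function(params = membrane_params(), t_end = 2000,
                                 dt = 0.02) {
  S0 <- membrane_initial_state(1, params)
  res <- cpp_run_cell(attr(S0, "Vm"), S0[, 1], unclass(params), dt, t_end,
                      0, 1, numeric(0), t_end, numeric(0))
  list(Vm = res$Vm_end,
       state = matrix(res$state_end, 19, dimnames = list(.state_names, NULL)))
}

#' Run a space-clamped single cell under square-pulse pacing
#'
#' @param params a [membrane_params()] list.
#' @param n_beats number of stimuli.
#' @param bcl basic cycle length (ms).
#' @param stim_amp stimulus current density (uA/cm2).
#' @param stim_dur stimulus duration (ms).
#' @param dt ODE step (ms).
#' @param t_end total duration (ms); default runs one full cycle past the
#'   last beat.
#' @param record_dt trace sampling interval (ms).
#' @param init list with `Vm` and `state` (e.g. from
#'   [equilibrate_membrane()]); equilibrated internally when `NULL`.
#' @param snapshot_times times (ms) at which full states are captured.
#' @return list with trace vectors `t`, `Vm`, the final state, and
#'   `snapshots`.
#' @export
run_single_cell <- function(params = membrane_params(), n_beats = 5,
                            bcl = 500, stim_amp = 30, stim_dur = 2,
                            dt = 0.02, t_end = NULL, record_dt = 1,
                            init = NULL, snapshot_times = numeric(0)) {
  if (is.null(init)) init <- equilibrate_membrane(params, dt = dt)
  if (is.null(t_end)) t_end <- n_beats * bcl
  stim_times <- bcl * (seq_len(n_beats) - 1)
  res <- cpp_run_cell(init$Vm, init$state[, 1], unclass(params), dt, t_end,
                      stim_amp, stim_dur, stim_times, record_dt,
                      snapshot_times)
  res$state_end <- matrix(res$state_end, 19,
                          dimnames = list(.state_names, NULL))
  res$stim_times <- stim_times
  res
}

#' Action potential duration at 90% repolarisation
#'
#' Measured on a sampled trace for the beat starting at `onset`:
#' time from crossing upward through the 90%-repolarisation level to crossing
#' back down through it.
#' @param t,Vm trace vectors.
#' @param onset stimulus onset time (ms) of the beat to measure.
#' @param v_rest,v_peak optional resting / peak override.
#' @return APD90 in ms (NA if the beat did not fire).
#' @export
apd90 <- function(t, Vm, onset = 0, v_rest = NULL, v_peak = NULL) {
  sel <- t >= onset
  t <- t[sel]; Vm <- Vm[sel]
  if (is.null(v_rest)) v_rest <- Vm[1]
  if (is.null(v_peak)) v_peak <- max(Vm)
  if (v_peak < 0) return(NA_real_)
  v90 <- v_rest + 0.1 * (v_peak - v_rest)
  above <- Vm > v90
  up <- which(diff(above) == 1)
  dn <- which(diff(above) == -1)
  if (!length(up) || !length(dn)) return(NA_real_)
  dn <- dn[dn > up[1]]
  if (!length(dn)) return(NA_real_)
  # linear interpolation at both crossings
  cross <- function(i) {
    t[i] + (v90 - Vm[i]) / (Vm[i + 1] - Vm[i]) * (t[i + 1] - t[i])
  }
  cross(dn[1]) - cross(up[1])
}
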