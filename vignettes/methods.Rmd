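---
title: "Virtual-electrode formation at detached trabeculae: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-electrode formation at detached trabeculae: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Low-energy defibrillation protocols deliver monophasic shocks from an
intracavitary electrode.  Where the applied current crosses a boundary of the
intracellular domain it must enter or leave the tissue through the membrane,
producing *virtual electrodes* (VEs): regions of de- or hyperpolarisation far
from the physical electrodes.  A trabecula that is detached from the
endocardial wall -- a muscular strand connected only at its two ends, with a
blood-filled cleft beneath its mid-span -- inserts an extra pair of
tissue--bath interfaces into the current path.  For an *anodal* shock
(electrode positive), current enters the trabecula on its electrode-facing
(proximal) side, hyperpolarising it, and leaves on its wall-facing (distal)
side, depolarising it, before hyperpolarising the smooth endocardium below.
A cathodal shock reverses every sign.  The depolarised VE can seed make
excitations (at shock onset, into recovered tissue) or break excitations (at
shock offset, into shock-hyperpolarised and therefore re-excitable tissue),
so the polarity asymmetry of the response is an interaction of geometry with
active membrane dynamics: in a passive membrane the anodal and cathodal
responses are exactly equal and opposite.

`veshock` implements this physics end to end at desk scale: synthetic
labelled grids that emulate the endocardial anatomy, a bidomain/monodomain
solver, a human ventricular membrane model with shock augmentation currents,
the pacing/shock/reentry protocols, and the analysis statistics (activation
fractions, VE polarity summaries, filament counts, electrode resistance and
shock energy).

## Governing equations and discretization

The tissue is a two-potential continuum: intracellular and extracellular
potentials $\phi_i, \phi_e$ with $V_m = \phi_i - \phi_e$,

$$\nabla\cdot\sigma_i\nabla\phi_i = \beta I_m,\qquad
  \nabla\cdot\sigma_e\nabla\phi_e = -\beta I_m - I_{ei},\qquad
  I_m = C_m \partial_t V_m + I_{ion}(V_m,\eta) - I_s,$$

with $\nabla\cdot\sigma_b\nabla\phi_e = -I_{eb}$ in the surrounding blood
bath, no-flux conditions for $\phi_i$ at tissue boundaries and for $\phi_e$
at the outer bath boundary, and Dirichlet values on electrode and ground
node sets during shocks.  The monodomain reduction replaces the pair of
tensors by the harmonic mean $\sigma_m = \sigma_i\sigma_e/(\sigma_i+\sigma_e)$
per principal direction and is used, as in the study design, for pacing
preconditioning and reentry evolution; all shock delivery is bidomain.

Space is discretized with node-centred bilinear (2-D) / trilinear (3-D)
finite elements on structured axis-aligned grids with cell-wise constant
conductivity tensors.  This choice (rather than a two-point finite-volume
flux) is deliberate: the rule-based fibre field produces full anisotropic
tensors with off-diagonal entries, which the element formulation handles
consistently, while the symmetric stiffness matrix makes discrete
conservation exact -- summing stiffness rows over the ground nodes evaluates
the boundary flux integral $\int_S \sigma_b\nabla\phi_e\cdot\hat n\,dS$ to
round-off, which the electrode-resistance computation relies on.  Time
integration is operator split: Rush--Larsen exponential updates for gates,
forward-Euler concentrations, an explicit parabolic update of $V_m$
(unconditionally stable at the default steps for the grids used here), and a
sparse Cholesky solve for $\phi_e$ whose factorization is cached per
electrode configuration and reused across all steps.

Default steps follow the protocol: 20 us for pacing and reentry, 5 us
during shock delivery, with the elliptic update interval equal to the ODE
step on the standard slab.  For the large reentry domains the shock runs use
a 10 us membrane step with the elliptic field refreshed every 0.1 ms (the
shock field is Dirichlet-driven and quasi-static at that scale) and the
reentry evolution uses 50 us; halving any of these steps changes APD90 by
under 1 ms in the convergence tests.

Internal units: mV, ms, cm, uF/cm^2, uA/cm^2, and mS/cm for conductivities
(S/m x 10).  Membrane capacitance is 1 uF/cm^2 and the surface-to-volume
ratio 1400 1/cm, standard bidomain values.

## Membrane model

The default membrane is the 2004 formulation of the ten Tusscher human
ventricular cell model (epicardial parameter set), with the 2006 revision
available as a variant.  Which formulation the conditioning dynamics assume
is not derivable from the protocol alone, so both are implemented and
validated against their published action-potential durations (our kernels
give APD90 of 278 ms and 306 ms at a 1000 ms cycle length, against published
values of about 276 and 301 ms); the 2004 variant is the default because its
faster repolarisation lies closer to the conditioning-state benchmark used
by the shock protocols (maximum Vm of -25 mV at a 220 ms coupling interval;
see limitations below).  Gates advance by Rush--Larsen updates using
interpolation tables for the voltage-dependent rates (0.05 mV spacing; the
tabulated and direct evaluations agree to better than 1e-4 relative in the
tests).

Two shock augmentation currents reproduce the asymmetric membrane response
to strong shocks:

* an electroporation current with a dynamic pore-density state following the
  DeBruin--Krassowska form, $dp/dt = \alpha e^{(V/V_{ep})^2}(1 - p\,
  e^{-q(V/V_{ep})^2})$ with $V_{ep} = 258$ mV, $q = 2.46$, and current
  $I_{ep} = g_{ep}\,p\,V_m$; and
* a hypothetical outward potassium current activating beyond +160 mV,
  $I_{Ka} = g_{Ka}\,(V_m - E_K)\,/\,(1 + e^{(160 - V_m)/8})$.

The source publications of this protocol family cite these currents without
printing their constants, so every constant lives in one swappable parameter
list (`membrane_params()`); defaults were fixed once from the behavioural
constraints that the sum vanishes (< 1e-9 uA/cm^2) at rest with virgin
pores, that the potassium component at +100 mV is under 1% of its +200 mV
value, and that enabling augmentation perturbs a physiological paced beat by
well under 0.1 mV.

The uniform conditioning stimulus is 30 uA/cm^2 for 2 ms, about 1.5x
diastolic threshold; the protocol's published amplitude is dimensionally
inconsistent with any standard surface-to-volume ratio, so a suprathreshold
value was chosen once and kept.

## Conductivities and conduction velocity

Tissue conductivities are the standard experimentally derived values:
intracellular (0.174, 0.0193) S/m, extracellular (0.625, 0.236) S/m along
and across fibres, blood bath 1.0 S/m isotropic.  To represent the reduced
conduction of failing myocardium, both tissue tensors are scaled uniformly
so that planar conduction velocity drops by 25%.  `calibrate_cv_scale()`
performs this calibration by bisection on a refined strand (125 um, where
the continuum square-root law CV ~ sqrt(sigma) holds to a few percent); the
working-resolution slab runs use the scale 0.6375 obtained by the same
bisection on the 250 um strand they share, so that the *simulated* velocity
reduction is 25% at the resolution actually used.

## Synthetic geometry

`build_slab_with_trabecula()` produces the standard domain: a 60 x 30 cell
grid at 250 um (the mean tissue edge length of the source anatomical mesh
is 252 um), with a 10-cell wall, a 20 x 3 cell trabecular bar whose two end
attachments bridge a 2-cell bath cleft ("detached"), an attached-ridge and
a no-trabecula control, a plate/line electrode in the cavity bath and a
grounded outer boundary behind a thin epicardial bath.  Proximal and distal
trabecular faces are defined operationally by the face normal relative to
the direction towards the electrode (the anatomical definition is
pictorial); face-edge nodes shared between the two sets are assigned to
neither.  `build_annulus_cavity()` is the radial-field analogue of a
ventricular cavity -- central electrode, blood pool, annular wall, outer
bath, grounded rim -- reproducing the geometric field asymmetry (stronger on
the endocardium than the epicardium) that a planar slab cannot.

Fibres follow the rule-based method: Laplace solves with Dirichlet data on
the endo-/epicardial surfaces give the normalised transmural depth and
direction; the inclination angle interpolates linearly in depth from +60 deg
to -60 deg (the published rule states the endpoints but not the functional
form); detached trabeculae carry fibres along the structure axis.  In 2-D
the inclination rotates the fibre within the plane -- a stated reduction of
the 3-D rule.

## Protocol notes and numerical choices

* **Pacing.**  5 uniform beats at a 500 ms cycle length; check-points at
  coupling intervals (CIs) 220-340 ms.  A uniformly stimulated state has
  identically zero discrete diffusion current, so the tissue follows the
  space-clamped cell exactly; the fast path integrates one cell and
  broadcasts, and the equivalence is itself tested against the explicit
  tissue integration.
* **Shocks.**  Monophasic square pulses, 1-10 V for 10 ms, electrode
  positive (anodal) or negative (cathodal) against a grounded boundary;
  shock-end fields are sampled at 9 ms and post-shock fields at 20 ms from
  onset, matching the reporting convention of the study design.  The
  desk-scale domain is centimetres rather than torso-scale, so a given
  voltage produces much stronger tissue fields here; 1-3 V shocks on the
  slab span the same 0.5-3 V/cm tissue field-strength range that the
  full-scale study reports for its 5-10 V shocks, and the polarity-pattern
  analyses are therefore run at 1-3 V.
* **VE polarity.**  dVm is always measured against a matched unshocked
  control run with identical numerics (a zero-voltage shock reproduces the
  control to < 0.01 mV).  The sign pattern is assessed at a relatively
  refractory CI (240 ms), where shock-induced make waves do not yet
  contaminate the surface means, which is also the regime the mechanism
  figures of the source study illustrate.
* **Reentry.**  Sustained reentry on a centimetre-scale domain requires a
  reentrant wavelength (CV x APD) of about 1-2 cm, which no physiological
  human parameter set reaches.  The arrhythmia runs therefore use a
  documented short-APD variant of the same cell model
  (`membrane_params_vt()`: I_Kr and I_Ks x 8, I_CaL x 0.4 with faster
  inactivation, I_Na x 2, I_K1 x 0.6), chosen once so that broken wave ends
  curl rather than retract at the working resolution (400 um) and APD90 is
  about 40 ms.  Induction is cross-field: an apical S1 plane wave, then a
  half-domain S2 delivered into the refractory tail, with the S2 timing
  scanned until at least three rotations and a persistent filament are
  observed.  The geometry seed randomises only trabecula placement; the
  physics is deterministic.
* **Filaments.**  A cell is marked when its corner voltages straddle the
  -20 mV isosurface and its corner dVm/dt values (backward difference
  between stored frames) straddle zero; marked cells are joined by face
  adjacency (6-neighbour in 3-D) and the component count is the filament
  count.  The voxel-marking variant is validated against an independent
  phase-winding oracle on analytic spiral fields, including a randomized
  20-case suite.
* **Energy and resistance.**  Square-pulse energy is evaluated in closed
  form $V^2 T/R$ (trapezoid rule for sampled waveforms).  Resistance uses
  the discrete ground-node flux sum; by symmetry of the operator the
  electrode- and ground-side currents balance to < 1e-8 relative, and the
  computed value is voltage-independent to < 1%.

## What the synthetic domains do and do not show

The generator emulates the *mechanistic* ingredients: a detached strand
with a bath cleft, the conductivity contrast between blood and myocardium,
transmural fibre rotation, an intracavitary source and a distant ground.
It does not reproduce the human anatomy's size, its hundreds of trabeculae,
papillary muscles, vessels, or torso-scale field decay.  Consequently the
qualitative outputs -- VE sign patterns, passive antisymmetry,
make/break-excitation regimes, monotone strength-response trends, the sign
of the anodal-cathodal differences -- are the reproducible content, while
absolute activation percentages and filament counts of the full-scale study
are explicitly not.  Passing tests show that the mechanism and its polarity
asymmetry emerge from the stated physics, not that the desk-scale numbers
transfer to a human ventricle.

## Problem sizes

The standard slab is 60 x 30 cells at 250 um (about 1.9k nodes), the
annular cavity 132 x 132 cells, and the reentry slab 80 x 10 x 80 cells at
400 um (about 72k nodes, 20k of them tissue).  These sizes were chosen so
the full analysis suite runs on a laptop-class single core; every quantity
reported by the analysis scripts is recomputed at run time.

## Known limitations

* The conditioning-state benchmark (maximum Vm of -25 mV at CI 220 ms) is
  not reproduced by either published formulation of the cell model: the
  2004 variant gives about -10 mV there (crossing -25 mV near 242 ms),
  robustly across initialisation, stimulus strength and augmentation
  settings.  The value is reported as computed rather than adjusted; see
  `analysis/02_single_cell.R`.
* The short-APD reentry variant is a desk-scale device; filament dynamics
  under shocks are compared only between polarities on identical substrate,
  never against full-scale counts.
* Electroporation constants are behavioural defaults, not fitted to pore
  conductance data; at the field strengths of these protocols the
  hypothetical potassium current dominates the augmentation.
* The 2-D in-plane fibre-rotation convention concentrates anisotropy
  effects into the simulation plane; 3-D runs use the full rule.
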