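# veshock

Bidomain simulation of low-energy monophasic defibrillation shocks
interacting with trabeculated endocardial anatomy.

## The problem

Monophasic shocks from an intracavitary electrode polarise cardiac tissue
wherever the applied current crosses a boundary of the intracellular domain,
creating *virtual electrodes* (VEs) far from the physical electrodes.  A
**detached trabecula** — a muscular strand attached to the endocardial wall
only at its two ends, with a blood-filled cleft beneath its mid-span —
inserts an extra pair of tissue–bath interfaces into the current path.  For
an anodal shock (electrode positive relative to ground) current *enters* the
trabecula on its electrode-facing (proximal) side, hyperpolarising it, and
*leaves* on its wall-facing (distal) side, depolarising it, before
hyperpolarising the smooth endocardium below; a cathodal shock reverses all
signs.  Because the depolarised VE sits next to tissue whose excitability
the same shock has just restored, it can launch make excitations (at shock
onset, into recovered tissue) or break excitations (at shock offset) — and
only the anodal polarity leaves the smooth endocardium excitable for the
resulting wavefronts, an asymmetry relevant to optimising low-energy
defibrillation.  `veshock` reproduces this mechanism at desk scale for
computational electrophysiologists: synthetic labelled geometries, a
bidomain/monodomain finite-element solver, a human ventricular membrane
model with electroporation and large-polarisation potassium augmentation
currents, pacing/shock/reentry protocols, and quantitative analysis
(activation and hyperpolarisation fractions, VE polarity summaries,
scroll-wave filament counts, electrode resistance `R = V / ∮ σ_b ∇φ_e·n̂ dS`
and pulse energy `E = V²T/R`).

The model system: the bidomain equations

    ∇·σᵢ∇φᵢ = β Iₘ,   ∇·σₑ∇φₑ = −β Iₘ − Iₑᵢ,   ∇·σᵦ∇φₑ = −Iₑᵦ,
    Iₘ = Cₘ ∂Vₘ/∂t + I_ion(Vₘ, η) − Iₛ,     Vₘ = φᵢ − φₑ,

with experimentally derived conductivities (σᵢ = 0.174/0.0193 S/m,
σₑ = 0.625/0.236 S/m along/across fibres, blood 1.0 S/m), uniformly scaled
to reduce conduction velocity by 25%, rule-based ±60° transmural fibre
rotation from Laplace solves, and monophasic 1–10 V, 10 ms shocks between a
cavity electrode and a grounded boundary.

## Worked example

Build the standard trabeculated slab, pace it, and measure the
virtual-electrode polarity of a 3 V anodal shock delivered to relatively
refractory tissue (coupling interval 240 ms):

```r
library(veshock)
ops <- standard_slab_ops("detached")     # 60 x 30 cells at 250 um
ve  <- ve_experiment(ops, V = 3, polarity = "anodal", ci = 240)
ve$summary
#>                   surface  n      mean       min       max
#> 1             endocardium 61 -74.06744 -96.70923 -57.96922
#> 2              epicardium 61 175.99297 111.53091 188.42408
#> 3 trabecula_proximal_face 21 -56.19601 -64.37766  11.70842
#> 4   trabecula_distal_face 19 158.71207  94.13375 170.12027
```

The signs are the mechanism: the distal (wall-facing) trabecular surface is
depolarised (mean ΔVm > 0) while the proximal face and the smooth
endocardium are hyperpolarised; `polarity = "cathodal"` flips every sign,
and the `"attached"` ridge control has no distal surface at all.  The
numbered scripts under `analysis/` run the full study — shock energies and
electrode resistance (`01`), single-cell conditioning states (`02`), the VE
polarity table (`03`), the strength × coupling-interval activation sweep
(`04`), the anodal-vs-cathodal total-activation comparison on the
radial-field cavity (`05`), and anodal/cathodal shocks during sustained
reentry with filament counting (`06`) — writing their tables under
`results/`.

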