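# graftflow

Desk-scale computational hemodynamics for the femoral bifurcation in the
setting of superficial femoral artery (SFA) endografts.

Stent grafts that recanalize an occluded SFA sometimes re-thrombose even
when anatomy, duplex ultrasound and run-off all look normal. A candidate
mechanism is hemodynamic: downstream of the femoral flow divider — where
endograft edges typically sit — flow separates during systolic
deceleration, and if the resulting recirculation zones persist over the
cardiac cycle the wall experiences chronically low time-averaged wall
shear stress (TAWSS), which promotes fibrin accumulation on the
thrombogenic graft surface. `graftflow` provides the full analysis chain
for studying this mechanism on parametric synthetic configurations, for
researchers in vascular biomechanics who want the boundary-condition and
wall-shear machinery of patient-specific CFD without patient data:

* **Geometry**: parametric planar CFA→SFA/DFA bifurcations with C1
  cosine-profile stenoses and widenings (severity = fractional area
  change), endograft wall annotations, a conforming multiblock
  triangulator, and a *virtual angioplasty* operator that restores a
  stenosed interval to nominal caliber.
* **Waveforms**: synthesis of triphasic and monophasic duplex-like
  centerline velocity waveforms, Fourier decomposition, CSV I/O.
* **Womersley closed forms**: harmonic-wise conversion between
  centerline velocity and volumetric flow for a tube,
  `Q_n / u_{c,n} = πR² (1 − 2J₁(Λ)/(ΛJ₀(Λ))) / (1 − 1/J₀(Λ))` with
  `Λ = i^{3/2} α_n`, `α_n = R√(nω₀/ν)`, and the planar-channel (cosh)
  analogue used for inlet velocity profiles; complex-argument Bessel
  evaluation included.
* **Windkessel outlets**: 3-element RCR models
  (`C dP_d/dt = Q − (P_d − P_ref)/R_d`, `P = P_d + R_p Q`), impedance
  `Z(ω) = R_p + R_d/(1 + iωR_dC)`, and two-stage tuning (analytic
  initialization + Nelder–Mead on a lumped junction surrogate) that
  recovers generating parameters from target outlet flows.
* **Flow solver**: pulsatile incompressible Newtonian rigid-wall flow on
  the 2D mesh — stabilized P1–P1 finite elements (PSPG/SUPG), Womersley
  inlet, implicitly coupled RCR outlets with backflow stabilization —
  run to cycle periodicity with exact discrete inlet/outlet mass
  balance.
* **Wall shear analytics**: signed wall shear τ = μ ∂u_t/∂n, TAWSS maps
  `TAWSS(s) = (1/T)∫|τ| dt`, low-shear fractions against the clinical
  0.4 / 0.15 / 0.05 Pa thresholds, and pre/post-intervention comparison.

The methods vignette (`vignettes/graftflow-methods.Rmd`) documents the
model, its assumptions, all tunable parameters, and known limitations.

## Worked example

Synthesize a triphasic common-femoral duplex waveform, convert it to
volumetric flow through the Womersley relation, and drive a Windkessel
outlet with it:

```r
library(graftflow)

cfa <- synth_duplex_waveform(psv = 0.9, reverse_fraction = 0.3, T = 1,
                             phase = "triphasic", site = "CFA")
cfa
#> <velocity_waveform> site=CFA  T=1 s  n=256  mean=0.06745 m/s  range=[-0.2698, 0.8995]

blood <- fluid_properties(hematocrit = 0.43)
blood
#> <fluid_properties> rho=1060 kg/m^3  mu=0.004121 Pa s  nu=3.888e-06 m^2/s  (from hematocrit 0.43)

womersley_number(R = 4e-3, omega = 2 * pi, nu = blood$nu)
#> [1] 5.085236

Q <- flow_from_centerline(cfa, R = 4e-3, fluid = blood)
Q
#> <flow_waveform> site=CFA  T=1 s  n=256  mean=1.695e-06 m^3/s (1.7 mL/s)

p <- rcr_parameters(Rp = 1.2e8, C = 2e-9, Rd = 1.2e9)
round(range(rcr_pressure(Q, p)$P) / 133.32, 1)   # mmHg over the cycle
#> [1]  4.0 49.5
```

The waveform peaks at the prescribed 0.9 m/s PSV with a −0.27 m/s
early-diastolic reverse lobe; the conversion yields a 1.7 mL/s mean
common femoral flow, and the example outlet sees a 4–50 mmHg pressure
swing (a realistic distal-resistance outlet would be tuned with
`tune_rcr()` against measured daughter flows instead).

End-to-end analyses run from a single configuration:

```r
res <- run_case(fixture_occlusion_config("ci"), output_dir = "occ_out")
res
#> <case_result> 'occlusion': periodic at cycle 3, mass residual 9.78e-12
#>   global min TAWSS 0.09816 Pa in SFA_proximal (SFA wall, s = 16.9 mm)

itv <- run_intervention(fixture_occlusion_config("ci"), "SFA", c(0.004, 0.02))
```

The bundled `fixture_control_config()` (lesion-free, triphasic inflow)
and `fixture_occlusion_config()` (proximal edge stenosis + monophasic
inflow) are paired study conditions: the control's proximal SFA stays
above 0.4 Pa everywhere, the occlusion case drops to ~0.1 Pa minimum
TAWSS with a third of the proximal SFA wall below 0.15 Pa, and virtual
angioplasty of the edge stenosis raises the proximal minimum. A thin
command-line wrapper for these verbs is installed at
`inst/cli/graftflow.R`.

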