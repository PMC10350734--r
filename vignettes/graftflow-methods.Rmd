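---
title: "Methods: pulsatile hemodynamics and wall shear analysis in graftflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile hemodynamics and wall shear analysis in graftflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

graftflow computes pulsatile blood flow and wall shear stress in a
parametric planar model of the femoral bifurcation — the common femoral
artery (CFA) dividing into the superficial (SFA) and deep (DFA) femoral
arteries — for studying the low-shear conditions associated with
thrombosis of SFA endografts. The question it serves: do the boundary
conditions and lesions seen in a given configuration produce wall regions
whose time-averaged wall shear stress (TAWSS) falls below the levels
(0.4, 0.15, 0.05 Pa) associated with proatherogenic endothelial activity
and fibrin accumulation, and does restoring a stenosed segment
("virtual angioplasty") relieve them?

The flow model is incompressible Navier–Stokes with constant density
(1060 kg/m^3 by default) and constant Newtonian viscosity, in a rigid
2D planar lumen. Both simplifications are standard first-order choices for
arterial WSS work: published sensitivity studies place the Newtonian and
rigid-wall effects on TAWSS near or below 10% and, more importantly for
this package's use, they do not move the *location* of low-TAWSS regions.
The reduction from a patient 3D lumen to a planar channel tree is the one
deliberate scope reduction: it keeps the machinery (Womersley inlet,
Windkessel outlets, separation downstream of the flow divider, TAWSS
thresholding) while making runs tractable on a single core. Quantities
that depend on three-dimensionality (helical flow, out-of-plane
secondary vortices) are outside what this model can show.

An out-of-plane `depth` converts between volumetric flows (m^3/s) and
the planar solver's per-depth flows. The default, `pi * R_inlet / 2`,
makes the channel's mean velocity equal that of a circular tube of the
inlet radius carrying the same volumetric flow, so velocities and shear
magnitudes stay physiologic.

## Geometry and the virtual-angioplasty operator

Vessels are straight channels with half-width
`a(s) = R_nominal * f(s)` along an axial coordinate `s` (measured from
the inlet plane for the CFA, from the bifurcation apex for daughters).
Lesions multiply `f` by a C1 cosine bump: a stenosis of severity `sigma`
reduces the local width — and hence the local cross-sectional area at
fixed depth — by `(1 - sigma)` at the lesion center, so a reported
"50%-area stenosis" has `sigma = 0.5`. The cosine profile avoids
curvature jumps at the lesion shoulders that would create spurious shear
singularities. An endograft is an annotation on a wall interval (rigid,
smooth wall — no strut micro-geometry, whose TAWSS fluctuations are of
order 0.05 Pa and below the contrasts of interest here).

Virtual angioplasty ("cylindrical inflation") restores the wall over an
interval to nominal caliber. It is implemented as a C1 mask on each
lesion's bump: zero on the interval core, blending to one over bands of a
tenth of the interval length just inside its ends. Masks are stored as
cleared intervals on the lesion, so reapplying the same interval is
exactly idempotent, geometry outside the interval is untouched, and a
lesion strictly inside the interval is removed exactly.

Meshing is multiblock-transfinite: one mapped structured block per
vessel, conforming at the junction plane (the apex node is shared), quads
split into triangles. Daughter blocks blend their cross-section
orientation and width from the junction segment to the vessel's own axis
over a short blend length, which keeps cells well-shaped at the flow
divider. The mesher refuses resolutions coarser than the narrowest local
half-width and meshes whose minimum triangle angle falls below 10
degrees. Wall nodes carry their vessel, side, axial coordinate, true arc
length, and a two-layer wall-normal sampling stencil used later for
shear recovery.

## Waveforms and Womersley boundary conditions

Duplex-like centerline velocity waveforms are synthesized as sums of
Gaussian lobes: triphasic (forward systolic peak of height PSV at 0.12 T,
reverse lobe of depth `reverse_fraction * PSV` at 0.30 T, small late
forward wave at 0.55 T) or monophasic (forward lobe plus a broad forward
diastolic component, clamped non-negative as a duplex envelope is). The
lobe widths (0.035/0.045/0.07 T) are narrow enough that the printed PSV
and reverse fraction are met to well under 0.1%. No patient PSV or
reverse-flow magnitudes are published for this setting, so the defaults
are package choices; noise is additive Gaussian on samples, seeded.

Centerline velocity converts to volumetric flow harmonic-by-harmonic
under the fully developed Womersley assumption. For harmonic `n` at
Womersley number `alpha_n = R sqrt(n w0 / nu)`,

    Q_n / u_c,n = pi R^2 (1 - 2 J1(L)/(L J0(L))) / (1 - 1/J0(L)),
    L = i^{3/2} alpha_n,

with the Poiseuille ratio `pi R^2 / 2` for the mean. The tube form is
used for duplex conversion (the measurements are made in circular
vessels); the planar-channel cosh-form equivalent supplies the solver's
inlet profile. Complex-argument Bessel functions are evaluated with the
periodic trapezoid rule on `J_n(z) = (1/2 pi) \int_0^{2 pi}
cos(n t - z sin t) dt`, which is spectrally accurate at arterial
Womersley numbers; both variants are verified against numerical
quadrature of their radial profiles to better than 1e-6 relative.
Ten harmonics are kept by default — femoral waveforms are band-limited
and the residual above harmonic 10 is negligible for the templates used.

Blood viscosity defaults to 3.5 mPa s, or is derived from hematocrit via
`mu = mu_plasma (1 + 2.5 H + 7.35 H^2)` with plasma viscosity 1.2 mPa s.
The exact hematocrit relation used in patient-specific practice varies;
this quadratic form is monotone, has the right plasma limit, and is
configurable, which is all the package relies on.

## Windkessel outlets and tuning

Each outlet carries a 3-element Windkessel: `C dP_d/dt = Q - (P_d -
P_ref)/R_d`, `P = P_d + R_p Q`, integrated with the implicit trapezoid
rule. Tuning to duplex-derived daughter flows is two-stage. Stage 1 sets
the total resistance from a mean-pressure target (default 100 mmHg — a
documented default, since femoral pressures are not routinely measured
in this setting), splits `R_p : R_d = 0.09 : 0.91` and takes
`R_d C = T/3` —
conventional peripheral-outlet heuristics. Stage 2 refines all six
log-parameters jointly with Nelder–Mead against the L2 mismatch between
target flows and the flows of a lumped junction surrogate: the two
branches (each the vessel's lubrication-theory resistance in series with
its Windkessel) share one junction pressure and split the inlet flow.
Because outlet *flows* constrain only impedance ratios, the mean outlet
pressure target enters the objective as a penalty; without it the total
resistance level is unidentifiable. Tuning succeeds when each outlet's
mean-flow error is within tolerance (default 5%); parameter-recovery
tests require total resistance back within 5% and the flow split within
1% when the targets are generated by known parameters.

## Flow solver

The solver is P1–P1 finite elements on triangles with PSPG pressure
stabilization and SUPG streamline stabilization, advanced per time step
as a linearized (Oseen) system with element-centroid advection velocity
and solved directly with a sparse LU factorization:

* convective runs: backward Euler, matrix reassembled each step
  (advection, SUPG weights and backflow terms change), chosen for
  robustness at femoral Reynolds numbers on coarse meshes;
* Stokes runs (`convection = FALSE`): Crank–Nicolson with a constant
  matrix factorized once — this is the path used for the oscillatory
  verification problems, where the exact solution has no convective
  term, and it is second-order in time and space (observed L2 rate ~2.0
  against the oscillatory channel closed form).

The stabilization parameter is
`tau = ((2|u|/h)^2 + (12 nu / h^2)^2)^{-1/2}` *without* the usual
`2/dt` term: at the small time steps used here the `dt` term would
switch the pressure stabilization off and re-admit the checkerboard
mode. With this choice the PSPG term vanishes for the constant test
function, so summing the discrete continuity equations gives exactly
`\oint u_h . n = 0`: the inlet/outlet flow balance measured with the
same boundary quadrature is conserved to solver precision (observed
residuals ~1e-12, asserted < 1e-3).

Boundary conditions: no-slip walls; the inlet imposes the channel
Womersley profile reproducing the inlet flow waveform (ramped from rest
over the first half cycle to suppress the startup transient); each
outlet is a traction boundary with `sigma . n = -P_out n`. The
Windkessel coupling uses the trapezoidal update to express
`P_out^{n+1} = alpha + beta Q^{n+1}`, and the implicit `beta Q` part
enters the matrix as a symmetric rank-one boundary term — no
sub-iterations between the 0D and 2D models. During reverse outlet flow
a backflow-stabilization term `-beta_bf (u^n . n)_- (u, v)` (default
`beta_bf = 0.2`) is added with its coefficient lagged one step;
triphasic waveforms guarantee outlet backflow, and uncontrolled traction
outlets diverge without it.

The run advances whole cardiac cycles until every outlet flow waveform
changes by less than `periodicity_tol` in relative L2 between
consecutive cycles (`check_periodicity` returns the first compliant
cycle), and the final cycle's full-resolution velocity and pressure are
kept.

## Wall shear and TAWSS

Signed wall shear is `tau = mu du_t/dn` with `n` the inward normal and
positive sign meaning traction in the downstream wall tangent. The
derivative is recovered from a one-sided quadratic through the no-slip
wall value and the two interior grid layers of the wall stencil — exact
for parabolic profiles, so the steady-channel closed form is met to a
few tenths of a percent at the default resolution.

TAWSS is the time average of `|tau|` over one cycle (not the magnitude
of the time-averaged vector — the standard definition, and the one that
penalizes oscillating-but-nonzero shear correctly). With uniform
periodic sampling the trapezoid rule reduces to the sample mean; against
`tau = A sin(w0 t)` (TAWSS `2A/pi`) the integration error at the default
storage (every step, >= 200 per cycle) is far below the 0.1% contract.
"Area below threshold" is realized as wall arc-length fraction (with
absolute arc length alongside), per reporting segment — by default CFA,
proximal daughter segments (first 3 cm, matching the clinically relevant
near-bifurcation zone where endograft edges sit) and distal remainders —
and both the per-segment minima and the global minimum location are
reported, since published per-case minima do not state whether they are
nodal or regional.

## Synthetic study conditions

The bundled fixtures define the study conditions and are first-class,
tested code:

* `fixture_control_config()`: lesion-free bifurcation, triphasic
  waveforms everywhere (CFA PSV 0.9 m/s, reverse fraction 0.3),
  hematocrit 0.43.
* `fixture_occlusion_config()`: a severity-0.5 edge stenosis in the
  proximal SFA immediately upstream of an annotated endograft whose
  proximal edge lies within 3 cm of the bifurcation, monophasic CFA and
  SFA waveforms (no reverse phase, hence no backflow washout of
  separation zones), hematocrit 0.30.

Vessel calibers (CFA 4 mm, SFA 3 mm, DFA 2.5 mm half-widths) and all
PSVs are plausible femoral values — no patient geometry or velocity data
are published for this setting — with outlet PSVs set so the
duplex-derived daughter mean flows are consistent with the inlet mean
flow, as tuning targets must be. What the paired fixtures emulate is the
*contrast* between a patent and a thrombosis-prone configuration:
separation and low TAWSS downstream of the flow divider and stenosis,
sustained by the absence of reverse flow. What they do not emulate:
patient-specific lumen irregularity, 3D secondary flow, measurement
error in duplex angles, or CTA segmentation error; passing fixture
tests therefore validates the machinery and the direction of the
clinical contrast, not patient-level numbers.

## Problem sizes and numerical defaults

Two named profiles are used throughout. The `default` profile (mesh edge
= smallest nominal radius / 8, `dt = T/1000`, up to 6 cycles at 1%
periodicity tolerance) is the production setting. The `ci` profile (mesh
edge = radius / 4, `dt = T/200`, up to 3 cycles at 5%) is the
package's fast end-to-end setting used by the test-suite fixtures and
the acceptance script; a full fixture run at this size (~2700 nodes,
400-600 steps) completes in a few minutes on one core. The verification
problems (channel oracles) run at the default resolution. Fixture TAWSS
minima carry a few-percent numerical margin at the `ci` profile (a
one-step refinement of the occlusion fixture moves the proximal-SFA
minimum by about 4%), so case-vs-case and pre-vs-post contrasts are
robust while absolute minima should not be over-read.

One consequence worth stating: under the bundled occlusion conditions
(severity-0.5 edge stenosis, monophasic inflow) the proximal-SFA TAWSS
minimum converges to just under 0.1 Pa — clearly in the adverse band
below 0.15 Pa, but not below the deepest clinical threshold of 0.05 Pa.
The paired-fixture contrast therefore discriminates at the 0.4 and
0.15 Pa thresholds, while at 0.05 Pa both fixtures report zero wall
fraction; producing sub-0.05 Pa regions in this analogue would require a
more severe edge stenosis or lower inflow than the defaults chosen here,
and those defaults are deliberately not revisited.

## Known limitations

* Planar 2D: no out-of-plane flow; reported magnitudes are analogue
  values, comparisons (case vs case, pre vs post) are the meaningful
  output.
* The structured quad-split triangulation is not mirror-symmetric, so
  symmetric problems show discretization-level (few percent) asymmetry.
* Backward-Euler convective stepping is first-order and dissipative;
  separation extents at the `ci` profile are conservative.
* No shear-thinning rheology (the Newtonian assumption shifts low-WSS
  thresholds in vitro), no fluid–structure interaction, no transition
  or turbulence modeling.
* The Windkessel tuning surrogate lumps branches by lubrication theory;
  strongly non-Poiseuille branches (severe stenoses at high Reynolds)
  bias the branch resistance low.
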