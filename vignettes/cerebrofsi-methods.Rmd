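---
title: "Modelling stenosed and aneurysmal cerebral bifurcations with cerebrofsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stenosed and aneurysmal cerebral bifurcations with cerebrofsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cerebrofsi)
```

## What the package models

`cerebrofsi` is a desk-scale pipeline for studying how atherosclerotic
stenosis alters the hemodynamics of an intracranial artery bifurcation, and
what that implies for the initiation of a saccular aneurysm. Three
physiological conditions are compared on a common parametric geometry:

* **INTACT** — a healthy bifurcation: a parent artery of 3.2 mm diameter
  splitting into two 2 mm daughters;
* **ICAS** — the same artery occluded by atherosclerotic stenoses (three by
  default: one in the parent, one per daughter);
* **ACA** — the same bifurcation carrying a saccular aneurysm of 2.5 mm
  radius at the apex, with the same plaques (an atherosclerotic aneurysm).

The quantities of interest are the wall shear stress (WSS) field along the
lumen, the velocity and pressure fields, and the flow-induced wall
displacement, compared across the three scenarios and at two target points:
the middle of the arterial wall at the bifurcation apex, and the vertex of
the aneurysm sac.

The reference discretization is a **2D planar midplane** model. This is the
central desk-scale reduction: the constitutive models (blood rheology, wall
elasticity) are identical to their 3D counterparts, the qualitative
hemodynamics (jet formation at stenoses, apex impingement, sac recirculation)
are preserved, but absolute field values of a 3D vessel are not reproduced.
All comparisons against 3D reference values are therefore band and ordering
checks, never point matches.

## Blood rheology

Blood is a yield-stress, shear-thinning fluid; the package uses the
Herschel–Bulkley law
$$\eta(\dot\gamma) = \kappa\,\dot\gamma^{\,n-1} + \frac{\tau_0}{\dot\gamma}$$
with the whole-blood constants
$\kappa = 8.9721\times10^{-3}\ \mathrm{Pa\,s}^n$, $n = 0.8601$,
$\tau_0 = 0.0175$ Pa, density $\rho = 1020\ \mathrm{kg/m^3}$, and a
Newtonian reference viscosity of 0.04 g/(cm s) = 0.004 Pa s used only for
Reynolds-number bookkeeping. The scalar shear rate is the second invariant
$\dot\gamma = \sqrt{2\,\dot\varepsilon:\dot\varepsilon}$ of the symmetric
rate-of-deformation tensor, which makes the law frame-indifferent.

Two numerical choices matter:

* **Regularization.** The yield term diverges as $\dot\gamma \to 0$. The
  package freezes the viscosity below `gamma_min = 1e-3` 1/s (bi-viscosity
  regularization). The cutoff only matters at stagnation points and deep
  inside recirculation zones; in the physiological shear range
  ($10^1$–$10^3$ 1/s) the law is untouched.
* **Units.** Everything internal is SI. The configuration loader converts
  CGS viscosities ("0.04 g/(cm.s)") and clinical pressures ("120 mmHg",
  1 mmHg = 133.322387415 Pa) on input.

With the printed parameters the Reynolds number of the parent artery is
$\rho V D/\mu = 1020 \cdot 0.23 \cdot 0.0032 / 0.004 \approx 188$ — firmly
laminar. (Nominal reports of Re in the low 200s for these conditions are not
recoverable from any combination of the stated velocity, diameter, density
and viscosity; the package always reports its own computed value.)

## Flow solver

Steady incompressible momentum and continuity are discretized with
equal-order linear triangles (P1–P1) and SUPG/PSPG stabilization, with an
orthogonal-subscale correction that subtracts the projected pressure
gradient from the stabilization residual. The correction is linear in the
pressure and assembled implicitly, so it adds no lag to the nonlinear
iteration; it removes the first-order consistency error plain PSPG leaves in
smooth flows — with it, the discrete scheme reproduces plane Poiseuille flow
to machine precision and converges at second order on the non-polynomial
Herschel–Bulkley profile.

Boundary conditions follow the study conditions: a parabolic inflow profile
with mean 0.23 m/s (peak 0.345 m/s in 2D), no-slip walls, and both outlets
at 4 kPa. The inlet is deliberately a velocity condition: prescribing both
an inlet velocity and an inlet pressure would over-determine an
incompressible problem, so the nominal 16 kPa (~120 mmHg) inlet pressure
enters only as the transmural datum at which the wall is prestressed
(below). Because both outlets carry the same pressure, the flow split is
determined by the geometry alone.

The two nonlinearities — convective transport and the shear-dependent
viscosity — are resolved by a staged fixed-point iteration:

1. **Picard phase** with Anderson acceleration (depth 4) until the relative
   velocity change falls below $10^{-3}$;
2. **terminal phase**: Newton linearization of convection (viscosity still
   lagged, as is robust for shear-thinning laws), under adaptively damped
   updates with a safeguarded one-mode extrapolation.

Convergence is declared at a relative velocity change below `picard_tol`
($10^{-8}$). The bi-viscosity kink makes the lagged-viscosity map
non-differentiable, and in yielded near-stagnant regions (the sac
recirculation, the wide plug of a low-velocity ramp step) it can become
locally non-contractive: progress then genuinely stops at some floor
(about $2\times10^{-7}$ for the aneurysm scenario at the default mesh,
higher for near-yield ramp states). The solver detects this stagnation and
accepts the iterate — always the last assembled-system solution, so discrete
mass conservation is unaffected — flagging the field with `stalled = TRUE`.
The stagnation floor (`stagnation_tol`, default $10^{-3}$) sits an order
below the spatial discretization error; intermediate quasi-static ramp
states use a visualization-accuracy floor of $10^{-2}$, while the final ramp
state keeps the caller's settings.

Discrete mass conservation is exact by construction: the continuity
equations are retained unmodified for every pressure unknown, so the sum of
boundary fluxes of any returned field vanishes to linear-solver precision
(validated at $10^{-11}$ or better in the tests).

## Arterial wall model

The wall is an incompressible neo-Hookean solid,
$W = C_1 (I_1 - 3)$, with $C_1 = 166$ kPa, i.e. shear modulus
$\mu_w = 2C_1 = 332$ kPa and small-strain Young's modulus $6C_1 \approx 1$
MPa. (The printed form of this energy in some sources reads $C_1(I_1-1)$,
which is nonzero in the undeformed state; the package uses the standard
$I_1 - 3$ so that the reference configuration is stress-free. $D_1 = 0$ is
interpreted as the exact-incompressibility limit: the volumetric term is
dropped and $J \equiv 1$ enforced.) Wall thickness is 125 µm on the artery
and 27 µm on the sac, blended linearly over a 0.3 mm band across the neck.

Two closed-form thin-wall equilibria serve both as model components and as
oracles:

* **Cylinder** (axially tethered, plane strain):
  $\mu_w(\lambda^2 - \lambda^{-2}) = P \lambda^2 R_0 / t_0$, with the
  closed-form root $\lambda = (1 - P R_0 / (\mu_w t_0))^{-1/4}$;
* **Sphere** (balloon): $P(\lambda) = 2\mu_w (t_0/R_0)(\lambda^{-1} -
  \lambda^{-7})$, with its limit point at $\lambda^\ast = 7^{1/6} \approx
  1.3831$; for the sac parameters the limit pressure is about 4.4 kPa.

### The membrane closure

A 1D string along the 2D wall curve has no hoop stiffness: under a uniform
transmural load it can only respond by catenary-like sagging between its
clamped ends, which neither matches the tube equilibrium nor the physics of
a pressurized vessel. The package therefore closes the 2D wall model with
two force paths per wall node:

* **arc-length string tension** from the plane-strain neo-Hookean law
  applied to segment stretch (plus the axial tether prestress tension
  $P_\mathrm{ref} R/2$), which supplies clamped-end smoothing and
  longitudinal load transfer; and
* a **nonlinear hoop (Laplace) foundation** representing the out-of-plane
  circumferential load path: the restoring transmural pressure of the local
  cylinder (artery) or sphere (sac) section, written about the prestressed
  as-meshed state.

For a uniform load the foundation dominates away from the clamps and the
update reproduces `tube_equilibrium()` exactly (verified to machine
precision mid-channel); near clamps the string term takes over. The
equilibrium is solved by Newton iteration on the free nodal positions with
an analytic tangent, with residuals measured relative to the as-meshed
reference state (whose internal forces are self-equilibrated by definition
of the prestressed configuration).

### Prestress

A 16 kPa transmural load on a *stress-free* sac would exceed its balloon
limit point (~4.4 kPa), and physiological displacements of tens of
micrometers are only consistent with perturbations about a loaded state.
The package therefore adopts the standard imaged-geometry convention: the
as-meshed wall *is* the equilibrium configuration at the reference
transmural pressure (16 kPa minus the configurable external pressure,
default 0). Prestretches follow by inverting the thin-wall relations with
the as-meshed radius — about 1.27 for the parent artery and, for the sac,
formally 1.63, which lies beyond the balloon limit point where the
neo-Hookean sphere softens. A real aneurysm wall at systemic pressure is
stabilized by collagen recruitment that the neo-Hookean law does not
represent, so the sac foundation is linearized on the stable branch with
the prestretch capped at 1.2 (`sac_prestretch_cap`). FSI wall loads are
tractions relative to the zero-flow hydrostatic datum (uniform outlet
pressure), and all reported displacements are flow-induced perturbations
about the prestressed state.

## Partitioned coupling

`solve_fsi()` iterates: steady flow solve on the current configuration →
full fluid traction $t = (-pI + 2\eta\dot\varepsilon)\hat n$ at the wall
(recovered gradients, absolute pressure) → membrane update → Aitken
under-relaxation (initial factor 0.5, clamped to [0.1, 1]) → mesh morphing
(wall nodes moved, interior relaxed by a graph-Laplacian solve) — until the
maximum interface displacement increment falls below $10^{-7}$ m, two
orders below the expected displacement signal. The steady formulation
replaces a full Arbitrary Lagrangian–Eulerian treatment: time terms vanish
at the quasi-static limit, so morphing the mesh between steady solves is
exact for the states reported. The default scenarios converge in about
three outer iterations, with flow-induced displacements of roughly 0.6 µm
(intact), 4 µm (stenosed) and 19 µm (aneurysm sac) — small, as expected for
perturbations about a prestressed state under flow-scale (not
pressure-scale) load changes.

The quasi-steady inflow ramp (`ramp_series()`, $\sin^2$ shape over 0.1 s in
50 steps) stands in for a transient start-up; at these Reynolds and
Womersley numbers the flow is quasi-static on the ramp time scale. Series
figures are truncated to 0.036 s to focus on the rising flank. Per-step wall
displacements in the report are one-way (traction → membrane) responses;
the fully coupled solution is computed at the final state.

## WSS extraction

The WSS is the tangential part of the viscous traction
$2\eta\,\dot\varepsilon\cdot\hat n$ on the lumen, evaluated with the local
converged effective viscosity (consistent with the generalized-Newtonian
momentum equation; a single constant viscosity would be inconsistent with
the rheology actually solved). The 3D tensor formula reduces to its 2×2
form on the planar discretization. Velocity gradients at wall nodes are
recovered by quadratic least-squares fits over two-ring node patches: the
fit is exact for quadratic fields, so plane-Poiseuille WSS is recovered to
machine precision and the dominant error on curved walls is the
discretization error of the flow itself (0.1–0.2 % on the developed
Herschel–Bulkley channel at the default mesh size). Wall medians are
weighted by the lumped edge length so they are stable under refinement.

## Geometry generation and meshing

No installed triangulation library is available (and determinism is a
contract), so the mesher is a deterministic block-structured construction:
a parent strip, a transfinite junction patch (a triangle for INTACT/ICAS,
a quad when the sac opens at the apex), two daughter strips (the second an
exact floating-point mirror of the first), and a polar patch for the sac.
Shared interface node arrays guarantee conformal merging; identical specs
produce byte-identical mesh files. Stenoses are C1 cosine wall insets whose
one-sided amplitude realizes the full occlusion degree at the throat
(throat width $(1-d)w$); the exported `stenosis_profile()` is the per-wall
half of that occlusion.

Dimensions not fixed by the study conditions carry explicit defaults chosen
once for physiological plausibility: bifurcation half-angle 50° (typical of
intracranial bifurcations), parent length 12 mm and daughters 10 mm (enough
development length at Re ≈ 190), stenoses of length 1.6 mm and degree 0.5
placed 4.8 mm upstream (parent) and 3.0 mm downstream (daughters) of the
apex on the outer walls, sac neck width 2.2 mm, thickness blend band
0.3 mm, and a target element size of 0.25 mm (about 1800–2500 nodes per
scenario). The `seed` recorded in the spec is part of the reproducibility
contract; the construction itself uses no randomness.

## What the generator does and does not emulate

The parametric geometries reproduce the printed study dimensions and the
qualitative flow features that drive the science: stenotic jets, elevated
throat WSS, apex impingement, sac inflow and recirculation. They do not
emulate patient-specific tortuosity, out-of-plane curvature, 3D secondary
flows, pulsatile waveforms, or the circumferential jet focusing of a real
3D neck. Consequently, passing tests demonstrate correctness of the
numerics and the stated 2D model — they do not certify 3D field magnitudes.
One known consequence: in the 2D midplane, opening the sac neck at the apex
*removes* the inner-wall impingement zone while the 3D neck-jet
amplification has no 2D counterpart, so the two stenosed scenarios peak
within about one percent of each other (ACA marginally above ICAS at the
default discretization, both roughly double the intact peak) rather than
showing the distinct separation a 3D model produces. The comparative
report's ordering flags are computed exactly as defined; the ACA-vs-ICAS
comparison should be read as a near-tie, not a robust margin.

## Numerical choices at a glance

| Quantity | Value | Why |
|---|---|---|
| mesh size | 0.25 mm | ~13 elements across the parent; WSS errors at the percent level; minutes-scale pipeline |
| `gamma_min` | $10^{-3}$ 1/s | regularization only at stagnation |
| stabilization constant | 1 | standard SUPG/PSPG scaling, fixed |
| `picard_tol` | $10^{-8}$ | far below discretization error |
| `stagnation_tol` | $10^{-3}$ | honest floor for non-smooth viscosity; flagged |
| `interface_tol` | $10^{-7}$ m | two orders below displacement signal |
| Aitken clamp | [0.1, 1] | robust partitioned coupling |
| `sac_prestretch_cap` | 1.2 | stable-branch linearization of the balloon |
| ramp | 0.1 s, 50 steps, $\sin^2$ | quasi-static start-up |

## Known limitations

* Planar 2D reduction: no secondary flows, no out-of-plane curvature; 3D
  field magnitudes are out of reach by design.
* Steady/quasi-steady only: no pulsatile waveform, hence no oscillatory
  shear indices (they require a cardiac cycle and are deliberately not
  computed).
* Laminar only; the solver warns beyond Re 1500.
* The membrane wall has no bending stiffness and no contact; the sac
  foundation beyond the balloon limit point is a stable-branch surrogate.
* The bi-viscosity law bounds attainable fixed-point precision in
  near-stagnant yielded regions (stagnation guard, documented above).

## Reproducing the study pipeline

```{r, eval = FALSE}
library(cerebrofsi)
report <- run_pipeline(NULL, "results/")   # all three scenarios, defaults
report
```

Every number in the report traces to a stored artifact (VTK fields, CSV
profiles and series) in the output directory, and re-running with the same
configuration reproduces the report bit for bit.
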