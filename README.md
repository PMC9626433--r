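# cerebrofsi

Fluid–structure interaction modelling of stenosed and aneurysmal cerebral
artery bifurcations, at desk scale, in R.

## The problem

Intracranial atherosclerosis narrows brain arteries with plaque; saccular
aneurysms balloon out of bifurcation apices. The two pathologies interact
through hemodynamics: a stenosis accelerates the blood into a jet, the jet
impinges on the wall downstream, and the resulting wall shear stress (WSS)
and pressure anomalies are prime suspects in arterial remodeling and
aneurysm initiation. Quantifying that interaction requires solving the
coupled problem of non-Newtonian blood flow and an elastic arterial wall.

`cerebrofsi` is a self-contained, fully parametric pipeline for that
question on an idealized planar (2D midplane) bifurcation. It is aimed at
vascular-biomechanics researchers and students who want a transparent,
tested, dependency-light implementation of every ingredient — not a wrapper
around an external solver. Three scenarios are built, solved and compared:

* **INTACT** — healthy bifurcation (parent Ø 3.2 mm, daughters Ø 2 mm);
* **ICAS** — the same artery occluded by three atherosclerotic stenoses;
* **ACA** — the same bifurcation carrying a saccular aneurysm (radius
  2.5 mm) at the apex, plaques included.

## The models

* **Blood**: Herschel–Bulkley generalized-Newtonian rheology
  η(γ̇) = κ γ̇ⁿ⁻¹ + τ₀/γ̇ with κ = 8.9721×10⁻³ Pa sⁿ, n = 0.8601,
  τ₀ = 0.0175 Pa, ρ = 1020 kg/m³ (bi-viscosity regularized below
  10⁻³ 1/s). Analytic plane-channel solutions (including the yield plug)
  serve as solver oracles.
* **Flow**: steady incompressible Navier–Stokes, P1–P1 finite elements with
  SUPG/PSPG stabilization plus an implicit orthogonal-subscale correction
  (nodally exact on plane Poiseuille; observed order ≈ 2 on the
  Herschel–Bulkley profile). Parabolic inlet of mean 0.23 m/s, outlets at
  4 kPa, no slip at the wall; Re ≈ 188.
* **Wall**: incompressible neo-Hookean membrane, W = C₁(I₁ − 3) with
  C₁ = 166 kPa; thickness 125 µm (artery) / 27 µm (sac). Closed-form
  cylinder and balloon equilibria (balloon limit point at λ = 7^(1/6),
  ≈ 4.4 kPa for the sac) are both model components and oracles. The wall is
  prestressed at the 16 kPa (~120 mmHg) reference transmural pressure in
  its as-meshed configuration.
* **Coupling**: partitioned quasi-static loop — flow solve, traction
  extraction t = (−pI + 2η ε̇)·n̂, membrane update, Aitken under-relaxation,
  mesh morphing — to an interface tolerance of 10⁻⁷ m.
* **Post-processing**: tangential WSS from quadratic least-squares gradient
  recovery, target-point time series along a quasi-steady inflow ramp, and
  a cross-scenario comparative report.

## Worked example

```r
library(cerebrofsi)

mesh <- build_scenario(scenario_spec("INTACT"))
flow <- solve_steady_flow(mesh, rheology_params(), flow_bcs())
wss  <- compute_wss(flow, mesh, rheology_params())
summarize_scenario(wss, flow, mesh)
```

prints

```
flow_field: 1827 nodes, Re = 187.7, converged in 17 Picard iterations
  peak |u| = 0.343 m/s, gauge pressure range [-0.01008, 67.64] Pa
INTACT: peak WSS 5.5 Pa (median 1.86), target WSS apex=0.000974 Pa
  peak |u| 0.343 m/s, peak p 4067.6 Pa
```

Reading: the inflow parabola peaks at 1.5 × 0.23 = 0.345 m/s; the healthy
wall sees WSS between ~1.7 Pa (straight parent) and 5.5 Pa (apex
shoulders), inside the 1–7 Pa physiological band; the apex target node
itself is a stagnation point, so its WSS is nearly zero; and the pressure
falls ~68 Pa from inlet to the 4 kPa outlets.

The full three-scenario comparison (FSI, ramp series, figures, JSON +
Markdown report) is one call:

```r
report <- run_pipeline(NULL, "results/")
```

A command-line front end with the same stages is provided in
`inst/cli/cerebrofsi.R` (`build`, `flow`, `fsi`, `wss`, `report`,
`validate`).

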