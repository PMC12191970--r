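---
title: "A desk-scale model of primary drying in upright and tilted bioreactor vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale model of primary drying in upright and tilted bioreactor vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyosim)
```

## The process being modeled

Protein-coated alginate microcarriers suspended in a trehalose/saline
solution are frozen and freeze-dried directly inside the cylindrical
suspension-bioreactor (SBR) tube in which the cells will later be expanded.
During the cycle the tube either stands upright (90° to the shelf) or rests
tilted at 22°. Tilting spreads the same 16 mL of frozen solution over a much
larger free surface, and the tilted contents dry out far sooner than the
upright ones. `lyosim` is a compact simulator of the primary-drying
(sublimation) stage built to quantify that orientation effect: it predicts
the average normalized remaining ice content $s(t)$ of both configurations
over the 31.5 h primary-drying window of the reference cycle.

## Governing model

Per unit volume of frozen matrix, the remaining normalized ice content $s$
depletes as

$$\frac{\partial s}{\partial t} = -\frac{\dot m}{\rho_{ice}\,\varepsilon_0},$$

where $\varepsilon_0$ is the initial ice volume fraction and $\dot m$ the
volumetric sublimation rate. The rate is kinetic (Hertz–Knudsen), driven by
the deficit between the ice saturation pressure and the local vapor
pressure $p$:

$$\dot m = S_v\,\alpha\,(p_v(T) - p)\sqrt{\frac{M_v}{2\pi R T}},$$

with the saturation pressure over ice from the Murphy–Koop correlation
(valid above 110 K)

$$p_v = \exp\!\left(9.550426 - \frac{5723.265}{T} + 3.53068\,\ln T -
0.00728332\,T\right),$$

and every kilogram of sublimed ice consumes the heat of sublimation,
$\dot Q_{subl} = \dot m\,\Delta H_s$. Vapor leaves through the already-dried
porous cake by Darcy flow; heat arrives by conduction through the solid with
the sublimation sink at the front. When the local pressure exceeds
saturation the flux is clamped to zero: re-deposition is not modeled,
which keeps $s$ monotone (at a 5 Pa chamber pressure the deposition branch
is never approached).

## Geometry and discretization

The vessel is a cylinder (default inner radius 14.5 mm, length 115 mm — a
50 mL-class SBR tube; exact tube dimensions vary by vendor, and only the
ratio of drying behaviors between orientations is treated as robust to
them). It rests on the
shelf plane $z = 0$, axis tilted in the $x$–$z$ plane, lowest surface point
touching the shelf. The solution froze under gravity, so the frozen body is
the cylinder clipped by a horizontal plane whose height is solved from the
fill volume by monotone bisection (`fillPlaneHeight()`, relative tolerance
$10^{-6}$). The exposed (vacuum-facing) surface is that plane clipped to
the cylinder: a circle of area $\pi r^2$ upright, an ellipse of area up to
$\pi r^2/\sin\theta$ when tilted — at 22° and 16 mL the ellipse is partly
clipped by the lower end cap, giving an exposed-area ratio of about 2.4
rather than the unclipped $1/\sin 22° = 2.67$.

The domain is voxelized on a uniform lab-frame grid (`voxelize()`).
Boundary cells carry the fraction of their volume inside the frozen region
(corner convexity test plus $4^3$ midpoint subsampling with exact clipping
of the horizontal fill plane). Faces are tagged *exposed* (frozen cell
against headspace, weighted by the in-vessel face fraction), *wall*
(adiabatic) and *shelf contact*. The frozen body is static: drying is
tracked through the per-cell ice content, and the sublimation front is the
emergent $s>0$/$s=0$ boundary, not a deforming mesh.

**Specific surface area at the front.** The material parameter $S_v$
converts areal kinetic flux into a volumetric sink for an unresolved
sublimating medium, and the closed-form operations
(`volumetricSublimationRate()`) use it as such. The voxel solver, however,
resolves the front: there the sublimating area per unit volume is the
geometric interface density of the front cell (interface face area divided
by cell volume). Using a fixed $S_v$ per front cell would make the front
speed proportional to the cell size and destroy mesh convergence; with the
geometric interface density the front speed
$\alpha J/(\rho_{ice}\varepsilon_0)$ is resolution-independent, and halving
the cell size changes the tilted drying time by under 2%.

## Thermal boundary conditions

The reference cycle holds the shelf at its maximum-cooling setpoint
(−55 °C by default) throughout primary drying, with the chamber at
0.05 mbar. Ice at 218 K has $p_v \approx 2$ Pa — *below* the 5 Pa chamber
pressure — so a sample fully equilibrated with the shelf cannot sublime at
all. Since both configurations demonstrably dry, heat must enter
predominantly from the near-ambient chamber environment through the
vacuum-exposed surface — the same mechanism that makes the orientation
effect an *exposed-surface* effect (a larger free surface carries higher
heat *and* mass transfer). The model therefore uses:

* **Exposed surface**: exchange with the chamber environment at
  `T_ambient` (293.15 K) with coefficient `h_exposed` (default
  12 W m⁻² K⁻¹). Radiative exchange between a high-emissivity cake surface
  and near-ambient chamber walls contributes
  $\varepsilon\sigma(T_w^2+T^2)(T_w+T) \approx 5\text{–}7$ W m⁻² K⁻¹ at
  near-unity view factor; free-molecular gas conduction at 5 Pa adds a few
  more.
* **Shelf contact**: exchange with the shelf at its schedule temperature
  with coefficient `h_shelf` (default 13 W m⁻² K⁻¹), applied over the
  *physical* contact area — the vessel surface within a 0.5 mm tolerance of
  the shelf plane. Upright, that is the full base disk; at 22° it is a
  ~10 mm² patch at the rim touching the shelf, so the tilted vessel is
  nearly decoupled from the cold shelf while the upright one is actively
  chilled through its base. Normalizing the conductance to this analytic
  area (rather than to a resolved strip of mesh faces whose width scales
  with the cell size) is what keeps the shelf coupling mesh-independent.
  The coefficient sits below glass-vial values (20–65 W m⁻² K⁻¹) because a
  polypropylene tube base in imperfect contact conducts less.
* **All other walls**: adiabatic; chamber radiation onto the side walls is
  neglected.

The pair (12, 13) was fixed from a reduced-order energy-balance analysis of
the two-configuration system before any full simulations were run, and both
are ordinary configurable parameters. This boundary design is the model's
single largest source of structural uncertainty and is deliberately exposed
rather than buried.

Dried (ice-free) cells retain pure-ice conductivity and heat capacity —
the working simplification that all material properties match pure ice,
adequate for a drying-rate *comparison* but not for absolute cake
temperatures.

## Vapor transport

The dried cells form an open pore network carrying Darcy flow. Each
time step solves the quasi-steady mass balance on that network
(`darcyPressureSolve()`): face transmissibilities
$\rho_v \kappa/\mu \cdot A/\Delta x$ with ideal-gas density lagged from the
previous pressure iterate, Dirichlet chamber pressure across exposed faces
(half-cell spacing), no-flux walls, and the Hertz–Knudsen front flux
coupled *implicitly* as a linear exchange term toward $p_v(T_{front})$ —
the system is a symmetric M-matrix solved by sparse Cholesky, and front
fluxes that would reverse (deposition) are deactivated in an outer clamp
loop. Interior frozen cells, having no escape path, are reported at their
saturation pressure; the network pressure can never fall below the chamber
pressure. The dried-layer permeability defaults to $10^{-8}$ m²: a
Kozeny–Carman estimate for a 97%-porosity cake templated by ~50 µm ice
crystals, at the open end of reported cake resistances — the single most
uncertain transport parameter, and configurable.

## Time stepping

Each step, in order: boundary conditions from the schedule → quasi-steady
pressure solve → explicit ice depletion → implicit (backward-Euler) heat
conduction with the step's sublimation heat as a sink. The step size
adapts between 1 s and 300 s on a geometric ladder (so cached Cholesky
factorizations of the constant heat operator are reused), constrained so
no cell's ice content changes by more than `cap` (default 0.02) per step;
cells within one cap of empty are exempt — they floor at zero and the
truncated residual stays in the ice, accounted exactly by the mass ledger.
Mass conservation closes to machine precision, and the energy ledger
equals $\Delta H_s$ times the sublimated mass by construction of the same
accumulator. Halving the cap moves the tilted drying time by under 0.1%.

The average remaining ice is the frozen-volume-weighted mean of $s$,
normalized to 1 at the window start; the zero-ice time is the first
crossing of $10^{-3}$, linearly interpolated between steps (exact zero is
asymptotic in floating point).

## The reduced one-dimensional front model

`movingFront1d()` collapses a scenario onto a column of area equal to the
exposed surface: a planar front at depth $x_f$ recedes under the areal
Hertz–Knudsen flux, with the front pressure from the closed-form
quasi-steady compressible Darcy resistance of the dried layer and the
remaining ice treated as a thermal lump heated through the surface
(surface exchange in series with dried-layer conduction; exact exponential
relaxation of the lump energy balance, stable for any step). It serves as
an independent cross-check: for the upright column it reproduces the voxel
solver's drying behavior to within a few percent, and in the
kinetics-limited limit it recovers the closed-form drying time
$L\rho_{ice}\varepsilon_0/J$ exactly. For the tilted vessel the
constant-area column misrepresents the wedge-shaped fill, so the voxel
solver is authoritative there.

## Calibration design

The model has one free kinetic scalar, the evaporation (accommodation)
coefficient $\alpha$. Everything else is fixed a priori (pure-ice
properties, geometric defaults, the boundary coefficients above).
`calibrateAlpha()` bisects $\log\alpha$ so that the tilted scenario's
zero-ice crossing matches the observed ~15.5 h, verifying bracket
monotonicity at the endpoints; the calibrated default is
$\alpha = 4.87\times 10^{-3}$, physically plausible for ice sublimation
through a partially resistive interface. The upright configuration is
deliberately *not* fitted: run with the identical parameter set it retains
about 40% of its ice at 31.5 h, against the observed ~33% — a one-free-
parameter, two-observation consistency check, not a replication. The
zero-ice event is defined as the $10^{-3}$ crossing of the average
normalized ice content, since exact zero is asymptotic in floating point.

## The scenario generator

`randomScenario()` exists for property-based testing: it samples vessel
radius 10–20 mm, length 80–150 mm, tilt 15–90°, fill 20–60% of capacity
(rejecting fills whose free surface is clipped by the end caps),
$\alpha \in [10^{-3}, 1]$ log-uniformly and chamber pressure 1–20 Pa —
the neighborhood of realistic desk-scale freeze-drying, not any particular
instrument. It emulates geometry and operating-point diversity; it does
*not* vary formulation physics (porosity, permeability, thermal
properties), so the property suite demonstrates robustness of the
*orientation ordering* (more tilted never dries slower, all else equal)
rather than validity across formulations. Passing tests on generated
scenarios say nothing about absolute drying times of real products.

## Problem sizes and runtimes

The default resolution is a 2 mm cell (~2,800 frozen cells for the 16 mL
fill, ~14 cells across the diameter), chosen so a full 31.5 h simulation
runs in tens of seconds and the complete calibrate-and-compare experiment
in a few minutes on one core; the mesh-halving and cap-halving checks
bound the associated discretization error at a few percent, well inside
the structural uncertainty of the boundary conditions. Finer cells
(`cell_size = 1e-3`) change the headline numbers by under 2%.

## Known limitations

* Primary drying only: no bound-water desorption, no secondary-drying
  kinetics; the simulated window is the 31.5 h primary-drying segment.
* The thermal boundary (radiative-equivalent surface coefficient, shelf
  contact) is an effective model with hand-set coefficients, not a
  first-principles chamber radiation solution.
* Pure-ice properties for the frozen matrix *and* the dried cake; no
  glass-transition, collapse or meltback physics.
* Cartesian voxels staircase the cylinder wall; exposed areas are
  face-weighted to compensate, but wall-adjacent transport is first-order
  accurate at best.
* The vessel interior above the fill is treated as chamber (open, vented
  lid); lid or membrane vapor resistance is not modeled.
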