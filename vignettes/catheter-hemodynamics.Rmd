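---
title: "Desk-scale hemodynamics of peripheral intravenous catheters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale hemodynamics of peripheral intravenous catheters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Peripheral intravenous catheters (PIVCs) fail at notoriously high rates, and
several failure pathways — phlebitis, thrombosis, occlusion — are mechanistic:
they depend on the hemodynamic environment the catheter creates inside the
vein. Following Virchow's triad, the quantities of interest are endothelial
injury (wall shear stress, WSS), blood trauma (hemolysis), and flow stasis
(residence time). `pivcflow` implements a desk-scale computational study of
these quantities across the controllable PIVC parameters: catheter gauge
(18G vs 20G), insertion angle (5-20 degrees), tip position (centre of the
vein vs adjacent to the wall), and saline infusion rate (2.1, 50 and
300 mL/min, i.e. slow rehydration, rapid infusion, and forceful flushing).

The vessel is an idealized straight cephalic vein: diameter 2.4 mm, length
100 mm, steady venous inflow of 28 mL/min, rigid walls, no valves. Blood and
saline are Newtonian with densities 1050 and 1005 kg/m^3 and viscosities
2.78 and 1.02 mPa.s. (These viscosities are sometimes quoted in Pa.s in the
literature; that would be three orders of magnitude above physiological, so
the constructors normalize units explicitly — see `fluid_properties()`.)

## Model reduction: the 2-D mid-plane

The full problem is three-dimensional and, at the flushing rate, turbulent.
This package deliberately solves a *reduced-order* problem sized for a
laptop: the steady incompressible Navier-Stokes equations on the 2-D
mid-plane through the catheter axis,

$$ (\mathbf{u}\cdot\nabla)\mathbf{u}
   = -\tfrac{1}{\rho}\nabla p + \nabla\cdot(\nu(f)\nabla \mathbf{u}),
   \qquad \nabla\cdot\mathbf{u} = 0, $$

with the mixture kinematic viscosity $\nu(f)$ linear in the blood mass
fraction $f$. Boundary conditions follow the study design: a parabolic
venous inflow, a parabolic saline jet at the catheter inlet, zero gauge
pressure at the outlet, and no-slip rigid walls.

Mapping 3-D volumetric rates onto a plane requires a choice. The default
(`equivalence = "mean_velocity"`) reproduces each inlet's 3-D mean velocity
$Q/A$, preserving the jet velocity scale that drives wall shear. The
alternative (`"flux_ratio"`) preserves the blood:saline flux ratio instead,
so that the outlet flux-weighted blood fraction equals
$Q_{vein}/(Q_{vein}+Q_{cath})$; use it when the mixing balance is the
quantity of interest. Both the nominal rates and the imposed 2-D fluxes are
recorded on the `flow_bc` object.

Two consequences of the reduction deserve emphasis:

* **Absolute magnitudes are not comparable to 3-D.** The 3-D study reports
  maximum WSS thousands of times the patent-vein value and localized
  turbulent jets; a 2-D laminar mid-plane cannot and should not reproduce
  those numbers. The package's claims are therefore *directional*: WSS
  rises with infusion rate, stasis falls with rate, residence time falls
  with insertion angle. These directions are asserted by the test suite on
  the desk-scale sweep.
* **Edge-position damming.** In the mid-plane, an edge-positioned catheter
  spans nearly the whole vessel height, so the entire venous flow must
  squeeze through the 0.10 mm standoff gap beneath the tip; in 3-D the flow
  passes around the catheter sides. The squeeze flow produces a high,
  nearly rate-independent wall shear under the tip that masks the
  infusion-driven signal. For this reason the rate-trend property is
  evaluated on centre-position geometry, while edge geometry (where wake
  and stasis physics are meaningful) carries the angle and stasis trends.

## Geometry and grid

`build_domain()` rasterizes a configuration onto a uniform Cartesian grid
(stair-step masking, default 0.1 mm cells, at most a quarter of the
catheter's inner diameter). The vein is a rectangle with one-cell wall
layers; the catheter is an angled channel of wall thickness $(OD-ID)/2$
entering through the near wall and ending in a blunt tip face perpendicular
to its axis. A uniform grid was chosen over local refinement: the masked
ghost-cell treatment (below) recovers parabolic near-wall profiles exactly,
which removes the main motivation for near-wall refinement at this scale.

Positions: a *centre* tip puts the catheter axis on the vessel centerline at
the tip face; an *edge* tip leaves a declared 0.10 mm standoff between the
outer surface and the far wall (a literal zero gap would close the mid-plane
entirely). The tip face sits at 40% of the vein length by default
(`tip_axial_mm`), leaving the longer downstream segment for wake and stasis
metrics; the wall-entry station follows from the insertion angle by
trigonometry. Clinically irrelevant combinations are excluded up front:
edge tips at 5 degrees (nearly the whole catheter would be intravascular)
and centre tips at 15-20 degrees (almost none of it would), leaving five
(position, angle) pairs per gauge.

## Flow solver

`solve_steady_flow()` is a pseudo-transient projection solver on a staggered
(MAC) grid:

* first-order upwind convection, second-order central diffusion;
* wall boundaries on cell faces via ghost values; tangential ghosts use a
  *quadratic* extrapolation ($u_{ghost} = (u_2 - 6u_1 + 8u_{wall})/3$), which
  reproduces a parabolic profile to machine precision — plane Poiseuille and
  Couette are recovered exactly at any resolution, and the wall-shear
  stencil $\tau = \mu\,(9u_1-u_2)/(3h)$ is consistent with it;
* an exact discrete pressure projection (sparse Cholesky, zero-pressure
  outlet), so each iterate is divergence-free to solver precision and the
  global mass imbalance at convergence is at roundoff;
* deterministic initialization (zero velocity, uniform pressure), no
  randomness anywhere in the solver;
* convergence when the normalized velocity residual falls below `tol`
  (default 1e-6; the orchestrated sweeps use 1e-5), capped at 50,000
  iterations with a diagnostic error carrying the residual history.

The time step follows a combined CFL/diffusion bound and adapts to the
current maximum speed. Density variation between the components (about 4%)
is neglected in the projection (reference density: blood); viscosity
variation is kept.

**High-rate closure.** The 300 mL/min flushing jet has a catheter Reynolds
number above 10,000; a 2-D laminar solve at that rate is neither stable nor
meaningful, and turbulence modelling is out of scope. Two declared closures
are offered. `"reynolds_scaled"` (the default in sweeps) reduces both
inflows so the catheter Reynolds number is at most 500, solves the reduced
problem, and rescales the velocity field linearly back to nominal rates —
a Stokes-flow extrapolation that preserves directions but ignores inertial
amplification, so the flushing-rate results are conservative and labelled
`scaled`. `"eddy_viscosity"` instead augments the molecular viscosity with
a constant eddy viscosity $\nu_t = 0.01\,U_{jet}\,ID$ from a mixing-length
estimate in the jet.

## Passive scalars

Blood mass fraction and residence time are steady advection-diffusion
scalars on the frozen flow (`solve_species()`, `solve_residence()`),
discretized with the same upwind fluxes and solved directly (one sparse
solve each). Upwinding makes the species operator an M-matrix, so the mass
fraction obeys the discrete maximum principle and stays in $[0,1]$.
Residence time carries a unit volumetric source (one second per second) and
zero inlet age — its solution is the mean age of fluid at each point.

The scalar diffusivity is set by a Schmidt number of 1000 relative to the
local kinematic viscosity (liquid-like mass diffusion; the upwind scheme's
inherent numerical diffusion dominates in practice and stabilizes the
solve). Near-stagnant recirculation cores make the steady age unbounded, so
values are capped at 1000 s and capped cells are counted and reported.
Because the literal field maximum lives in those capped corners, the run
summary reports both the capped maximum and the 99th percentile of the
vein-lumen residence distribution; the percentile is the well-posed summary
and is what the angle-trend property uses. The flow and species solves are
Picard-coupled (two outer passes by default) so the mixture viscosity feels
the saline plume.

## Hemodynamic metrics

`wall_shear()` extracts $\tau = \mu\,|\partial u_t/\partial n|$ on the vein
wall only (catheter-wall shear is deliberately excluded from endothelial
summaries) with the second-order one-sided stencil; profiles are indexed by
signed distance from the catheter tip. The blood-damage (hemolysis) rate
uses the power law

$$ \sigma = C^{1/\alpha}\,(\tau f)^{\beta/\alpha},
   \qquad C = 3.62\times10^{-7},\ \alpha = 0.785,\ \beta = 2.416, $$

where multiplying $\tau$ by the blood mass fraction $f$ discounts shear
applied to saline rather than to red cells. Because the study never states
how "blood damage" was reduced to one number, the summary reports both the
volume integral of $\sigma$ (primary; used for normalized ratios) and its
per-cell maximum. Stasis volumes are the percentage of the *vein lumen*
(catheter lumen excluded) whose residence time exceeds 1, 2 and 5 s. WSS
and damage are normalized by the patent-vein control computed with identical
grid settings; the control normalizes to exactly 1 by construction.

## Surrogate models and the critical flushing rate

The published quadratic surrogates $WSS = a x^2 + b x + c$ (infusion rate
$x$ in mL/s, valid on $[0, 10]$ mL/s) are carried verbatim in
`printed_models()`; `fit_wss_model()` fits the same form to simulation
output by least squares, and `critical_rate()` inverts a model against the
38 Pa endothelial injury threshold (Fry), returning the smallest
non-negative root plus a one-decimal presentation value, `NA` if the
threshold is not reached within validity. The threshold is plugged directly
into the model equation — the most literal reading of the source analysis;
no alternative normalization convention reproduces all four published
critical rates simultaneously, and only the 20G-edge value (0.3 mL/s) is
treated as checkable. The 20G-edge model's negative intercept is preserved
bit-faithfully; predictions below zero warn rather than clamp.

## Factorial statistics

The study design is fractional-factorial, so `study_subsets()` mirrors the
original analysis: separate between-subjects ANOVAs on the centre subset
(gauge x angle(5,10) x rate, 12 cells), the edge subset (gauge x
angle(10,15,20) x rate, 18 cells), and the position contrast at 10 degrees
(position x gauge x rate, 12 cells). With one observation per cell there is
no residual; following standard unreplicated-factorial practice the
highest-order interaction is pooled as the error term. Generalized
eta-squared is reported with all factors treated as manipulated, where it
reduces to $SS_{effect}/(SS_{effect}+SS_{error})$; in the general
formulation the denominator adds the summed measured-factor variance
components, none of which exist in this design. Responses are analysed on
the raw normalized scale by default (a `log_transform` flag exists, since
the responses span orders of magnitude and are usually plotted on log
scales).

## Synthetic data

Two generators make every stage testable without a solver run:

* `generate_analytic_field()` builds exact closed-form fields (plane
  Poiseuille, Couette, plug, stagnant, and an axisymmetric pipe with exact
  advection-only residence times and radial volume weights) on the solver's
  own grid, satisfying its divergence and no-slip invariants to machine
  precision (the plug profile is slip-walled by construction and is used
  only for residence checks). The axisymmetric fixture is the no-diffusion
  oracle for stasis: for pipe Poiseuille the stasis fraction at threshold
  $T$ is exactly $L/(4UT)$ once $2UT \ge L$.
* `generate_factorial_table()` emulates the study's 30-run response table
  with a multiplicative model, `baseline x factor multipliers x exp(noise)`.
  Noise is log-normal because the study's responses span orders of
  magnitude and are plotted on log scales. The default multipliers encode
  the observed effect directions (rate dominant: 1/8/60 across
  2.1/50/300 mL/min; edge position x4; 20G x2.5; angle modest), chosen once
  as a realistic emulation of the normalized-response surfaces. A single
  seeded stream per table makes output deterministic; the seed is recorded
  on the table.

## The study pipeline and problem sizes

`run_study()` executes the control first (it is the normalization
baseline), then every configured run; it assembles the tidy metrics table,
the stasis-by-rate table (configurations averaged within each rate, which
the absence of rate interactions permits), subset ANOVAs per metric when
the design is complete, and quadratic surrogate fits of normalized WSS
against rate with their 38 Pa critical rates. `report()` writes CSV tables,
a JSON manifest sufficient to re-run deterministic stages bit-identically,
optional VTK fields, and log-scale summary figures.

The default `"ci"` sweep is the package's desk-scale working size, chosen so
the whole suite runs in minutes on one CPU: a 48 mm vein (20 diameters, the
same 2.4 mm bore) at 0.15 mm cells, with the full rate ladder on the
20G/10-degree/centre geometry (300 mL/min Reynolds-scaled) and the edge
angle ladder at 2.1 mL/min, plus the control. The `"full"` sweep enumerates
all 32 study runs on the 100 mm vein at the same machinery and is available
behind a flag; it is compute-hours rather than compute-minutes.

```{r, eval = FALSE}
library(pivcflow)
res <- run_study(study_config("ci"), progress = TRUE)
print(res)
report(res, "pivcflow-out")
```

## Numerical choices, degenerate inputs, tie-breaks

* Convergence tolerances: momentum residual 1e-6 (solver default) or 1e-5
  (sweeps); scalar solves are direct.
* Discrete inlet faces are renormalized so each inlet's rasterized flux
  equals its analytic 2-D rate exactly; species balances then close on the
  imposed fluxes to solver precision.
* Zero infusion caps the catheter aperture: the lumen becomes a dead-end
  cavity and the tip-mouth recirculation decays with depth, leaving the
  deep lumen stagnant (asserted in the tests).
* Empty enumeration requests return empty lists, not errors; infeasible
  geometries (catheter longer than the insertion path, tip outside the
  vein, aperture outside the domain) raise configuration errors.
* One-cell-wide passages fall back from the quadratic wall ghost to linear
  reflection (the quadratic form needs two interior cells).
* Stasis thresholds must be positive; an empty stasis region is an error,
  as is a non-positive normalization baseline.

## Known limitations

* Absolute 3-D magnitudes (maximum WSS, damage ratios, absolute stasis
  percentages, recirculation geometry) are out of scope by design; only
  effect directions are claimed, and the edge-position mid-plane damming
  described above is the main structural artifact of the reduction.
* The Reynolds-scaled closure linearizes inertia; flushing-rate results are
  conservative lower bounds on shear amplification and are always labelled.
* The catheter tip is blunt; real tips are tapered and many have side
  eyelets. Venous valves, vessel compliance, pulsatility and non-Newtonian
  rheology are excluded, matching the source study's own exclusions.
* Passing the trend properties on synthetic and desk-scale runs shows the
  machinery is sound, not that a 2-D mid-plane predicts clinical
  hemodynamics quantitatively.
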