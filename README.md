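# pivcflow

Desk-scale computational hemodynamics of peripheral intravenous catheters
(PIVCs).

PIVCs are the most common invasive medical device, and up to half fail —
often for mechanistic, fluid-dynamic reasons: excessive wall shear stress
(WSS) injures the endothelium (phlebitis), shear lyses red cells
(hemolysis, platelet activation), and slow recirculating flow promotes
stasis and thrombosis. `pivcflow` simulates saline infusion through a
catheter into an idealized cephalic vein (2.4 mm bore, 28 mL/min venous
inflow) across the controllable parameters — gauge (18G/20G), insertion
angle (5–20°), tip position (centre/edge), infusion rate (2.1/50/300
mL/min) — and reports the hemodynamic environment each configuration
creates.

## What it computes

* **Flow**: steady incompressible two-component (blood/saline)
  Navier–Stokes on the 2-D mid-plane through the catheter axis; masked
  finite-volume projection solver on a staggered grid, parabolic inlets,
  zero-pressure outlet, no-slip walls. High-rate (turbulent in 3-D) runs
  use a declared Reynolds-scaled closure and are labelled as such.
* **Metrics**: vein-wall shear stress `tau = mu |du_t/dn|`; power-law
  hemolysis `sigma = C^(1/alpha) (tau f)^(beta/alpha)` with
  `C = 3.62e-7, alpha = 0.785, beta = 2.416` and `f` the blood mass
  fraction; residence time as a passive scalar with unit age source; venous
  stasis volumes above 1/2/5 s thresholds. WSS and damage are normalized to
  the patent (catheter-free) vein.
* **Surrogates**: the published quadratic models `WSS = a x² + b x + c`
  (infusion rate `x` in mL/s) per gauge/position, a least-squares fitter
  for simulation output, and inversion against the 38 Pa critical
  endothelial shear threshold.
* **Statistics**: fractional-factorial ANOVA on the study's subsets with
  generalized eta-squared (η²G) effect sizes.
* **Synthetic data**: exact analytic flow fixtures and seeded factorial
  response tables, so every kernel is testable without a solver run.

## Worked example

Catheter regime numbers and the critical flushing rates from the published
surrogate catalogue:

```r
library(pivcflow)

gauge_spec("20G")
#> Catheter 20G: ID 0.61 mm, OD 0.91 mm, length 35 mm

reynolds(saline_properties(), 300, 0.61)   # flushing a 20G catheter
#> [1] 10282.91                             # turbulent in 3-D (Re > 10^4)

pipe_flow_profile(28, 2.4)$tau_wall        # patent-vein WSS, axisymmetric
#> [1] 0.9567027                            # analytic 4*mu*Q/(pi R^3) = 0.956 Pa

critical_rate_table()
#>                   label threshold_Pa rate_mL_s presented_mL_s
#> 18G-central 18G-central           38 2.2740963            2.3
#> 18G-edge       18G-edge           38 0.7651350            0.8
#> 20G-central 20G-central           38 1.2749296            1.3
#> 20G-edge       20G-edge           38 0.2832912            0.3
```

The last table answers the practical question "how hard can you flush?":
for a 20G catheter lying against the vessel wall, the surrogate model
crosses the 38 Pa endothelial-injury threshold at only 0.3 mL/s — an order
of magnitude below a typical manual flush.

The full desk-scale sweep (control + rate ladder + angle ladder, a few
minutes on one CPU):

```r
res <- run_study(study_config("ci"), progress = TRUE)
print(res)      # stasis-by-rate table and normalized WSS per run
report(res, "pivcflow-out")   # CSVs, manifest.json, figures, VTK fields
```

Across the sweep, normalized WSS rises with infusion rate, stasis volumes
fall with rate, and residence times fall with insertion angle — the
directions the test suite asserts. A thin CLI over the same functions is
installed at `inst/scripts/pivc-study.R` (verbs `run`, `stats`,
`surrogate`, `synth`).

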