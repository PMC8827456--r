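# thrombosim

Three-dimensional multiscale simulation of platelet deposition and thrombus
growth under flow, at single-platelet resolution, for researchers studying
thrombosis in microfluidic assays and idealized vessel geometries
(channel, cylindrical vessel, stenosis).

The package couples four models on one cubic lattice:

* **Flow** — steady incompressible Newtonian flow over walls plus the
  instantaneous bound-platelet mass, solved by a D3Q19 BGK lattice
  Boltzmann scheme (half-way bounce-back; prescribed inlet wall shear rate
  or fixed total pressure drop).
* **Platelets** — a rejection-free lattice kinetic Monte Carlo engine:
  single-voxel platelets with hard exclusion, motion rates
  `max(v·e, 0)/h + D/h²` per lattice direction, Poisson inlet injection
  with a marginated (near-wall-enriched) concentration profile, and
  attachment/detachment events.
* **Adhesion kinetics** — closed-form rate laws combining Hill-normalized
  integrin activation `F(ξ)`, the shear-dependent VWF capture enhancement

      E(γ) = 1 (γ ≤ 3000 s⁻¹);  1 + 19(γ−3000)/5000 (3000 < γ ≤ 8000);  20 (γ > 8000)

  and the Bell-type breakage function

      G(γ) = exp(γ/γc) (γ ≤ 1000 s⁻¹);  exp(1000/γc)·exp(γ/γc′) (γ > 1000),

  e.g. collagen attachment `k_att·F(ξ)·F(ξΔt)·E(γ)` and collagen detachment
  `k_det·F⁻¹·F⁻¹·E⁻¹·G`.
* **Signaling** — per-platelet calcium traces from a pluggable calcium
  model (a phenomenological receptor-occupancy model ships as default;
  any fixed-step model honoring the interface can replace it), integrated
  into the cumulative and recent-history activation states
  `ξ = ∫(Ca−Ca₀)dt` and `ξΔt`, with latched dense-granule release of ADP
  and TXA2 above `ξ_crit`.
* **Agonist transport** — finite-volume convection–diffusion–reaction for
  ADP and TXA2 with exponential per-platelet release sources
  `R = (M/τ)·exp((t_rel − t)/τ)`.
* **Coagulation** — an 8-ODE reduced cascade in a well-mixed 15 µm
  thin film over the tissue-factor-bearing patch (extrinsic/intrinsic
  tenase, prothrombinase, FXIa feedback, fibrin generation,
  thrombin–fibrin sequestration; Michaelis–Menten with effectiveness
  factors, 2 s elution half-life). Film thrombin feeds platelet signaling
  inside the film only.

Scenario presets reproduce the study conditions at desk scale: a perfusion
channel at 200 s⁻¹ over a collagen+TF patch, a 60 µm vessel at 100 s⁻¹
with a semicylindrical injury, and 37/50/63/75 % stenoses driven by the
pressure drop giving an initial inlet wall shear of 1000 s⁻¹, with
antiplatelet treatment arms (aspirin/COX-1 → no TXA2, MRS-2179 → no ADP,
iloprost → IP-receptor shutdown) and a VWF-ablation switch.

## Worked example

Validate the flow solver against Poiseuille flow, then run the scaled
channel scenario:

```r
library(thrombosim)

dom <- build_tube(100, 60, 0.5, 50, h = 2.5, tf_on = FALSE)
ff  <- solve_flow(dom, NULL, flow_params(bc_kind = "constant_shear_inlet",
                                         inlet_wall_shear = 1000))
ff$Q
#> [1] 1.2725        # uL/min; analytic pi*gamma*R^3/4 = 1.2723

res <- run_simulation(scenario_presets("channel_200", seed = 1))
res
#> <thrombosim_result>
#>   geometry  : channel, treatment control, seed 1
#>   simulated : 150.0 s (300 macro steps)
#>   deposited : 1521 bound platelets (final)
#>   flow      : Q0 = 0.392, final Q = 0.392 uL/min
```

The constant-flow boundary condition keeps Q fixed while the aggregate
grows to ~26 µm; without the tissue-factor coating (`treatment = "no_TF"`)
deposition drops to 1111 platelets over the same interval.

`res$metrics` holds the platelet count, flow rate and film thrombin time
series; `res$clot_height` the mean aggregate height along the flow
direction (the clot crest sits upstream of the patch midpoint — venous
growth favors the upstream edge); `res$snapshot_final` the per-platelet
positions and activation states ξ, for activation-colored rendering via
`write_vtk_fields()` / `write_platelets_csv()`.

A stenosis under fixed pressure drop runs to occlusion (flow below 5 % of
its initial value):

```r
sten <- run_simulation(scenario_presets("stenosis_75", seed = 1, t_end = 300))
occlusion_time(sten)
#> [1] 169.2       # seconds; with wall TF the same vessel occludes at 135.1 s
```

A command-line front end for the presets is installed at
`inst/cli/thrombosim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/thrombosim.R", package="thrombosim"))')" \
    stenosis_75 --seed 1 --t-end 300 --out out/
```

## Vignette

`vignettes/thrombosim-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and default, the
calibration rationale for the constants that are configuration-owned, the
numerical schemes and their accuracy oracles, and the desk-scaling of the
shipped presets.
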