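---
title: "Multiscale thrombus growth under flow: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale thrombus growth under flow: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thrombosim)
```

## The problem

Platelet-rich thrombi grow on injured vessel walls under flow. The process
couples four very different physics: hemodynamics over an evolving obstacle,
transport of the soluble agonists that platelets release (ADP, thromboxane
A2), intracellular signaling that converts agonist exposure into calcium
mobilization and integrin activation, and stochastic single-platelet motion
and bonding. `thrombosim` simulates this system in 3D at single-platelet
resolution, in three vessel idealizations: a rectangular perfusion channel
with a collagen/tissue-factor patch on its floor, a straight cylindrical
vessel with a semicylindrical injury, and a stenosed vessel where a
pathological high-shear throat drives von Willebrand factor (VWF) mediated
capture.

## Model components

### Flow

Blood is treated as an incompressible Newtonian fluid (density 1060 kg/m3,
viscosity 3.5 mPa s by default; both are configurable). The steady velocity
field over walls plus all currently bound platelets is solved with a D3Q19
BGK lattice Boltzmann scheme with half-way bounce-back. Two boundary modes
are supported: a prescribed inlet wall shear rate (the perfusion-pump
condition; the inlet carries the fully developed analytic profile scaled to
the requested floor/wall shear) and a fixed total pressure drop (the
physiological condition under which occlusion is possible; inlet and outlet
planes are held at fixed density).

Because all simulated regimes are viscous (Re of order 1 or less), the solver
exploits Stokes linearity: it runs at a fixed small lattice Mach number
(velocity amplitude 0.002 in lattice units) and rescales the converged field
linearly to the requested physical driving. This keeps the compressibility
error in the flow rate below about half a percent regardless of the physical
shear rate. The relaxation time is fixed at tau = 1, which places the
bounce-back wall accurately at the half-way plane.

The solver is validated against closed forms rather than trusted as a
scheme: Poiseuille tube flow (flow rate and the linear shear profile
gamma(r) = gamma_w r/R), the rectangular-duct series solution (interior
profile to 2%, floor-midline wall shear to 5%), and mass conservation across
stations. At an inlet wall shear of 1000 1/s in a 60 um tube the computed
flow rate is 1.27 uL/min.

Wall shear at a stenotic throat is reported as the median of the shear
magnitude over wall-adjacent voxels of the stations around the minimum
lumen. The median is used deliberately: voxelizing a curved wall makes
individual near-wall gradients scatter both ways (oblique stencils
under-read, staircase corners over-read), so the extremes are artifacts
while the ring median is stable under refinement.

### Platelet motion and bonding (lattice KMC)

Platelets are single lattice voxels (default spacing h = 2.5 um at full
scale, one voxel per platelet, hard exclusion). A rejection-free
(direct) kinetic Monte Carlo engine advances the population: each mobile
platelet has six directional motion rates combining the upwind projection of
the local fluid velocity, max(v . e, 0)/h, with an isotropic diffusive rate
D/h^2. The platelet diffusivity (default 10 um2/s) stands in for the
red-blood-cell-enhanced dispersion of platelets near walls; red cells are
not resolved. Near-wall platelet enrichment (margination) is imposed at the
inlet: arrivals are Poisson with intensity proportional to the local axial
velocity times a concentration profile that is `factor` (default 3) times
the mean within `delta` (default ~5 um) of the wall, with the core depleted
so the flux-weighted mean matches the bulk platelet concentration.

Attachment events bind a mobile platelet to an adjacent reactive (collagen)
wall face and/or to every face-adjacent bound platelet; detachment releases
all bonds at once. The per-bond closed-form rates follow the
activation-and-shear laws below; a multi-bond platelet detaches at the
series (harmonic) combination of its per-bond rates, which reduces exactly
to the closed form for a single bond and slows detachment as bonds
accumulate. Bound platelets left without any bond after a neighbour
detaches are released (local cascade); no global connectivity analysis or
clot remodeling is performed, since realistic 3D trajectories already
suppress the dendritic artifacts that plague 2D lattice models.

The engine is validated against free-diffusion (MSD = 6Dt to 3%), pure drift
(displacement = vt to 2%), direct-KMC selection frequencies and exponential
waiting times, and an exact audit of the incrementally maintained event
table against a full rebuild.

### Adhesion kinetics

Integrin activation enters through the Hill-normalized activation factors
F(xi) and F(xi_dt) (below). Shear enters twice:

* capture enhancement E(gamma): 1 up to 3000 1/s, linear to 20 at 8000 1/s,
  and 20 beyond. This represents the recruitment of VWF-mediated bonds as
  the polymer unfolds at pathological shear. It can be disabled
  (`vwf_enhancement_on = FALSE`) for ablation studies.
* bond breakage G(gamma): a Bell-type exponential,
  exp(gamma/gamma_c) up to 1000 1/s and
  exp(1000/gamma_c) exp(gamma/gamma_c') beyond. The printed two-branch form
  is discontinuous at the breakpoint (it jumps by exp(1000/gamma_c')); the
  package implements it as printed by default and offers a
  continuity-corrected variant (`G_continuous_variant = TRUE`) in which the
  second branch uses exp((gamma - 1000)/gamma_c'), since the jump is most
  plausibly typographical. All tests of the printed branches pin the
  default.

The four rate laws are: collagen attachment
k_att_col F(xi) F(xi_dt) E(gamma); platelet-platelet attachment with the
geometric mean of both platelets' activation and enhancement factors;
collagen detachment k_det_col F^-1 F^-1 E^-1 G; platelet-platelet
detachment with the inverse square-rooted activation/enhancement product
times sqrt(G_i G_j). The shear "around" a platelet is the maximum shear
magnitude over its face-adjacent fluid voxels, because a deposited platelet
itself sits in a zero-velocity voxel.

The four rate constants and the two breakage scales are not published for
this model family; they are configuration parameters with defaults
calibrated once against the qualitative behavior of the channel system:
a resting platelet touching collagen is captured within its near-wall
residence time; resting platelet pairs do not aggregate in the bulk;
activated platelets bind orders of magnitude faster and essentially never
detach at venous shear; and at a 75% stenosis the balance between E and G
makes aggregates hold with VWF enhancement and shed without it
(defaults: k_att_col = 2e5, k_att_plt = 1e4, k_det_col = 2e-7,
k_det_plt = 2e-3 1/s; gamma_c = 1000, gamma_c' = 1700 1/s).

### Signaling

Each platelet carries a calcium trace sampled on the signaling step
(default 0.5 s). The cumulative activation state xi integrates calcium
above the 100 nM basal level (trapezoidal; sub-basal excursions are clipped
to zero so xi is monotone and the Hill map stays well defined); the
recent-history state xi_dt is the same integral over a trailing window
(default 30 s), maintained as a ring buffer. Both are mapped to integrin
activation through the Hill function F with basal and maximal levels
alpha_min = 0.01 and alpha_max = 1, exponent n = 2 and half-activation
theta_50 = 15000 nM s. When xi exceeds xi_crit = 15000 nM s the platelet
(once, latched) begins exponential dense-granule release of ADP and TXA2,
and keeps releasing if it detaches and moves (moving sources).

The calcium model itself is pluggable: any object honoring the
fixed-step contract (exposure record in, nM out; basal fixed point at
100 nM; deterministic) can stand in for a patient-trained model. The
shipped default is a phenomenological receptor-occupancy model: each
agonist drives a first-order receptor state with agonist-specific on/off
kinetics (thrombin fast-on/slow-off; collagen slow and sustained; ADP and
TXA2 faster off and desensitizing), and calcium relaxes toward a saturating
function of the summed drive. Iloprost (IP receptor) and GSNO enter as an
inhibition factor that saturates exactly at 1, shutting calcium down to
basal. Drug treatments reproduce the in-silico mimicry of the antiplatelet
agents: COX-1 inhibition (aspirin/indomethacin) zeroes TXA2 in the signaling
inputs, MRS-2179 zeroes ADP, iloprost saturates the IP drive. The agonist
weights are calibrated so ADP is the more potent soluble agonist (its
removal costs a double-digit percentage of deposition in the scaled channel
at 150 s, the largest soluble-agonist effect, as expected for P2Y
signaling), TXA2
the least potent, and collagen/thrombin dominant - producing the core/shell
activation architecture in which platelets exposed to collagen and film
thrombin reach strictly higher xi than platelets recruited by soluble
agonists alone.

The signaling time step (0.5 s) also clocks transport and coagulation;
signaling-relevant defaults (theta_50, xi_crit, the receptor kinetics) were
chosen once so that a platelet adhering to collagen at time zero crosses
xi_crit after roughly a minute, matching the observed lag before
dense-granule release, and were not revisited afterwards.

### Agonist transport

ADP and TXA2 fields obey convection-diffusion-reaction equations on the
flow lattice (diffusivities 240 and 210 um2/s), with per-platelet
exponential release sources (M_ADP = 2.4e-17 mol and M_TXA2 = 6e-18 mol
per platelet over time constants 5 and 10 s; EC50s of 500 and 50 nM are
used to report concentrations in the receptor-relevant scale). Released
amounts and EC50s are configuration-owned; the defaults put the near-wall
boundary layer in the fraction-to-several-EC50 range at venous shear, which
is the regime in which released agonists can recruit the near-wall platelet
shell. Walls and platelet surfaces are zero-flux; the inlet admits
agonist-free blood; the outlet is zero-gradient outflow. The clot interior
is treated as no-flow voxels that still exchange species by diffusion.

Discretization is finite-volume with first-order upwind convection and
central diffusion, advanced explicitly with sub-stepping to the stability
bound. When the stability bound would demand more than
`max_explicit_substeps` (default 120) sub-steps per macro step - which
happens in stenotic flows where velocities reach tens of mm/s - the same
upwind flux discretization is advanced instead by a dimensionally split
backward-Euler step (one tridiagonal solve per lattice line and direction).
The split-implicit step is unconditionally stable, conservative in flux
form, and nonnegativity-preserving (each 1D operator is an M-matrix), at
the cost of first-order temporal smearing; the explicit path remains the
reference for the transport oracles (point-source Green's function to 5%,
global mass balance to 0.5% per step).

### Thin-film coagulation

Wall tissue factor initiates the extrinsic cascade inside a thin
fibrin-rich film, 15 um measured normal to the TF-bearing patch, assumed
present from the start of the run and spatially well mixed. The reduced
cascade is 8 ODEs over the six lumped activities: extrinsic tenase/FIXase
(TF:VIIa activating FX and FIX, plus FXIa-driven FIX activation), intrinsic
tenase (FIXa activating FX), prothrombinase (FXa converting prothrombin),
thrombin feedback activation of FXI, fibrin generation, and reversible
thrombin-fibrin binding (sequestration). All reactions are Michaelis-Menten
with an effectiveness factor in (0, 1] per reaction representing transport
limitation. Soluble enzymes elute with a 2 s half-life; the tracked
zymogens (prothrombin, fibrinogen) are replenished toward plasma levels at
the same exchange rate, and fibrin and fibrin-bound thrombin stay in the
film.

The exact equation set and constants of the original reduced model are not
published in the text this package works from, so the network topology and
integration contract are fixed while every rate constant ships as a
literature-guided configuration default. The defaults were chosen once so
that the linearized amplification loop (thrombin -> FXIa -> FIXa -> FXa ->
thrombin) is mildly supercritical against the 2 s elution: free thrombin
then shows the expected sigmoid rise, reaching 10% of its maximum no
earlier than ~60 s and saturating as prothrombin depletion pulls the loop
gain back to critical. Film thrombin feeds the signaling of platelets
inside the film mask only; thrombin is not monitored outside the film.
Integration uses lsoda each macro step. The oracles are structural: zero
TF means identically zero thrombin and fibrin; with all production switched
off, elution halves free thrombin every 2 s exactly; fibrin is
nondecreasing; enabling fibrin binding strictly lowers eluted free-thrombin
exposure.

## Coupling and schedule

Each macro step (0.5 s): (1) inlet injection; (2) KMC events at frozen
flow, shear and activation until the step elapses; (3) calcium and
activation updates from agonists sampled at each platelet's voxel plus film
thrombin; (4) transport with the current release sources; (5) coagulation;
(6) a quasi-steady flow re-solve when the bound voxel set changed by at
least `flow_resolve_voxels` (30 in the desk-scale presets, 60 in the
stenosis presets where deposition is faster) or a maximum interval elapsed.
Re-solves warm-start from the previous field and use a slightly looser
stopping rule with a sweep cap, since each update is a small local
perturbation of an already converged field; the quasi-steady treatment is
appropriate at these Reynolds and Womersley numbers. Under the fixed
pressure drop the run terminates when the inlet flow rate falls strictly
below 5% of its initial value (occlusion).

Determinism: all stochastic draws (injection, KMC selection and waiting
times) use R's RNG, so a fixed seed replays a run bit-identically.

## Scaled study conditions

The shipped presets are desk-scaled so a complete run takes minutes on one
CPU core: lattice spacing h = 5 um, a 250 x 80 x 60 um channel with a
100 um collagen+TF floor patch at 200 1/s inlet wall shear (150 s), a
300 x 60 um tube with a semicylindrical patch at 100 1/s (180 s), and
400 um stenosed tubes (60 um inlet diameter, 200 um cosine-bump narrowing,
collagen over half the circumference of the stenotic segment) at a fixed
pressure drop calibrated to an initial inlet wall shear of 1000 1/s
(300 s). The mean inlet platelet concentration in the scaled presets is
3e4 platelets/uL - about a tenth of physiological - so that the platelet
flux matches what the coarsened lattice can resolve; `full_scale = TRUE`
switches to the full experimental dimensions (500 um domains, h = 2.5 um,
400-500 s, 1.5e5 platelets/uL) at roughly two orders of magnitude more
compute. The stenosis profile is a cosine bump (smooth, symmetric), the
least-assumption choice given that only the percent area reduction is
specified; both the profile and the axial extent of the collagen coating
are configuration-exposed.

What the scaled runs do and do not show: they reproduce the mechanistic
orderings (TF amplifies deposition; iloprost < no-ADP < no-TXA2 < control;
upstream-biased venous growth; throat-localized, VWF-dependent growth and
occlusion under pressure drop) and are tested for exactly those orderings.
Absolute counts, heights and occlusion times at desk scale are not
calibrated to the experimental numbers, which would require the full-scale
conditions and the original patient-trained signaling model.

## Degenerate inputs and edge cases

A fully occluded domain is handled, not an error: under a velocity inlet
the solver returns a zero field (there is no admissible steady state), and
under a pressure drop the flow rate simply tends to zero. A zero-length
patch gives pure perfusion. Zero film thickness gives an empty film. A
zero-duration schedule returns empty series. Exactly 5% of the initial
flow rate is not occlusion (the criterion is strict). Platelets that exit
the outlet are removed and accounted for; the bookkeeping identity
injected = bound + mobile + exited is asserted every macro step in the
tests.

## Known limitations

* Flow is quasi-steady between clot updates; pulsatility and
  fluid-structure interaction are out of scope.
* Platelets are rigid single voxels; no shape, orientation, or multi-voxel
  deformation, and no explicit red blood cells (their effect enters through
  the enhanced diffusivity and the margination profile).
* The shipped calcium model is a phenomenological stand-in with the right
  qualitative structure (basal stability, agonist-specific kinetics,
  saturating inhibition), not a patient-trained response surface.
* The coagulation constants are literature-guided defaults for an
  unpublished equation set; the network topology, conservation structure
  and elution physics are fixed, the numbers are configuration.
* Thrombin exists only in the film ODE; it is not transported.
* Detachment releases all bonds at once with a series-combined rate; bonds
  have no memory of their formation shear.
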