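---
title: "Methods: flashing-light and mixing metrics for tubular photobioreactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flashing-light and mixing metrics for tubular photobioreactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microalgae grow best when cells shuttle rapidly between the well-lit rim
of a culture vessel and its dark interior — the *flashing-light effect* —
instead of sitting in either zone. In a tubular airlift photobioreactor
(PBR) this shuttling is driven entirely by the secondary flow that
aeration induces in the tube cross-section, so the design question is
geometric and hydrodynamic: where should the aeration tube sit, in which
direction should its pores blow, and at what rate?

`pbrflash` provides the evaluation layer for that question. It models the
2-D cross-section of three reactor layouts, generates (or ingests)
gridded cross-sectional flow and turbulence fields, tracks neutrally
buoyant algal-cell surrogates through them, and reduces the trajectories
and fields to the four decision metrics used to rank designs:

* light/dark cycle frequency `f = 1/T`, where a cycle `T` is the time to
  cross the light/dark interface twice;
* light-time ratio `phi`, the fraction of time spent in the light zone;
* the field-synergy statistic `|cos(alpha)|`, the mean alignment between
  the liquid velocity and the light propagation direction;
* mean turbulent kinetic energy (TKE) and the dead-zone fraction.

## Geometry

All layouts share one coordinate frame: a *depth axis* pointing up toward
the illuminated top of the outer tube and a *lateral axis*, origin on the
outer-tube axis, lengths in mm. Light enters from the top at normal
incidence and travels straight down the depth axis. The light/dark
interface is the horizontal line through the axis (`boundary_depth = 0`),
configurable because the effective photic depth depends on biomass
density.

The *tangent* layout places an 80 mm inner aeration tube internally
tangent to the bottom of a 200 mm outer tube. A 60 degree arc is removed
from the bottom of the inner tube and the opening closed by a flat panel
so that cells cannot be trapped in the cusp between the two walls. We
model the removed arc plus panel as a single horizontal chord at the
depth of the arc end points (-94.64 mm for the defaults): everything
below the chord — panel gap and both cusp corners — is excluded from the
culture region. This is the simplest wall-attachable closure; no panel
coordinates beyond the arc width are specified for the design, and the
closure is toggleable (`fillet_enabled = FALSE`).

Area quantities are computed by uniform cell-centre counting at
`outer_radius / 500` spacing; the plain disc and concentric annulus agree
with their closed forms to better than 0.1%, and the tangent culture area
agrees with an independent Monte-Carlo membership oracle (1e7 samples) to
0.02%.

A note on the zone partition: under the stated rule — light zone = light
path shorter than 60 mm — the plain 200 mm tube has a light/dark area
ratio of 0.603 and the tangent layout 0.816. Published zone ratios for
these cross-sections (0.493 and 0.648) are not reproducible from any
single-direction light-path rule we tested; their exact light-path
definition (refraction, shadowing, bidirectional illumination) is
unstated. The package therefore implements the stated rule, and the
printed pair 0.493/0.648 enters only the improvement arithmetic
(`percent_change(0.493, 0.648) = 31.4%`), never the geometry.

## The synthetic flow generator

The two-phase hydrodynamics that produce the cross-sectional flow are out
of scope: the package's job is the metrics layer, which is testable only
with controlled fields. `default_scenario()` therefore builds a
parametric surrogate with the structural features of airlift
cross-sectional flow:

* **Streamfunction construction.** Velocities are derived from a scalar
  streamfunction by centred differencing, so the matching discrete
  divergence vanishes identically (round-off level) — cells never create
  or destroy fluid. Kernels are Gaussian-core (Lamb–Oseen-like) vortices
  and dipole jets; the streamfunction is multiplied by a smoothstep of
  wall distance (length scale 6 mm) so it is constant on walls, giving
  no-penetration.
* **Structure.** Two mirror-symmetric pore jets on the sides of the
  inner tube drive a counter-rotating vortex pair (core radius 14 mm) at
  the pore lateral offsets. For 30 degree downward jets the pair sits
  with its centres on the light/dark boundary — the configuration that
  pushes cells across the interface most effectively. As the jet
  direction rotates upward the pair is displaced into the light zone by
  `60 * sqrt(sin(direction + 30 deg))` mm, and the dark-side secondary
  circulation fades quadratically with that displacement, leaving the
  dark zone sparse and weakly stirred. Weaker secondary vortex pairs
  (0.45 x) above and below the main pair keep the whole section
  circulating, mirroring the stacked streamline pattern of real airlift
  cross-sections. The concentric layout gets a single canted jet, a
  primary vortex in the dark zone on the aerated side and a weak
  counter-vortex opposite — an asymmetric, dead-zone-heavy flow.
* **Calibration.** The composed field is rescaled so the peak |vertical
  velocity| sampled on the +-40 mm monitoring lines matches the target
  (defaults: 0.0393 / 0.045 / 0.049 m/s at 0.3 / 0.7 / 1.0 vvm for the
  tangent layout at -30 degrees; 0.047 m/s for the concentric layout),
  and the turbulence field is rescaled so the culture-mean TKE matches
  its target (60 / 80 / 76.8 cm^2/s^2; 54 for concentric). Both are
  exact linear rescalings, so they hold by construction. The 0.7 vvm TKE
  anchor is the tabulated reference value; the 1.0 vvm anchor encodes
  the reported 4% TKE decrease past the optimum; the 0.3 vvm anchor is
  unreported and was fixed once at 60 cm^2/s^2 as a plausible
  sub-optimal value.
* **Direction efficiency.** The calibration anchors describe the optimal
  -30 degree configuration. Other directions stir the reactor less
  effectively, so both targets are scaled by an efficiency factor
  falling from 1.0 at -30 degrees to 0.35 at +60 degrees. This factor is
  the construction that fixes the qualitative direction ordering (every
  mixing metric improves as aeration rotates clockwise from +60 to -30);
  its magnitude was chosen so the ordering is resolvable by replicated
  20-particle tracking runs, and was verified stable across ten disjoint
  16-replicate seed sets.
* **Turbulence structure.** TKE is a sum of Gaussian blobs centred on
  the vortex cores and (displaced 30 mm along the jet, as a plume
  carries its energy) on the pore sites, width twice the kernel core,
  plus a 5% background so the dissipation rate is positive everywhere.
  Dissipation follows the mixing-length closure
  `eps = C_mu^(3/4) k^(3/2) / L` with `L = 4 mm`, the usual 7% of the
  60 mm annular gap.

Pore count, diameter and spacing are not constrained by the design
description; the defaults (4 pores of 5 mm per row, one row per side,
every 250 mm of a 1 m tube) are configurable, and the aeration rate in
vvm converts to a pore jet speed through the culture volume. A single
momentum-transfer coefficient (0.05) links gas jet speed to the liquid
driving speed; the calibration to the printed velocity peaks is the
authoritative scaling, so this coefficient only sets relative component
strengths.

What the generator does *not* emulate: bubble dynamics, gas holdup,
axial (3-D) flow development, vortex meander and intermittency, and the
absolute magnitudes of trajectory-level statistics. Calibrated field
quantities (velocity peaks, mean TKE) are comparable to reference
values by construction; trajectory statistics (f, phi) are meaningful
as *orderings and contrasts* between scenarios, not as absolute
reproductions of 3-D CFD values.

## Particle model

Algal cells are represented by 20 neutrally buoyant spheres (diameter
10 um, density 1000 kg/m^3) tracked for 60 s with positions recorded
every 0.1 s. Two forces act per unit particle mass:

* quadratic drag `(3 C_D rho_f) / (4 d rho_p) |u_f - v| (u_f - v)` with
  the Newton-regime constant `C_D = 0.44`;
* the pressure-gradient force `(rho_f / rho_p) Du/Dt`, the standard
  per-mass form of the local fluid material acceleration.

Gravity and buoyancy cancel at equal densities and are omitted. The
fluid velocity seen by a particle is the bilinear-interpolated mean flow
plus a discrete-random-walk (DRW) fluctuation: each component Gaussian
with variance `2k/3`, held for an eddy lifetime `tau_e = 2 T_L`,
`T_L = 0.15 k / eps` — the conventional DRW constants.

Numerics: classical RK4 with an outer step of 0.01 s. Quadratic drag of
10 um particles is stiff (linearised rate `2 C |slip|` reaches ~5e3 1/s
right after an eddy resample), so each outer step is subdivided by a
deterministic stability rule (`h <= 0.3 / rate`); runs under a fixed
seed are bit-reproducible. Inside the tracker the material acceleration
is the gradient of the same bilinear velocity patch the particle is
advected by, which makes "velocity = fluid velocity" an exact solution
in the tracer limit; the exported `fluid_accel()` uses the smoother
centred-difference gradients, and the two agree to the grid order.
Walls reflect particles specularly (speed-conserving); the wall model is
not specified by the design description. Release positions are uniform
over the culture region under the run seed, and initial particle
velocity equals the local mean flow.

Two numerical caveats, verified empirically and reflected in how the
invariants are tested: (i) with purely quadratic drag, near-zero slip is
essentially undamped, so orbital *phase* perturbations accumulate and
endpoint-in-time comparisons against a pure-advection oracle diverge in
any recirculating field — the tracer limit is therefore checked
geometrically (distance from the streamline curve, < 1% of the outer
radius over 60 s on an axisymmetric vortex); (ii) bilinear interpolation
makes the acceleration discontinuous across cell edges, so strict
step-halving endpoint convergence is asserted on the smooth solid-body
field.

## Cycle statistics

Interface crossings are located by sign change of the depth coordinate
about the boundary, linearly interpolated between samples; refining a
trajectory by linear interpolation leaves the crossing count unchanged.
For each particle with at least one complete cycle (three crossings) the
period `T` is the mean spacing between alternate crossings; the
population `T` averages these and `f = 1/T`. The light-time ratio is
computed per particle as its full-trajectory light-zone residence
fraction and averaged over all particles that cross at least once: a
cell that dips into the dark zone and settles there counts, with its
long dark residence, which is exactly the behaviour that distinguishes
poorly aerated designs. Particles that never cross are excluded from all
statistics and reported as `n_noncrossing`. A pooled-time variant of
`phi` is available (`phi_method = "pooled"`).

Stagnant cells (speed below 1e-9 m/s) are excluded from `|cos(alpha)|`
means — coercing them to zero would bias aligned and stagnant flow alike
— and their fraction is reported.

## Problem sizes and replication

Default grids use 2 mm spacing (about 100 cells across the outer
diameter); area integrations use 0.2 mm. The direction-sweep analyses
replicate the 20-particle/60 s tracking protocol over 16 seeds and
average, because single runs of the dispersion model carry 20-30%
noise in `f` while adjacent aeration directions differ by 10-20%; the
replicate count was sized so the constructed ordering resolves reliably.
The acceptance script uses 8 replicates for single-scenario metrics and
16 for the sweep.

## Limitations

* The flow surrogate is structural, not dynamical: it cannot predict how
  an untested geometry would perform, only evaluate fields supplied to
  it or constructed from its calibrated building blocks.
* Absolute `f` and `phi` from the surrogate are roughly an order of
  magnitude below values reported from 3-D two-phase CFD trajectories;
  cross-scenario orderings are the meaningful output.
* The DRW model omits the near-wall drift correction, so inhomogeneous
  turbulence produces mild spurious accumulation in low-TKE regions;
  the broad turbulence blobs used by the generator keep this small.
* Light is a straight vertical ray with a sharp interface; no radiative
  transfer, scattering or photosynthesis kinetics.
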