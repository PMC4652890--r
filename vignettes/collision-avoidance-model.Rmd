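---
title: "An optic-flow collision avoidance model: assumptions, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An optic-flow collision avoidance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(comanv)
```

This vignette explains the model the package implements, the choices behind
its tunable parameters, and what the bundled tests do and do not establish.
Everything quantitative stated here is computed by the test suite or the
acceptance script; nothing is quoted from elsewhere.

## The model

An insect-like agent flies at constant speed `v = 0.1 m/s` in a fixed
horizontal plane, alternating **intersaccades** (50 ms translations, heading
fixed) with **saccades** (fast yaw turns following a Gaussian yaw-velocity
profile). During an intersaccade the per-tick translation direction is drawn
from a normal distribution around the heading (SD 18 deg), a mixture of
forward and sideways motion.

The eye is spherical, sampled on a cylindrical-projection grid of 91
elevation rows x 181 azimuth columns at 2 deg spacing. For translation in
the horizontal plane, the optic-flow components in viewing direction
(elevation eps, azimuth phi relative to the motion direction) are

```
OF_phi = v * mu * sin(phi),      OF_eps = v * mu * sin(eps) * cos(phi),
```

with `mu` the inverse distance. Their retinotopically modified norm

```
(v mu)^2 = OF_phi^2 + OF_eps^2 / sin(eps)^2
```

recovers relative nearness `v*mu` independent of the viewing angle. Exactly
at the flow singularities (focus of expansion/contraction) both components
vanish; because the intersaccade mixes motion directions, squaring the flow
per tick and averaging over the window fills in those directions. The
recovered map is averaged along elevation into a 180-bin azimuthal nearness
profile; its vector sum over azimuth is the center-of-mass average nearness
vector (COMANV). The collision avoidance direction (CAD) is the direction
opposite the COMANV, the collision avoidance necessity (CAN) its norm, and
the next saccade amplitude is

```
gamma = W * CAD + (1 - W) * (alpha + sigma),   W = 1 / (1 + (CAN/n0)^-g),
```

with `alpha` the bearing to a goal (0 without one) and `sigma` optional
goal-direction noise (default off). The COMANV is the plain vector *sum*
over the 2-degree bins: on that scale the geometric-flow CAN in the 0.4 m
arena crosses the working thresholds (`n0` of 1.6-4, units 1/s) at 14-17 cm
from a wall, which is what makes those thresholds meaningful operating
points; a bin-mean normalization would cap CAN near 0.2 in the same
conditions and the sigmoid would never engage.

Two flow sources feed the same control law:

* **geometric** -- exact flow computed from ground-truth nearness (the
  benchmark); nearness is re-cast once per phase, since the agent moves
  only ~5 mm within one;
* **emd** -- correlation-type elementary motion detectors on rendered
  images: a photoreceptor low-pass (default first-order, tau = 8 ms, unity
  DC; the measured insect photoreceptor kernel is not public, and any DC
  error is removed by the next stage, so only its band edge matters — the
  kernel is pluggable), a 20 ms high-pass, and opponent correlators with a
  35 ms delay low-pass between azimuth- and elevation-adjacent receptors.
  Correlator responses are squared and averaged over the last 5 ms of the
  intersaccade only, because the filters carry the previous saccade's
  rotational flow into the early intersaccade. Filters run on every 1 ms
  tick, including during saccades: that contamination is part of the model.
  At trial start the photoreceptor and DC-tracking states are initialized
  at their fixed point for the initial view (the agent takes off from
  rest), so the first decision is not driven by a filter turn-on transient.

## Rendering

Arenas are axis-aligned textured boxes (walls, floor, ceiling, vertical
square-base obstacles). Receptors average `n_subrays` (default 13) ray
casts over a Gaussian stencil (sigma = 2 deg, truncated at 2 sigma).
Each surface hit looks up the texture through a summed-area table over a
footprint proportional to hit distance (and elongated at grazing
incidence): sub-resolution texture genuinely washes out with distance, as
it does optically. A plain nearest-texel lookup is available
(`compile_scene(env, footprint_deg = 0)`) but makes checkerboard contrast
distance-independent — an aliasing artifact that lets the motion detectors
"see" arbitrarily distant 1 mm texture and, in cluttered scenes, swamps
the nearness profile. Brightness is quantized to 8 bits (the precision of
the package's PNG texture round-trip).

## EMD nearness units and the estimator

Correlator output units are arbitrary; the control thresholds are stated on
the geometric 1/s scale. The package therefore calibrates once, with
`emd_calibration()`: correlators respond predominantly to the contrast
contours of nearby objects, so the reference condition is a camouflaged
3 cm bar viewed from 0.1 m clearance (1 mm checks, large box so the walls
stay symmetric), and the calibration equates EMD and geometric CAN there.
The resulting constant is the package default and is a *unit match*, not a
behavioral tuning.

Two estimator details differ deliberately from the idealized formula:

* the `1/sin(eps)^2` correction of the vertical component is clamped below
  20 deg elevation for EMD sources (`correction_floor_deg`). The correction
  is exact for true flow, but near the equator it amplifies correlator
  noise and the aperture-leakage of horizontal contrast edges by up to
  three orders of magnitude; measured in the cluttered corridor, the
  unclamped estimator's profile is dominated by that band.
* the elevation average of EMD maps is inverse-variance weighted by
  default (`weighting = "sin2"`; the amplified noise variance scales as
  `1/sin(eps)^2`), which suppresses the same near-equator band further.
  This is the only configuration whose free-space necessity in cluttered
  scenes lands at the scale of the printed thresholds; its cost is that the
  wall-texture signal of the plain arena, which lives in the same
  low-elevation rows, is attenuated beyond ~7 cm, so EMD steering
  agreement with the geometric benchmark narrows to the near-wall range.
  The plain mean of the idealized formulation remains available
  (`weighting = "uniform"`).

The equator row itself (where the identity is singular) is interpolated
from its two neighbours (configurable to exclusion); the pole rows are
excluded from the average.

## Simulation parameters

| parameter | default | units | why |
|---|---|---|---|
| speed | 0.1 | m/s | reference flight speed of the modelled experiments |
| dt | 1 | ms | sensor and control tick (1 kHz) |
| intersaccade | 50 | ms | fixed translation phase, 50 jittered segments |
| segment SD | 18 | deg | motion-direction mixture that removes the FOE/FOC |
| EMD window | 5 | ms | accumulation limited to the segment least affected by the previous saccade |
| gain g | 2 | - | sigmoid steepness of the avoidance weight |
| threshold n0 | 4 | 1/s | CAN at which avoidance and goal terms balance |
| collision radius | 0.01 | m | crash when any surface is closer (strict) |
| goal radius | 0.05 | m | arrival criterion |
| saccade template | max(10, 30 + 20\|gamma\|/90) | ms | duration spanning the insect range; Gaussian yaw bell (sigma = D/6) renormalized so the turn integrates exactly to gamma; translation continues during the turn |

A zero-amplitude saccade is a minimal 10 ms straight segment, so the
phase alternation is preserved even when no turn is commanded.

## Environments

The generator reproduces the study conditions: a 0.4 m cubic arena with
random checkerboard walls (1/4/8/35 mm texels, or a 1/f field standing in
for natural texture); object arenas with 1, 2 or 4 camouflaged 3 cm bars at
the centre/diagonal positions (25% of the edge from the centre); and
2000 x 1000 x 400 mm cluttered corridors with 35 obstacles drawn from the
published size roster (heights five times the base edge), placed uniformly
in the box shrunk by 10% per side under a 60 mm minimum footprint
clearance — a stand-in for the unpublished "homogeneity" selection of the
original layouts. Floors and ceilings of the plain arena default to 8 mm
checks at half contrast (dark floor, light ceiling). Textures and layouts
are pure functions of their seeds; environment recipes round-trip through
a YAML config.

Start-position sets are even lattices over the arena interior (or a strip
at the low-x end for corridor crossings), filtered for 5 cm clearance; the
published start coordinates are not available, so these are the package's
own canonical grids.

## Route analysis

Obstacle centres are Delaunay-triangulated (direct empty-circumcircle
construction with lexicographic tie-breaking — exact for tens of nodes and
free of the super-triangle artifacts of incremental schemes at near-
collinear hulls). A trajectory maps to the sequence of cells crossed
(outside-hull samples emit a reserved token rather than being dropped, so
wall-hugging detours still differentiate routes); repeated visits are
removed by suppressing subsequences between the first and last occurrence
of a recurring cell, iterated to convergence. Identical simplified
sequences form a route; route distance is the number of cells not shared;
dendrograms use average linkage (the linkage is not dictated by the
method, and average linkage is the least-assumptive default for a
set-difference metric).

Reliability is the percentage of trajectories that crash before reaching
the goal. Path efficiency of a goal-reaching trajectory is the length of
the shortest collision-free path (visibility graph over obstacle corners
inflated by the collision radius) divided by the realized path length. A
maximal-clearance baseline path (the discrete analogue of a
Voronoi-skeleton route, computed on an occupancy grid by bottleneck
search) is available for comparison.

## Numerical choices

* Temporal filters use exact exponential (zero-order-hold) updates, so time
  constants are dt-independent.
* The azimuth grid duplicates the +/-180 deg column for regularity; the
  duplicate is dropped from azimuthal sums and horizontal correlators wrap.
* Correlator fields are re-gridded to receptor positions by the signed
  mean of the two flanking detectors.
* Ray casting uses a uniform ground-plane grid with mailboxing; collision
  distance is the exact point-to-surface distance.
* Saccade profiles renormalize the discrete Gaussian so the integrated turn
  equals the commanded amplitude to machine precision.

## Problem sizes in the checks

The bundled checks run at desk scale: closed-loop arena runs use 10 s
flights from 2-4 starts per condition; corridor crossings use 3 starts
(EMD source, 5 sub-rays) or 20 starts (geometric source); open-loop
comparisons sample a handful of positions after five settling
intersaccades. These sizes are the package's chosen defaults for its own
regression checks; larger replications only require changing `n_starts`
and `max_time_s`.

## What the tests show, and what they do not

The synthetic arenas reproduce the *structure* of the modelled experiments
(geometry, textures, object rosters) but not unpublished specifics: the
natural grass image, the exact obstacle layouts, start coordinates, the
measured photoreceptor kernel, or the saccade-template constants. Passing
tests therefore establish that the implementation realizes the model
faithfully and reproduces its qualitative regularities (nearness recovery,
threshold behavior, texture dependence, route convergence) — not that any
specific published trajectory or route count is reproduced; route counts
depend on the random layouts. Real-world validity of the model itself is
outside the package's scope.

## Known limitations

* Only planar self-motion is modelled; out-of-plane velocity components
  bias the recovered nearness (monotonically in the vertical speed), which
  the test suite demonstrates.
* The renderer supports axis-aligned textured rectangles only; no lighting,
  transparency, or curved geometry.
* EMD-derived nearness inherits the correlators' texture and
  temporal-frequency dependence; it is a distorted, monotone-near-range
  correlate of nearness, not a measurement.
* With coarse textures (35 mm checks) the motion-detector input is sparse
  and distorted enough that the closed loop fails near walls, as expected
  from the model's texture dependence.
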