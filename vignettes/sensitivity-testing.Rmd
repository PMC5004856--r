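---
title: "Sensitivity testing of larval-dispersal models with larvalsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity testing of larval-dispersal models with larvalsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalsens)
```

## The problem

Biophysical larval-dispersal models couple gridded ocean-model velocity
output with an offline particle tracker. Before such a model is used to
answer ecological questions, its *input parameters* need sensitivity
testing: release points placed too close together produce spatially
autocorrelated (redundant) trajectories, a too-long tracker timestep
skips velocity cells, too few spawning events under-sample the temporal
variability of the currents, and too few years of forcing data fail to
represent the longer-term mean. `larvalsens` implements a complete,
self-contained version of that testing process for a deep-sea setting:
releases around a flat-topped seamount (a guyot) at several fixed depth
horizons, with all five standard parameter sweeps and both analysis
engines, runnable end to end on a built-in synthetic ocean so that no
external hydrodynamic data are required.

The five tested parameters are:

* **TS** — tracker timestep (baseline 1 h; increments 3, 6, 12, 24 h),
* **HS** — horizontal separation of release points (increments +0.001,
  +0.005, +0.01, +0.025 degrees along the seamount contour),
* **VS** — vertical separation (increments −0.1, −1, −10, −50 m, at
  modified baseline depths 200, 1000, 1750 m chosen to sit in z-level
  bands of different vertical resolution),
* **RF** — release frequency (365/183/104/52/12/4 releases per year),
* **TR** — temporal range (1–4 year subsets of a 5-year baseline).

## The two statistics

**Distance Separation over Time (DST).** For TS, HS and VS, each
increment trajectory is compared with its baseline trajectory day by
day using the haversine great-circle distance (R = 6371 km). All
replicate pairs (release locations x release times) and all tracking
days are pooled into one distribution per (depth band, increment), and
its median is compared against an independence threshold (10 km by
default, a typical larval habitat-detection distance). A
shape-preserving piecewise cubic Hermite interpolant (MATLAB-style
`pchip`, via `pracma`) is drawn through the `(increment, median)`
knots, anchored at `(baseline, 0)` because a baseline is at zero
distance from itself, and the *optimal value* is the smallest increment
at which the curve first reaches the threshold (bisection to a relative
1e-6). If the curve never reaches the threshold inside the tested
range, the crossing of the linear continuation with the end Hermite
slope is reported and flagged `approx.` — the same convention as
sensitivity reports that extend the interpolant beyond the plotted
range.

**Fraction of Unexplained Variance (FUV).** For RF and TR, baselines
and increments contain different numbers of tracks, so trajectories are
rasterized into track-density grids at half the velocity-grid
resolution (0.04 degrees): each track is a polyline through its daily
positions, every cell the polyline *enters* counts that track once
(exact segment–grid intersection, so a long daily displacement cannot
skip cells; no track is counted twice per cell). For each replicate
release location, FUV = 1 − r² is computed between the increment and
baseline rasters, where r is the Pearson correlation over all cells
that are nonzero in at least one raster (joint-zero cells are excluded
because their number depends only on the arbitrary domain extent and
inflates r; this choice is stated because the literature is silent).
The 95th percentile of replicate FUVs per increment (linear
interpolation between order statistics, R quantile type 7) forms an
envelope; the optimal value is the smallest increment resolution at
which the envelope first drops to 0.05.

`fuv_to_correlation()` back-computes r = sqrt(1 − FUV), for reporting
what a sub-optimal setting costs in map correlation.

## The tracker

`run_release_set()` advects passive particles at fixed depth horizons
(no vertical motion — consistent with forcing data that omit vertical
velocity, whose deep-ocean background magnitude is negligible over a
100-day drift) using classical fourth-order Runge–Kutta in lon/lat
space with per-stage metric conversion (m per degree latitude =
pi R / 180; longitude scaled by cos lat). Horizontal interpolation is
bicubic (Catmull–Rom), falling back to bilinear wherever the 4x4
stencil touches the grid edge or a masked node, mirroring simulators
that switch to linear interpolation near land; depth and time are
linearly interpolated. The RK4 implementation converges at observed
order 4.0 on analytic flows (see the test suite).

Particle fates: a particle whose step leaves the grid is `escaped`; one
whose position ends over seafloor shallower than its depth (bilinear
topography, minus a 60 m near-bottom clearance tolerance) is `beached`.
Both freeze at the last valid position, and every track keeps
`pld + 1` daily records regardless of fate, so replicate designs stay
balanced. The clearance tolerance exists because release points sit at
the seamount interface: with a strict test, numerical wobble across the
boundary streamline would terminate a large fraction of particles at
release, which the underlying ocean models do not do (their near-bottom
cells remain navigable at the resolution of one grid cell).

Within the DST *pooling* of the bundled suite, pair-days after either
member of a pair froze are excluded: a frozen pair cannot separate
further, and counting its repeated frozen distance would turn the
median into a beaching-rate statistic rather than a spatial
autocorrelation statistic. The `dst_series()` operation itself still
exposes frozen positions as recorded, so either convention can be built
on top of it.

Release schedules snap to whole days. The driving fields are daily
averages and the output interval is daily, so sub-day release phases
carry no information; the printed per-year counts (365, 183, 104, 52,
12, 4) are preserved exactly, including 365 releases in leap years.
Snapping also makes every coarser schedule an exact subset of the daily
baseline, so the RF and TR tests subset one baseline run instead of
re-advecting identical trajectories.

## The synthetic ocean

`synthetic_series()` builds daily velocity snapshots per z-level from a
gridded stream function: 90 Gaussian vortices (alternating sign) whose
centres random-walk between snapshots and whose amplitudes follow an
Ornstein–Uhlenbeck process with a 2-day decorrelation time — the scale
on which daily averaged mid-latitude currents typically vary — plus a
weak constant background flow. Velocities are central differences of
the gridded stream function using a fixed local Cartesian metric at the
domain mid-latitude, so the discrete horizontal divergence vanishes to
machine precision and the flow creates no artificial particle sources
or sinks. Cells where the seafloor is shallower than the level are
masked invalid and carry zero velocity.

Topography is an idealized guyot (summit plateau 600 m, base 2000 m,
radii 20/45 km in a 2200 m basin) in a 6 x 6 degree domain at 0.08
degree spacing. Near the seamount the stream function is blended, over
1200 m of water-column clearance, towards its mean value on the
interface band, with 10% of the raw flow retained at the interface
itself. The blend makes the flow steer around the topography (with the
expected flank speed-up) rather than through it; the retained fraction
prevents the interface from becoming an exactly invariant streamline,
which would otherwise trap released particles on a fixed orbit.

Depth structure is imposed through two profiles, calibrated once to the
qualitative behaviour the testing process is meant to recover — current
variability greatest at mid-depth (~1000 m), moderate at 700 m, and
weakest at 1500 m, with the mid-depth variability organised in smaller
patches: peak vortex speeds of 0.05 / 0.125 / 0.008 m/s and vortex
scales of 40 / 26 / 75 km at 700 / 1000 / 1500 m. Overlapping vortices
(about two vortex areas per unit domain area) are essential: a sparse
field of isolated vortices rotates particle pairs almost rigidly and
produces no chaotic relative dispersion at any strength. Mean field
speeds come out near 0.10 / 0.19 / 0.03 m/s at the three depths.

What the generator deliberately does **not** emulate: tides,
sub-mesoscale motion, vertical velocity, density stratification,
boundary currents, and data-assimilated realism. Passing tests on these
fields therefore demonstrate that the *process* (tracking, pairing,
pooling, interpolation, threshold extraction) recovers structure that
is genuinely present in the forcing — not that any particular real
region behaves like the synthetic one.

## Problem sizes of the bundled experiments

The full study-scale design (16 points x 3 depths x 12 monthly releases
x 100-day drift at a 1-h timestep per sweep value) is expressible
directly with `experiment_design()` and `tracker_config()` defaults.
The bundled suite (`suite_config()`) and the seeded recovery
experiments run at sizes chosen for a single CPU: 45-day drifts, a 3-h
timestep, 1–2 release times for the spatial tests, a 60-day
release-frequency window (daily baseline = 60 releases; increments 30,
15, 9, 5, 2) and five 30-day "year" windows with 4 releases each for
the temporal-range test. Depth bands, point counts, increment lists and
both thresholds keep their standard values. `run_hs_ordering_experiment()`
repeats the HS test over 20 seeds and recovers the imposed depth
ordering of optimal separations (1000 m < 700 m < 1500 m) in ~90% of
runs; `run_rf_monotonicity_experiment()` verifies that FUV against the
daily baseline decreases monotonically with release count.

## Numerical choices

* Crossing extraction: bisection to relative 1e-6 inside the first
  bracketing interval, scanning 17 points per knot interval first
  because a shape-preserving cubic can cross mid-interval; exact knot
  hits take precedence.
* Quantiles: type 7 (linear interpolation between order statistics),
  stated because quantile conventions differ between environments.
* Contours: release rings are placed on the topography contour by
  equal great-circle bearing about the fitted circle centre; the
  contour polyline is densified and radially snapped onto the
  interpolated depth surface so along-contour offsets stay on the
  contour to well under a metre of seafloor depth. Ring points carry a
  150 m seafloor clearance (about half the radial depth change per
  grid cell on the guyot flank) — the release sites *interface* the
  seamount at the resolution the gridded topography can express.
* Horizontal-separation increments use buffer-radius-in-degrees
  semantics: an offset of x degrees is an along-contour arc of
  x * pi/180 * 6371 km, reproducing a GIS buffer-then-snap placement
  deterministically and additively.
* Degenerate inputs: duplicate increments, empty pools, zero-variance
  rasters and out-of-range conversions raise errors rather than
  returning silent values.

## Known limitations

* The tracker is 2-D at fixed depth; no diffusivity, behaviour or
  mortality modules, so one release = one trajectory.
* Optimal values at weakly mixed depths are usually extrapolated
  (flagged `approx.`) and are sensitive to the end slope of the
  interpolant; they should be read as "coarser than the tested range",
  not as precise settings.
* The synthetic calibration targets a qualitative depth ordering only;
  absolute optima depend on the imposed speeds and scales and carry no
  meaning for any real region.
* Field I/O uses a self-describing plain-text grid format with
  round-trip fidelity; gridded binary formats are out of scope.
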