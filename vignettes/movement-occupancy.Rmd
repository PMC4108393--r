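---
title: "Movement-based occupancy–abundance curves: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based occupancy-abundance curves: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`packtrack` derives occupancy–abundance curves for wolf monitoring from
simulated two-day track networks. This vignette is the package's account
of the science: the movement and survey model, the parameters that matter,
what the synthetic generators do and do not emulate, the numerical choices
behind the implementation, and the limits of what the simulations show.

## The survey problem

Aerial snow-track surveys score grid cells as occupied when fresh wolf
tracks cross them. If sampling is standardized — surveys flown two days
after snowfall, a fixed fraction of cells searched — the proportion of
occupied cells maps to pack density through a curve that can be built
entirely in simulation: place territories at a known density, move packs
with a realistic movement model for two days, overlay survey grids, sample
cells, and record occupancy. The value of such a curve depends on its
robustness to the biology the surveyor cannot control: movement rate on
the survey days, whether packs travel cohesively, and lone wolves laying
tracks that are not attributable to any territory. The package's scenario
engine quantifies each of these against survey-unit size.

## Movement model

Movement is a two-state, habitat-biased correlated random walk (CRW) at
the 2-h resolution of GPS collar fixes; a "2-day" path is exactly 24
steps.

**States.** Each step is *moving* with probability `p_move` (default
0.57, the observed fraction of active 2-h steps), independently across
steps. Only the marginal activity fraction is observed, so independence
is the minimal model; a first-order Markov chain would need transition
probabilities nobody has published.

**Moving steps.** Lengths are log-normal, truncated to
`[150 m, step_max]` with `step_max` the observed monthly maximum
(December 12,283 m; February 11,843 m), so simulated steps stay inside
the empirical support. The log-scale parameters are solved numerically so
that the *truncated* distribution has the month's observed natural-scale
mean and SD (December 3,013 ± 2,657 m; February 1,488 ± 1,606 m).
Truncating a distribution matched by plain method of moments would shave
~6% off the December mean — enough to corrupt parameter-recovery checks —
so the calibration matches moments of the family actually sampled.
Turning angles are wrapped normal (December −2.46° ± 103.85°; February
0.48° ± 105.12°) about the previous heading; an SD above 100° makes the
walk highly tortuous, with step-to-step directional correlation
`exp(-sigma^2/2)` of only ~0.19.

**Not-moving steps.** Displacement is Uniform[0, 150 m) with uniform
heading — bed and kill sites produce negligible but nonzero net
displacement, and every vertex stays well defined. The CRW heading is
*not* updated by a stationary step: the bearing of sub-150 m jitter is
noise, and directional persistence should survive a resting bout. For
the same reason `fit_movement_params()` estimates turning-angle
statistics only from consecutive pairs of moving steps; turns measured
across a resting step are uniform and would inflate the circular SD by
more than 10°.

**Habitat bias.** At each moving step, `n_candidates = 20` candidate
(length, bearing) pairs are drawn, each scored by the habitat-quality
surface at its endpoint, and one is kept by roulette selection. This is
the standard biased-CRW construction; with one candidate, or on a flat
surface, it reduces exactly to the unbiased CRW (a property the tests
assert bit-for-bit). Pack-owned paths score out-of-territory candidates
zero; if a whole candidate set is invalid the heading is reflected toward
the territory centre and redrawn (up to 10 retries), after which the path
is rejected and resimulated from a fresh start. Confinement is a hard
invariant — every pack-path vertex lies inside its circle — and has a
measurable side effect: near the boundary, long outward candidates are
discarded, so confined paths run a few percent shorter than unconstrained
ones under identical parameters. Lone wolves use the same model with no
territory constraint.

## Territory geometry

At density `d` packs/1,000 km², each circular territory has area
`A = 1000/d` km² (181.8 km² at 5.5; the source material also quotes an
1,800 km² figure at `d = 0.5` that no single rule reproduces — the
1000/d convention is the one consistent with the 182 km² endpoint).
Centres sit on a hexagonal lattice. The 8% neighbour overlap is read as
the *total* fraction of a territory shared with its six neighbours; the
per-neighbour lens is then 8%/6 of the area and the implied spacing is
~1.90 r. This reading is self-consistent in a way the pairwise-8%
alternative is not: it leaves an effective exclusive area within 0.5% of
`1000/d`, so the realized pack count tracks `d` × extent area — at
pairwise-8% spacing (~1.67 r) a 120 × 120 km extent would hold ~19
territories at `d = 1` instead of ~14, breaking the link between the
density axis of the occupancy curve and the number of simulated packs.
`measured_overlap()` verifies the realized fraction by closed-form
circle-lens areas (numerical union quadrature if lenses ever intersect).

The lattice phase is randomized by the seed so replicate layouts are not
grid-aligned artifacts, but the phase draw is conditioned on the lattice
realizing the pack count the density implies (`round(d × 14.4)` here):
pack count is the independent variable of the curve, and boundary
quantization would otherwise jitter it by ±2 packs between replicates.
Centres must fall inside the extent; circles may protrude beyond it,
which is why the habitat raster is padded by one maximum territory
diameter.

## Virtual surveys

Grids of 36, 144, 400 and 576 km² square cells tile the extent exactly
(400, 100, 36, 25 cells). Each survey samples `round(0.2 × n_cells)`
cells uniformly without replacement (round-half-even; the 400 km² grid
surveys 7 of 36 cells). A cell is occupied iff any path segment
intersects the *closed* cell square, computed exactly by cutting segments
at gridline crossings — never by vertex membership, so a long segment
spanning a cell marks it even without a vertex inside. A segment running
along a shared boundary (or through a corner) marks all touching cells:
an observer seeing tracks on a cell edge would call both cells occupied,
and the convention is measure-zero for the stochastic results. Detection
is perfect by assumption; a detection hook exists but defaults to 1 and
sits outside all headline analyses.

Ten replicate surveys are run per (grid, density); each replicate redraws
the surveyed cells, each pack's realized paths (drawn without replacement
from that territory's 1,000-path library — drawing the same path twice
would collapse two hunting units into one), and any loner paths.
`stabilization_check()` reproduces the running-mean diagnostic that
motivated ten replicates. Whether the original surveys redrew cells each
iteration is unstated; redrawing is the default and a flag
(`resample_cells`) exposes the alternative.

Scenario contrasts are paired by construction: layout, survey-cell and
landscape substreams do not depend on month, cohesion or loner settings,
so December vs February (or 1 vs 4 hunting units) differences are not
confounded by layout noise. Hunting-unit draws use per-pack substreams
with a prefix property: under one seed the 1-unit draw is a subset of the
2-unit draw, making cohesion monotonicity exact per replicate. Loner
counts convert pack density to wolves via a mean pack size of 7.8, with
loners 13% of the *total* population: `round(0.13/0.87 × packs × 7.8)`.

## Synthetic stand-ins and what the tests show

The original study's raw inputs — GPS collars from 11 wolves and a
resource-selection function (RSF) fitted to them — are not public, so
three generators supply inputs with the same roles:

* **Habitat surface** (`generate_rsf_surface()`): white noise smoothed by
  a normalized Gaussian kernel (FFT, periodic boundary) and mapped
  through the standard normal CDF into weights in (0.05, 1]; the 0.05
  floor avoids zero-weight traps. The field is deliberately *not*
  re-standardized after smoothing, so the correlation length also
  controls contrast: kernels approaching the extent width flatten the
  surface toward ~0.53, and at the default (5 km correlation on a 500 m
  raster — a typical boreal heterogeneity scale) the surface is
  smooth with mild contrast. Scenario results are accordingly
  insensitive to the surface; the bias mechanism itself is exercised by
  tests on high-contrast two-valued surfaces. Since the real RSF's
  roughness is unknown, this conservatism is a feature: the headline
  contrasts do not hinge on an invented landscape.
* **Linear features** (`generate_line_features()`): near-straight
  roads/pipelines and meandering rivers spanning the extent, as crossing
  targets for path statistics.
* **Telemetry** (`generate_synthetic_telemetry()`): the simulator itself
  chained over many days on flat habitat, with the generating parameters
  attached. Recovery tests close the loop: step decomposition is an
  exact round-trip of simulated geometry, and month-specific fits
  recover the December mean step within 10% and `p_move` within a
  binomial 99% CI at 10,000 steps.

Passing tests therefore demonstrate internal consistency — the simulator
reproduces its own generating parameters, and the survey machinery obeys
its geometric invariants — not fidelity to any particular empirical
landscape or wolf population. The validation harness
(`paired_path_comparison()`) likewise runs simulator-vs-simulator: it
shows the paired design flags nothing when nothing differs (per-statistic
rejection ~5%) and detects forced shifts, but real GPS paths are needed
for the empirical half of that comparison.

## Numerical choices

* Moving/not-moving threshold: a step is moving iff length **> 150 m**
  (the boundary itself is measure-zero; strict `>` keeps the classifier
  consistent with the simulator's truncation support).
* Turning-angle sign: counter-clockwise positive, wrapped to
  (−180°, 180°]. The near-zero monthly means make the convention
  immaterial.
* Circular dispersion: `sqrt(-2 log R)` (circular SD), the consistent
  estimator of the wrapped-normal sigma used by the simulator.
* Truncated log-normal sampling by inverse CDF between the bounds'
  quantiles; the moment calibration is a two-parameter Nelder–Mead solve
  initialized at the untruncated method-of-moments values.
* Degenerate inputs: `step_sd = 0` yields a point mass at the mean;
  collinear fixes give an MCP of zero area with a warning; fewer than
  two fixes give an empty step series; a territory wider than the extent
  collapses to a single centred circle with a warning.
* Fix-series gaps: intervals deviating more than 10% from nominal are
  flagged; steps spanning them are dropped and the following turn is
  undefined. Timestamps are exact interval multiples in synthetic data —
  fix failure modelling is out of scope.

## Problem sizes

The full reference design (12 densities × 4 grids × 1,000-path libraries
× 10 replicates, crossed over months, cohesion and loners) runs in
minutes. The test suite uses that full configuration where a headline
number is checked (density 1, 1,000-path libraries, 10 replicates) and
scaled-down sweeps (10–100-path libraries, 2–4 densities, census surveys)
for distributional properties, with sizes chosen so each property is
decided by its signal rather than Monte-Carlo noise: sweep contrasts use
paired seeds, and proportion claims are tested with binomial error in
mind.

## Known limitations

* The habitat surface is a stationary Gaussian field; real RSFs have
  linear features, patch structure and fitted covariates. Only the
  *role* of the surface (a spatial bias weight) is reproduced.
* Pack cohesion is modelled as independent paths from one library, not
  as coordinated sub-group movement; loners are independent of pack
  positions.
* Activity is an independent Bernoulli process; bout structure
  (auto-correlated resting) is not represented, though a Markov option
  is exposed through the same parameter object.
* Detection is perfect and constant across cell sizes; the package
  deliberately stops short of detection-probability occupancy models.
* The occupancy curve is reported, not inverted: converting a field
  occupancy estimate into a density with uncertainty is downstream work.
* With territory areas tied to density by `A = 1000/d`, low densities
  imply very large territories; below ~0.35 packs/1,000 km² a single
  territory no longer fits the 120 km extent.
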