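---
title: "Measuring diffusion on non-flat membrane surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diffusion on non-flat membrane surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memtopo)
```

Single-particle tracking, FRAP and FCS almost always analyse movement on
the plasma membrane as if the membrane were flat and aligned with the
imaging plane.  Real cell surfaces carry ridges, microvilli, pits and
large-scale crowns, so a molecule's true path lies in a folded or
deformed 2D sheet embedded in 3D.  `memtopo` provides a fully discrete
simulation-and-measurement framework for asking what that topography
alone does to diffusion measurements: it simulates ideal Brownian motion
on a voxelized surface and measures the resulting spread exactly the way
an experimentalist would, with planar (2D) or volume (3D) Euclidean
distances, or with the shortest within-surface (geodesic) distance
(SWSD).  Any departure from Brownian behaviour in the measured curves is
then *apparent* anomalous diffusion: an artifact of geometry plus
metric, not of the walker.

## The surface model

A surface is a set of cubic nodes at integer coordinates inside a 3D
volume, connected by face adjacency (6-connectivity).  All built-in
geometries are generated as integer *height maps* — one height per
pixel, exactly what a hopping-probe ion-conductance microscope or any
height-coded image provides — and converted by one rule:

* each pixel (x, y) contributes a node at (x, y, h(x, y));
* wherever 4-adjacent pixels differ in height, a vertical run of
  connector nodes is inserted at the **higher** pixel's (x, y), covering
  z from the lower height (inclusive) up to the higher height minus one.

Including the lower endpoint is not optional: a run that starts one node
higher leaves the two columns touching only diagonally, and the surface
would fall apart into sheets.  The rule is recorded in every surface's
metadata.

Node neighbour counts classify the local geometry ([classify_nodes()]).
Flat sheets and *folded* surfaces (parallel ridges; anything that
unrolls to a flat sheet without stretching) consist entirely of
4-neighbour interior nodes.  *Deformed* surfaces also contain external
corners with 3 neighbours and internal corners with 5.  These irregular
nodes are the engine of every effect below: the walk described next
redistributes mass per *source* node, so a 5-neighbour node feeds more
forward paths than a flat node and an external corner fewer.

One asymmetry of the higher-pixel convention is worth knowing: raised
features (ridges, pillars, slot corridors) carry their wall sheets on
the raised footprint and so exhibit 5-neighbour internal corners at
their bases, while sunken features (square pits) hang their walls
outside the hole and exhibit 3-neighbour corners instead.  Both are
deformed in the degree-census sense; the census for any surface is one
`classify_nodes()` call away.  Pillars built with the default indented
corners (`indent_corners = TRUE`) lose their base 5-neighbour nodes as
well; build them with square feet if the internal-corner signature is
wanted.

Builders: `build_flat()`, `build_ridges()` (width at least 3 — thinner
ridges have coinciding or base-touching walls and are not folded
surfaces), `build_pillars()`, `build_invaginations()`, `build_bumps()`,
`build_quadrant_composite()`, `build_from_height_map()`,
`build_from_nodes()`, and `insert_defect()` for the one-node-wide slot
(full-height cut, opening a passage at the ridge base) or notch (cut of
configurable depth from the top, default one node — the depth is a free
parameter of the geometry, not something the physics pins down).

## The walk

Brownian motion is a lazy random walk on the adjacency graph.  Per
iteration a node keeps half its probability mass and distributes the
other half equally among its surface neighbours:

$$u^{(t+1)} = D\,u^{(t)}, \qquad
D_{ij} = \begin{cases} 0.5 & i = j\\
0.5/\deg(j) & i \sim j\\ 0 & \text{else.} \end{cases}$$

Dividing by the degree of the *source* node $j$ is the only reading that
conserves mass on irregular graphs, and matches the verbal definition
"half of the particles in each node are redistributed among its
neighbours".  Isolated nodes keep all their mass so that $D$ stays
column-stochastic.  Mass conservation is asserted in the test suite (to
1e-9 over thousands of iterations at full scale), never enforced by
renormalization.  On a flat interior node the rule gives the familiar
numbers: 0.5 stays, 0.125 to each of four neighbours.

The stationary distribution of this operator is proportional to node
degree (detailed balance: the flow $j \to i$ is $0.5\,u_j/\deg(j)$),
which the tests verify against the dominant eigenvector on a small
deformed graph.  That degree bias is precisely why 5-neighbour corners
transiently accelerate and 3-neighbour corners decelerate the front.

Two equivalent simulation modes exist:

* `simulate_diffusion()` / `propagate()` — deterministic propagation of
  the full probability field, covering every possible path at once;
* `sample_tracks()` — stochastic single-particle tracks (one uniform
  draw per iteration decides stay-or-move and the neighbour), seedable
  and bit-reproducible.  Ensembles converge to the propagated field;
  single tracks are dramatically variable even on flat ground, which is
  itself a caution against small-n track analyses.

Time is measured in iterations throughout; node spacing is the distance
unit.  No continuous-time constant is exposed: the lazy walk fixes the
per-iteration rate (2D MSD of exactly $0.5t$ on an unbounded flat
sheet), and every reported quantity is either per-iteration or relative.

### The expanding-region optimization

Mass travels at most one hop per iteration, so the field at iteration
$t$ lives inside the graph ball of radius $t$ around the start.  The
engine orders nodes by geodesic distance from the start once, then
updates only the prefix of nodes within radius $t$ at iteration $t$,
growing the active region one shell per iteration.  This is a pure
optimization with an exactness contract — `restrict = TRUE` and
`restrict = FALSE` agree to better than 1e-12 per node in the tests —
because the excluded nodes provably hold zero mass.

## The three distance measures

From a start node, `distance_maps()` computes per node:

* `d2` $=\sqrt{\Delta x^2+\Delta y^2}$ — what 2D imaging measures;
* `d3` $=\sqrt{\Delta x^2+\Delta y^2+\Delta z^2}$ — the straight line
  through the volume, physically impossible for a membrane molecule
  whenever it leaves the surface;
* `dswsd` — the geodesic distance along face-adjacent surface nodes,
  computed by wave-front (breadth-first) propagation with every hop
  costing one node unit.

The SWSD is deliberately the orthogonal (city-block) geodesic: on a flat
surface the (3, 4) offset measures 7, against a Euclidean 5.  This
systematic elongation cancels in every relative measure, which is why
the package reports $D_{rel}$ rather than comparing metrics directly.
Euclidean-weighted geodesics with diagonal moves are out of scope.
Unreachable nodes are reported as `Inf`, never as a large finite number.
For every node $d_{swsd} \ge d_{3D} \ge d_{2D}$, and on folded ridge
surfaces the SWSD equals the city-block distance on the unrolled sheet
exactly (both are test invariants).

## From fields to MSD, D and D_rel

At every iteration the population MSD under a metric is the
probability-weighted mean of the squared distance from the start,
$\mathrm{MSD}_m(t) = \sum_i u_i(t)\, d_m(i)^2$, accumulated
in-stream by `simulate_diffusion()` (or from snapshots by
`population_msd()`).  Derived quantities:

* `fit_diffusion()` — ordinary least-squares slope of MSD versus
  iteration over a caller-chosen window (default: the last half), the
  discrete "least-squares tangent".  On flat ground the 2D slope is 0.5
  node²/iteration at any window.
* `drel()` — $D_{rel}(t) = \mathrm{MSD}_m(t)$ on the test surface
  divided by $\mathrm{MSD}_m(t)$ on a flat reference, same metric, same
  iteration.  A per-iteration *ratio* was chosen over a ratio of fitted
  slopes because the transient features of interest — a shortcut's
  superdiffusive hump, the slow confinement of 2D measurements — are
  functions of time that a single fitted slope collapses; the
  fit-based coefficient remains available separately.  $t = 0$ is
  excluded.
* `drel_plateau()` — D_rel curves on periodic surfaces approach their
  asymptote like $a + b/t$ (the bounded variance of the periodic height
  profile decays as $1/t$ against the linearly growing MSD), so the
  long-time plateau is estimated as the intercept of an OLS fit of
  $D_{rel}$ against $1/t$ over the last half of the curve.  Reading the
  raw curve at the final iteration instead converges to the same two
  decimals but only at several times more iterations; the extrapolation
  is exact on curves of exactly that form (tested).
* `classify_anomaly()` — labels each iteration super/normal/sub around
  a tolerance band (default 0.01) and reports the landmarks: peak,
  minimum, and first return to 1 after the peak, ties broken to the
  earliest iteration.
* `occupied_node_count()`, `probability_by_distance()` — the support
  size and integer-shell mass histograms (floor binning; SWSD shells
  are exact because those distances are integers).

The flat reference is generated by the same engine on `flat_1024`
(1024 × 1024 nodes, start at the centre).  At the largest horizon
analysed (3000 iterations) the per-axis displacement standard deviation
is $\sqrt{0.25 t} \approx 27$ nodes, so the 511-node margin keeps the
probability mass near the rim below $10^{-40}$ of the total — boundary
contamination is far beneath double precision even though the strict
support (radius $t$) formally touches the rim.  Sizing the reference to
keep even the strict support interior would need a 6001²-node sheet for
no measurable change.

## What the canonical geometries show

* **Folded ridges** (height 4, width 4, spacing 2): the SWSD unrolls the
  surface, so $D_{rel}^{swsd} \equiv 1$ to machine precision at every
  iteration.  The 2D and 3D measures converge to a common plateau of
  0.59: one unrolled period of 14 nodes projects onto 6 planar columns,
  and only the folded axis is compressed, giving
  $((6/14)^2 + 1)/2 = 0.5918$ — reproduced by the simulation to two
  decimals from either a gap-floor or a mid-wall start.  The 2D MSD
  curve is concave with MSD$/t$ falling at every iteration (exactly the
  signature usually read as confined or hop diffusion), while the SWSD
  MSD stays linear with $R^2 > 0.9999$.
* **Slot and notch defects** (ridges 7 high, 3 wide, 12-node pitch in a
  1023 × 1023 × 9 volume, start on the gap floor midway between the
  defect-carrying ridge and the next): a single one-node-wide slot
  creates four 5-neighbour base corners and a passage that both spreads
  mass faster and shortens the measured SWSD.  The result is transient
  apparent superdiffusion: with the default geometry the package
  computes a peak of $D_{rel}^{swsd} \approx 1.036$ at iteration 114, a
  return through 1 at iteration 270 and monotone apparent subdiffusion
  afterwards (0.88 at iteration 1100).  The notch (default depth 1)
  shows the same shape with a far weaker peak, strictly between 1 and
  the slot's.  The *landmark iterations* of such curves are sensitive at
  the ten-percent level to representation conventions that the physics
  does not constrain — connector attachment, wall-height counting, and
  whether D_rel is a ratio of MSDs or of windowed fitted slopes — so
  they should be compared between implementations only together with
  those conventions; the qualitative sequence
  super → crossing → sub is robust to all of them.
* **Deformed surfaces** (pillars, pits, dense bumps, cells): no metric
  recovers the flat baseline.  2D is worst and keeps falling, 3D helps
  only at short times, the SWSD is closest but still below 1 — on a
  deformed surface the geodesic understates true path lengths much as a
  mountain pass understates the wandering of the goats.

## The synthetic cell generator

`synthetic_cell_heights()` emulates the apical topography of cultured
epithelial cells as height-probe microscopy shows it: a few smooth
cell-scale crowns (2D Gaussians, default 3 crowns, amplitude 36 nodes,
σ = 90 px on a 512² map), superimposed sinusoidal ridge undulations
(amplitude 4, period 24) and several hundred small bumps, quantized to
integer heights.  Defaults were chosen once as a plausible cell-like
relief: crowns comparable in lateral scale to the simulated exploration
radius (so 2D underestimation keeps deepening over the run rather than
homogenizing into a plateau) and decorations that make the surface
strongly deformed (3/4/5-neighbour census).  The generator is seeded and
bit-reproducible.

What it does *not* emulate: real microscope noise and sampling
anisotropy, membrane motion during acquisition, sub-node curvature, or
any surface that changes while the walker moves.  Tests passing on this
fixture show that the measurement machinery behaves as designed on
cell-like static relief; they say nothing about dynamic or unresolved
topography, where the geometric effects can only grow.

## Numerical choices and degenerate inputs

* Double precision throughout; no per-step renormalization.
* The walk on an isolated node keeps its mass (operator stays
  stochastic even at degree 0).
* Ridge width below 3 is rejected as an invalid specification, not
  silently accepted.
* Tie-breaks on curve landmarks go to the earliest iteration.
* Start nodes may be given as coordinate triples or node indices;
  off-surface coordinates raise an invalid-spec error, provenance
  mismatches between fields, maps and operators raise contract errors.
* Serialization stores the sorted node list plus metadata and recomputes
  adjacency on load; height maps round-trip through CSV and 16-bit TIFF
  (TIFF projections are display copies; CSV holds exact values).

## Problem sizes used in the shipped analyses

The package's own test-and-reproduction runs use: the 1024² flat
reference and a 512 × 1024 folded-ridge domain for 3000 iterations; the
full 1023 × 1023 × 9 defect fixtures for up to 1100 iterations; a 512²
synthetic cell for 2000 iterations; and 64 000 sampled tracks of 400
iterations for the stochastic/deterministic cross-check (agreement
within three standard errors).  At these sizes every front stays far
from the volume rims (margins above ten standard deviations) and the
complete suite runs in minutes on one CPU.

## Limitations

Static surfaces only; no interacting particles, binding kinetics, or
genuine anomalous-diffusion generators — by design, so that every
observed deviation from Brownian behaviour is attributable to geometry
and metric.  Distances are isotropic in node units; anisotropic voxel
spacing is not modelled.  The SWSD is a hop-count geodesic; sub-node
geometry and Euclidean-weighted geodesics are out of scope.
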