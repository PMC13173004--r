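---
title: "Mid-range energy-layer selection for proton arc therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-range energy-layer selection for proton arc therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

Discrete proton arc plans deliver pencil-beam-scanning spots from many
gantry angles. If every angle stacks all energy layers that reach the
target, the plan pays a heavy time cost: each within-angle energy switch
takes on the order of a second, and full-range arcs accumulate thousands of
layers. Distal-edge-tracking alternatives (one layer per angle at the far
target edge) are fast but park every Bragg peak — and with it the high-LET,
high-RBE end of the track — on the boundary between target and normal
tissue, exactly where a range error does the most biological harm.

The mid-range strategy implemented here takes the single layer per gantry
angle whose Bragg peak sits at the water-equivalent *centre* of the target
along each beam direction. For each control point it:

1. traces the water-equivalent path length (WEPL) along each spot ray and
   records the proximal and distal target edges `R_p`, `R_d`;
2. computes the per-ray mid-range point `R_p + alpha * (R_d - R_p)` with
   `alpha = 1/2` (`alpha = 1` reproduces distal-edge tracking);
3. takes the median over the target-intersecting rays of the control
   point, converts that range to energy, and snaps it to the machine's
   deliverable list.

One layer per angle means zero within-control-point energy switches, and
the angular superposition of many mid-range peaks recovers target coverage
that a single direction could not provide. Because every peak sits well
inside the target along its ray, a +-3% range error moves peaks around
*within* the target rather than across its boundary.

## Geometry conventions

Images are axis-aligned voxel grids of relative stopping power (RSP), mm
coordinates, origin at the first voxel centre. Gantry angle 0 enters from
the anterior (+y) side travelling along -y and increases clockwise viewed
from the feet; the BEV basis is `u` (axial, `u = (cos t, -sin t, 0)`) and
`v = +z`, a right-handed triad with the beam direction, continuous in the
gantry angle. Arcs are coplanar and beams parallel (infinite SAD): the
mid-range logic is SAD-independent and the parallel geometry keeps every
ray identity exactly testable. A 360 degree arc at the 5.07 degree
control-point spacing used throughout discretizes to
`round(360 / 5.07) = 71` control points at exact 5.07 degree increments,
the closing gap absorbing the 0.03 degree remainder.

## The synthetic phantom

The built-in phantom is an ellipse (semi-major 15 cm lateral, semi-minor
10 cm anterior-posterior) of water-equivalent tissue, extruded 2 cm along
the superior-inferior axis, with a C-shaped target (annulus between 1.5
and 3 cm radius minus a 90 degree opening wedge facing +x) around a
central 1 cm OAR disk separated by a 0.5 cm gap. Target and OAR RSP are
1.01 and 0.99 — quoted densities of near-water media used directly as
stopping-power ratios, the only reading under which the WEPL arithmetic is
consistent. Outside-body voxels carry RSP 0.001 (air) rather than zero so
ratio operations stay finite. The elliptical outline makes WEPL
direction-dependent, the feature of patient contours this phantom is meant
to emulate; what it does not emulate are tissue heterogeneities, so
passing tests here say nothing about lateral scattering distortions at
bone/air interfaces. The C opening's width and orientation are package
parameters with documented defaults (90 degrees, facing +x); prescriptions
default to 20 Gy to 95% of the PTV in 10 fractions.

Default voxel size is 2 mm; at that resolution the phantom grid is
160 x 110 x 20 voxels, the problem size used for all shipped end-to-end
checks. A voxel belongs to a region when its centre does, and masks refine
consistently: halving the voxel size changes region volumes by less than a
one-voxel perimeter shell.

## Ray tracing

WEPL is accumulated by exact Siddon-style traversal: the ray is split at
every voxel-face crossing, so `WEPL(t)` is exact for the voxelized RSP.
Depth zero is the body surface (first voxel with RSP > 0.05), which makes
depths commensurate with in-water machine ranges; upstream air contributes
(negligibly) to nothing. A 0.1 mm fixed-step marching implementation lives
in the test suite as the independent oracle, never in the package path.
Rays crossing the target in several disjoint segments (both arms of the C)
use the outermost envelope for `R_p`/`R_d` — this guarantees the mid-range
point lies between the target extremes along the ray — while the
individual segments are kept for full-range spot assignment (below).

## Machine model

Range-energy conversion is the Bragg-Kleeman power law `R = a E^p` with
a = 0.0022 cm/MeV^p, p = 1.77 (a standard clinical-range fit), inverted
analytically. The deliverable list is 70-230 MeV in 1 MeV steps, giving
0.1-0.3 cm range granularity. Timing constants — 0.6 s per within-angle
energy switch (up = down by default; both fields exist), 2 ms per spot
transition, 40 MU/s, gantry speed 360/390.5 deg/s — are calibrated so the
additive time model's internal arithmetic is self-consistent; they are
config fields, not measured constants. Energy ties snap to the *lower*
energy, biasing peaks slightly proximal (conservative for tissue beyond
the target).

## Dose and LET engine

The engine is an analytic pencil-beam model — a deliberate, documented
substitution for Monte Carlo transport. Consequences are stated plainly:
absolute dose and LET_d magnitudes on real anatomies are approximations;
orderings, containment properties, and counting claims are the reliable
surface.

*Depth dose.* A Bortfeld-type power-law Bragg curve: stopping-power term
`(R0 - z)^(1/p - 1)` plus a fluence-reduction correction
(beta = 0.012 cm^-1, gamma = 0.6), cell-averaged over a 0.02 cm grid (the
singularity at `z = R0` is integrable) and convolved with a Gaussian whose
width combines range straggling `sigma_R = 0.012 R0^0.935` with beamline
momentum spread (default sigma_E/E = 1%, in quadrature). The curve is
evaluated on a grid extended upstream of the surface before smoothing so
the entrance plateau is not artificially halved at the boundary. Resulting
curves peak within [0.95, 1.02] R0 with entrance-to-peak ratios 0.2-0.35
across clinical ranges.

*Track LET.* The primary proton stopping power at the residual range,
averaged over the same straggling ensemble (smoothed stopping power over
smoothed residual fluence). This reproduces the monotone rise to a distal
maximum and the decrease of peak LET with increasing beam energy — the
mechanism that makes anterior-posterior beams (lower energy on this
phantom) dominate the LET_d distribution. It is primary-track only:
nuclear secondaries are not modelled, so absolute LET_d differs from Monte
Carlo values.

*Lateral model.* Single Gaussian, `sigma^2(z) = sigma0^2 + sigma_MCS^2(z)`
with a Highland-type growth `sigma_MCS = 0.0224 R0^0.896 (z/R0)^1.7`; the
nuclear-halo second Gaussian is omitted (a config hook is reserved). Point
dose is `DD(z) G(r; sigma(z))` with the WEPL depth taken from the spot's
central axis (no heterogeneity-driven lateral scaling). Contributions
below 1e-4 of the spot's on-axis maximum are dropped.

*Accumulation.* Dose is the weighted sum of spot kernels; LET_d is the
dose-weighted mean of track LET, reported only where dose exceeds 1% of
prescription — dose-averaged LET is numerically meaningless at near-zero
dose, and structures entirely below the threshold report "undefined"
rather than zero.

## Optimization and normalization

Spot weights minimize quadratic physical-dose objectives: a two-sided
target-uniformity term at the prescription, one-sided overdose penalties
for OARs (reference 0), a one-sided conformity-ring penalty (body within
1 cm of the target, reference half the prescription) and a one-sided
hotspot cap at 107% inside the target. The ring is this package's own
addition — with only a distant OAR penalized, the optimizer would happily
park Bragg peaks in the unpenalized gap between OAR and target; a
conformity ring is the standard clinical device for that. Objective
weights (100/10/2/50) are tuning parameters of this package, not reported
values.

The solver is projected gradient with Armijo backtracking from a cold
start at zero — deterministic, no randomness anywhere in the pipeline;
identical spots receive the symmetric split of degenerate optima. Rows of
the influence matrix are the voxels of target, OARs and ring (optionally
strided for very large comparator plans; the full-range arc at 165k spots
uses stride 4 to keep the sparse matrix near 10^7 nonzeros). Convergence
is a relative objective decrease below 1e-6 or 400 iterations.

Plans are then scaled multiplicatively so the target D95% equals the
prescription, using the exact type-7 sample quantile (idempotent to
floating precision). The DVH-read D95 can differ from the quantile by up
to one DVH bin plus the local order-statistic gap; at 2 mm voxels the
shipped checks show agreement within one 0.01 Gy bin.

## Full-range and IMPT comparators

The full-range arc enumerates, per control point, every deliverable energy
whose range falls in the `[min R_p, max R_d]` envelope over spot rays
("all possible layers"); the enumeration never returns an empty set (the
nearest deliverable layer is used when the envelope is narrower than the
energy granularity). Spots are assigned to a layer only where the layer's
range lies inside target tissue along that ray (the union of target WEPL
segments, not the envelope): under the envelope reading, rays crossing
both arms of the C would receive "target" layers whose peaks sit in the
OAR gap. Positions whose segments catch no layer fall back to their
nearest layer so no intersecting ray is left uncovered. The IMPT
comparator applies the same enumeration to two static beams
(lateral-opposed by default; the published comparator's angles are not
available, so the default is a package choice).

## Robustness model

Eight scenarios: RSP scaled by 1 +- 3% (so +3% stopping power shortens
every geometric range by ~3%) and +-3 mm rigid shifts along each
anatomical axis, implemented as an origin shift of image and structures
relative to the fixed beam geometry. Scenarios reuse the frozen optimized
weights and the nominal normalization — nothing is re-optimized. The
nominal scenario reproduces the nominal grids bit-for-bit. DVH bands are
per-bin min/max envelopes over scenarios; worst case is per metric
(minimum over scenarios for coverage, maximum for hotspots), not a single
worst scenario.

Bragg-peak containment — the mechanism behind the strategy's robustness —
is quantified as the MU-weighted fraction of positive-weight spots whose
range stays confined within the target along their rays under the scaled
WEPL. The default criterion is the *envelope* reading (range within the
ray's `[R_p, R_d]`, i.e. the peak is buffered by target tissue on both
sides along the beam); a stricter point-in-tissue criterion is available.
MU weighting is deliberate: the placement stage also creates central-ray
spots whose mid-range point falls in the OAR gap of the C, and the
optimizer switches those off; an unweighted count over placed spots would
grade spots that deliver no protons. Under +-3% range scaling the
mid-range plan's containment fraction is severalfold the distal-edge
(`alpha = 1`) plan's and essentially insensitive to the perturbation
sign, whereas the distal-edge fraction collapses under range
undershoot — the ordering the shipped tests assert. No single-energy-
per-angle plan reaches containment near 1 on this geometry: rays that
clip the target edge have short WEPL chords that cannot contain the
angle's shared energy, and the optimizer deliberately uses such rim spots
to sharpen the lateral falloff.

## Delivery-time model

`TBD = SST + SSWT + ELST + GRT`, exactly additive: scanning time
`MU / mu_rate`, spot-switch time `t_ss (spots - layers)`, energy-layer
switch time summed per control point over `(layers - 1)` switches (layers
delivered in descending energy within an angle), and gantry rotation
`arc_span / speed` (static fields instead accrue a per-field setup
constant, default 0). Energy changes *between* control points cost
nothing — they happen during rotation; a config flag (default off) adds
the excess when a switch outlasts the rotation interval. MU are accounted
per fraction. Single-layer-per-angle plans therefore have ELST identically
zero, which is the strategy's defining delivery property. A constant
gantry speed cannot reproduce case-to-case variation in reported arc
rotation times; the model makes no attempt to.

## Numerical choices and edge cases

- Median with even counts takes the lower central value (peaks biased
  proximal).
- Rays missing the target return a sentinel and the spot is dropped;
  control points whose rays all miss are flagged empty and excluded from
  sequencing.
- A target shallower than the lowest deliverable range clamps to the
  lowest energy layer.
- Zero-dose voxels are excluded before the RBE formula (singular at
  `D_p = 0`); voxels covered by no structure take the body
  (alpha/beta)_x = 3 Gy with a warning counter; overlapping structures
  resolve target > OAR > body.
- The RBE model (p0 = 0.99, p1 = 0.36, p2 = 1.101, p3 = -0.0039) is
  evaluated exactly as published. Its monotone LET dependence in target
  tissue holds for fraction doses up to ~13 Gy at (alpha/beta)_x = 10;
  above that the negative-p3 beta term dominates and RBE *decreases* with
  LET. Property tests therefore assert monotonicity over clinical
  fraction sizes only.

## Known limitations

- Analytic engine: no nuclear secondaries, no heterogeneity-driven lateral
  scaling, single-Gaussian lateral profile. Absolute LET_d and RBE values
  are model-specific; cross-strategy *orderings* on the same engine are
  the meaningful comparisons.
- One consequence worth stating explicitly: the 2-percentile LET_d inside
  a low-dose OAR adjacent to the target is *higher* than inside the target
  under this engine (and under any dose-averaged accounting in which the
  OAR's residual dose comes mostly from peak-depth lateral halo), because
  target voxels dilute their peak LET with entrance dose from 71
  directions while the spared OAR keeps only the high-LET component.
  Published phantom tables that report near-zero OAR LET_d values reflect
  a different (undocumented) low-dose reporting convention; this package
  reports the masked dose-averaged statistic and documents the divergence.
- Coplanar arcs and parallel beams only; no couch rotation, no divergent
  source model beyond the config flag reserved for it.
- No robust or LET-based optimization; objectives are physical-dose
  quadratics.
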