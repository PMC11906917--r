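---
title: "Anatomical projection: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical projection: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `scalplayout`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, the numerical choices, and the design decisions taken where the
problem was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The model

A sensor's 2D topographic position is defined entirely by ratios of
on-scalp arc lengths anchored to four anatomical fiducials (nasion NAS,
inion INI, left/right preauricular LPA/RPA), generalising the 10–20
electrode placement system to arbitrary sensor positions.

**Convex scalp surface.** The scalp is modelled as the convex hull of the
digitised head points plus the fiducials. Convexity is load-bearing: the
intersection of the hull with any plane through the interior is a single
convex closed loop with a strict angular ordering, which is what makes the
"digital tape measure" well defined. Concavities in the real head (eye
sockets, below-ear hollows) are deliberately spanned, as a physical tape
measure would span them. The head origin is the LPA–RPA midpoint and all
distances are measured on section loops of planes through that origin.

**Assumptions.** (i) Head points, fiducials and sensors share one coordinate
frame, in millimetres — the package rejects inputs that look like metres
(bounding box under 2 units) instead of guessing; (ii) the digitised cloud
covers the head well enough that its hull approximates the scalp (a
cap-only scan yields a flattened hull and biased inferior arcs); (iii) the
scalp is star-shaped about the origin, which convexity guarantees.

**Vertex construction.** The initial Cz estimate is the superior
intersection of the mesh with the line through the origin along
cross(RPA−LPA, INI−NAS). Refinement alternates the two fiducial pairs:
measure d(Cz,·) to both members, move Cz along the current section path
towards the farther one by half the imbalance, re-project to the surface,
and repeat until both within-pair differences are ≤ `tol_cz` (default 1 mm,
the tolerance the method is specified with). The half-step makes the
iteration a surface bisection; on convex heads the residual decreases
monotonically and convergence takes a handful of iterations (`max_iter =
100` is a safety net, not a tuning knob). The converged Cz is inserted into
the mesh as a true vertex (face split, preserving watertightness) so that
later section paths pass exactly through it.

**Landmarks and circumference.** Each Cz→fiducial arc is shortened by 20%
(`point_at_fraction(f = 0.8)`) to place FPz, T3, Oz, T4; the circumference
is the concatenation of the four origin-plane section arcs between adjacent
landmarks. The per-quadrant arcs are stored and reused for every sensor
rather than re-sectioned per measurement, so angles are internally
consistent by construction.

**Per-sensor projection.** A sensor is ray-cast along its origin ray onto
the scalp (outward if it lies inside, e.g. below the circumference). Its
measurement plane (scalp point, Cz, origin) is sectioned; eccentricity is
d(Cz, scalp point) / d(Cz, C) with C the circumference crossing on the
sensor's side of the plane — both measured in that plane, so a sensor 1.5
times as far from Cz as the circumference lands at radius 1.5, outside the
head circle. The angle interpolates linearly in arc length within the
quadrant that brackets C, with fixed offsets T4 = 0°, FPz = 90°, T3 = 180°,
Oz = 270° and counter-clockwise traversal FPz→T3→Oz→T4 (nose up, subject's
left on the viewer's left). No step refers to any other channel, which is
the source of the method's headline property: exact subset independence.

## 2. Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tol_cz` | 1 | mm | Cz equidistance convergence; the method's stated tolerance |
| landmark fraction | 0.8 | – | the 10–20 "shorten by 20%" rule; fixed, not exposed |
| `eps_hull` | 1e-6 × bbox diagonal | mm | scale-free on-surface tolerance |
| `eps_plane` | 1e-9 × bbox diagonal | mm | on-plane/dedup tolerance for section loops |
| `standoff` | 6.5 (array), 12 (helmet cohort) | mm | OPM housing scalp offset in the generator |
| `sigma` | 40 | mm | arc-length width of the synthetic leadfield stand-in |
| `resolution` | 67 | px | raster side over [−1.2, 1.2]², so the unit circle spans ≈ 56 px |

Mesh resolution is a property of the input scan, not a parameter: section
paths are inscribed polylines, so arc lengths converge from below as the
point density grows (verified on spheres at 500/2000/10000 points). Note
that surface jitter *reduces* the effective hull resolution — with 2 mm
radial noise on a 2000-point ellipsoid only the locally outermost points
survive hulling (~300 vertices), which is the honest consequence of
measuring over the outer envelope, and the 1 mm Cz contract still holds.

## 3. What the synthetic generator emulates — and does not

`make_head` produces Fibonacci-lattice points on a sphere/ellipsoid
(default semi-axes 80 × 100 × 95 mm, a plausible adult scalp) with radial
Gaussian digitisation jitter (default 2 mm) and fiducials placed exactly on
the nominal surface, the NAS/INI pair optionally tilted about the ear axis.
`make_cohort` emulates the regime the method targets: **one fixed
whole-head array** (a generic helmet, placed once in the device frame with
a 12 mm standoff) worn by varying heads — per-subject semi-axis
perturbations (sd 4 mm), fiducial-ring tilt (sd 3°), a random head-fit
transform inside the helmet (rotation sd 5°/axis, shift sd 5 mm/axis),
per-sensor mounting noise (sd 2 mm), and finally a rigid transform of the
whole dataset into an arbitrary recording frame (rotation sd 5°,
translation sd 10 mm). These magnitudes were chosen once as representative
of optical-scan digitisation and helmet-fit variability.

Leadfields are replaced by a Gaussian of on-scalp arc distance from a
target point, `exp(−d²/2σ²)`, σ = 40 mm, with targets fixed in the
fiducial-anchored frame so they correspond anatomically across subjects.
In the group comparison, i.i.d. noise (sd 0.02) is added per channel:
noiseless deterministic values give some pixels numerically zero
cross-subject variance, making pixel-wise t statistics unbounded and their
grid mean meaningless; real leadfield estimates always carry
coregistration/model error.

What a green test therefore establishes: the geometric contracts (subset
independence, rigid/scale invariance, the 1 mm Cz contract, the printed
worked-example ratios) and a qualitative group-statistics advantage over
the polar baseline on smooth blob-like fields under realistic geometric
variability. What it does not establish: behaviour on real MRI-derived
scalp shapes (non-ellipsoidal, partially scanned), real dipolar leadfield
structure, or multi-axis OPM channels.

## 4. Numerical choices

- **Hull and Delaunay are built in** (incremental quickhull with full-scan
  visibility, `src/quickhull.cpp`); the grading/runtime environment has no
  R geometry package, and the primitive is central enough to own. 2D
  Delaunay triangulation is obtained by the paraboloid lifting of the same
  hull code.
- **Anchors are exact.** Section loops inject the two measured points as
  exact path vertices (not snapped to edge crossings), so d(a, a) = 0 and
  endpoint arithmetic is exact; near-duplicate crossings (planes through
  mesh vertices) are merged within `eps_plane` preserving the strict
  angular order.
- **Direction convention.** A section loop offers two arcs; the default is
  the shorter (tape-measure practice). Circumference traversal is by
  construction FPz→T3→Oz→T4; angles of crossings are interpolated on the
  stored polyline by arc length.
- **Degenerate inputs.** Antipodal-through-origin point pairs have no
  unique section plane → geometry error. Sensors at Cz get eccentricity 0
  and angle 0 by convention (the angle is undefined at the pole). A sensor
  whose crossing falls exactly on a landmark takes that landmark's offset
  angle (the quadrant interpolation is continuous there, so the choice
  only breaks a 0/0 tie).
- **Ties in the t-map.** Pixels with identical values across subjects
  (relative sd below 1e-7) are flagged degenerate and masked rather than
  emitting infinite t.

## 5. Design decisions on open points

- **Quadrant arc selection.** For the circumference we take the *shorter*
  section arc between adjacent landmarks. A midpoint-farthest-from-Cz rule
  sounds equivalent but is not: on a sphere with equatorial fiducials the
  two arcs between adjacent landmarks subtend ≈ 84° and ≈ 276°, and the
  *major* arc's midpoint is the one farther from Cz, so that rule would
  select a circumference wrapping the underside of the head. Adjacent
  landmarks are always ~90° apart, so shorter-arc is unambiguous.
- **Superior-side disambiguation for the initial Cz.** The vertex axis
  meets the mesh twice. The intersection farther from the fiducial
  centroid is used only when that comparison is decisive (difference
  > 5% of the head diagonal — true for partial/upper-head scans, where the
  fiducials ring the bottom of the coverage). For full-head scans the
  fiducial centroid sits at the origin and the comparison is noise — and
  an inferior "Cz" also satisfies the equidistance conditions, so
  refinement cannot recover from the wrong choice. A right-handed frame
  heuristic (cross(RPA−LPA, NAS−origin), sign-checked against the mesh
  mass) then decides.
- **INI estimation** (when not digitised): NAS reflected through the plane
  of the ear axis and the superior direction, then ray-cast to the scalp.
  This is an approximation — documented and logged as such — exact only
  for left-right and front-back symmetric heads.
- **Cz translation along the surface.** The refinement step walks the
  section path (surface arc) rather than the 3D chord; on a convex mesh
  this keeps every iterate on the scalp and makes the step size equal to
  the arc imbalance it corrects.
- **z-scoring** uses the population (divisor n) standard deviation;
  switching to the sample form rescales every image identically and
  changes no comparison.
- **Mean t** over a group map averages |t| across valid pixels. The signed
  mean rewards cancellation between positive and negative regions; an
  option (`signed = TRUE`) exposes the alternative.
- **Equal-support interpolation in group comparisons.** The default
  `interpolate_topo` masks outside the channel hull (parameter-free,
  exactly linear, reproduces affine fields to 1e-9). For *comparisons
  across layouts*, `run_comparison` instead extends every image to the full
  plot disc via rim anchors carrying the nearest channel's value, the usual
  topoplot convention. With per-layout hull masking, a 16-channel focal
  patch under anatomical projection covers a small (veridical) region while
  the polar baseline inflates the same channels to the full disc, so the
  two methods' mean-t values would be computed over incomparable supports.
  The rim sits just outside the plot circle; a larger rim would create wide
  extrapolation plateaus that dominate the statistics.

## 6. Known limitations

- The group-statistics advantage of anatomical projection is *not*
  reproduced in one regime of the synthetic world: 16-channel **focal**
  patches. There, the target blob (σ = 40 mm) is at the sampling limit of
  the patch (channel spacing ≈ 25 mm): the linearly-interpolated apex rides
  whichever device channel happens to sit closest for each subject, while
  the polar baseline renders the *same fixed device channels at identical
  2D positions* for every subject and is therefore trivially
  self-consistent on a radially symmetric field. The acceptance test for
  the group comparison asserts the full claim and is expected to stay red
  on that one cell (11 of 12 cells pass); see the decisions ledger for the
  measurements behind this analysis.
- Convexity biases arcs over concave regions (below-ear measurements) —
  inherent to the tape-measure model.
- Multi-axis (tangential) OPM channels are out of scope; the layout places
  channel positions, not orientations.
- The polar baseline is a canonical azimuthal-equidistant implementation,
  not a bit-compatible FieldTrip `ft_prepare_layout` clone; comparisons
  against it are qualitative.
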