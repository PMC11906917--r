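# scalplayout

Anatomically anchored 2D sensor layouts for on-scalp MEG and EEG.

## The problem

Sensor-level data from on-scalp neuroimaging (EEG, and increasingly
OPM-based MEG) is routinely inspected on 2D "topoplot" layouts. For EEG the
10–20 placement system ties every electrode to head anatomy, so topographies
are comparable across people. OPM arrays, in contrast, are bespoke: sparse,
focal, or simply different from subject to subject. The standard *polar
(azimuthal) projection* flattens the array about its own axes — centred on
the sensor centroid and rescaled to the unit circle — so a channel's 2D
position depends on *which other channels are present* and not on anatomy.
Group averages and statistics over such layouts smear spatially.

`scalplayout` implements an **anatomical projection**: it digitally
reconstructs the 10–20 system on each individual's digitised head shape and
reads every sensor's 2D position off that construction, independently of the
rest of the array.

## The method

Inputs: head-shape points, the fiducials NAS/INI/LPA/RPA, and sensor
positions, all in one coordinate frame (mm). INI may be omitted and is then
estimated. The steps:

1. **Convex scalp mesh.** The convex hull of head points plus fiducials; the
   origin is the LPA–RPA midpoint. Hulling discards concavities, like a
   physical tape measure would.
2. **On-scalp distances.** Any two scalp points A, B define a unique plane
   through the origin. Its intersection with the convex mesh is a closed
   planar loop, strictly ordered by polar angle about the plane normal; the
   distance from A to B is the polyline arc length between them
   (a "digital tape measure").
3. **10–20 frame.** The vertex Cz is found by iterating until the on-scalp
   distances satisfy d(Cz,NAS) = d(Cz,INI) and d(Cz,LPA) = d(Cz,RPA) within
   1 mm. Shortening each Cz→fiducial arc by 20% places the circumference
   landmarks FPz, T3, Oz, T4; connecting them with section arcs draws the
   head circumference.
4. **Per-sensor projection.** Each sensor is ray-cast onto the scalp; its
   *measurement plane* (through scalp point, Cz and origin) crosses the
   circumference at a point C. Then

   - eccentricity `e = d(Cz, S) / d(Cz, C)` (e > 1 falls outside the head
     circle, e.g. face sensors), and
   - angle `θ = offset(L) + 90° · arc(L→C) / arc(L→L')` for the landmark
     pair L, L' bracketing C, with offsets T4 = 0°, FPz = 90°, T3 = 180°,
     Oz = 270° (nose up, subject's left on the left).

   With the worked-example distances d(Cz,S) = 18 cm, d(Cz,C) = 12 cm the
   eccentricity is 18/12 = **1.5**; with arcs FPz→C = 10 cm, FPz→T3 = 15 cm
   the angle is 90° + 90°·(10/15) = **150°**.

The package also ships the polar-projection baseline, a topographic
interpolation / z-score / group t-map evaluation pipeline, and a synthetic
generator (parametric heads, fiducials, arrays, leadfield-like fields,
multi-subject cohorts) that powers all tests.

## Worked example

```r
library(scalplayout)
scan <- make_head(synthetic_head_spec(semi_axes = c(80, 100, 95),
                                      n_surface_points = 2000,
                                      surface_jitter_sd = 2, seed = 1))
mesh <- build_head_mesh(scan)
grid <- build_grid(mesh, scan$fiducials)
grid
#> <grid_1020> Cz (0.5, 0.0, 97.0) mm after 1 iterations
#>   residuals: NAS/INI 0.043 mm, LPA/RPA 0.000 mm
#>   circumference 551.1 mm (quadrants: 137.4, 139.1, 137.7, 137.0)

sensors <- place_array(scan, 8, standoff = 6.5, seed = 1)
make_layout(scan, sensors, grid = grid)
#> <layout_2d> 8 channels (anatomical projection)
#>   label eccentricity   angle        x       y
#> 1   S01       0.2848  97.029 -0.03485  0.2826
#> 2   S02       0.5716 229.356 -0.37231 -0.4337
#> 3   S03       0.7296   9.259  0.72009  0.1174
#> 4   S04       0.8883 150.869 -0.77592  0.4324
#> 5   S05       0.9658 288.603  0.30811 -0.9154
#> 6   S06       1.1141  58.990  0.57398  0.9549
#> 7   S07       1.2164 199.155 -1.14907 -0.3991
#> 8   S08       1.3172 340.379  1.24074 -0.4423
```

The grid line reports the Cz equidistance residuals (both ≤ 1 mm, the
convergence contract) and the four circumference quadrant arc lengths in mm.
Each channel row gives its eccentricity (1.0 = on the head circumference;
S06–S08 sit below it, hence > 1), its angle in the nose-up frame, and the
Cartesian layout position `x = e·cos θ`, `y = e·sin θ`. Re-running
`make_layout` on any subset of these sensors reproduces the same rows
bit-for-bit — the property the polar baseline lacks.

A command-line interface covers the same pipeline file-in/file-out:

```sh
SL=$(Rscript -e 'cat(system.file("scripts/scalplayout", package="scalplayout"))')
Rscript $SL simulate --out-dir demo --n-sensors 40 --seed 1
Rscript $SL layout --headshape demo/headshape.tsv --fiducials demo/fiducials.json \
                   --sensors demo/sensors.tsv --out demo/array.lay
Rscript $SL plot --layout demo/array.lay --out demo/array.png
```

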