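---
title: "Measuring navigation system accuracy with a simulated wire-cross phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring navigation system accuracy with a simulated wire-cross phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usnav)
```

## The problem

In image-guided therapy (IGT) a tracked instrument is displayed inside a
patient model built from medical images. The clinically decisive question is
how far the displayed tool position can be from the true physical position
relative to the anatomy — the *navigation system accuracy* (NSA). For
navigation based on intraoperative ultrasound the dominant error source is
the spatial calibration of the ultrasound probe (the rigid transform from
the image plane to the tracking sensor), followed by tool tracking and
display interpolation; in a clinical setting, sound-speed deviations and
anatomical shift add further, much larger terms.

`usnav` implements the computational chain needed to measure NSA with a
wire-cross phantom: rigid-transform bookkeeping and pose interpolation,
freehand 3D ultrasound reconstruction, segmentation and centerline
extraction, rigid registration (landmark least squares, a fast one-landmark
method, centerline ICP, and a trajectory-to-airway variant), the
displacement-based NSA statistic, and a root-sum-of-squares error budget.
Because the physical phantom, scanner and tracker are hardware, the package
also ships a seeded simulator that renders tracked sweeps over a virtual
wire cross with *injectable* errors, so the whole pipeline can be exercised
and validated on a desk.

## The accuracy method

The automatic accuracy measurement runs in five steps:

1. a tracked sweep of the ultrasound probe over a single wire cross in a
   water tank;
2. reconstruction of the 2D frames into a 3D volume (`reconstruct_pnn()`);
3. segmentation of the wire cross from the volume (`segment_wires()`);
4. extraction of the centerline of the segmented cross
   (`extract_centerline()`);
5. registration of the extracted centerlines onto a centerline model of the
   accurately known physical cross with a modified ICP
   (`compute_nsa()`).

The displacement that this registration imposes, evaluated **at the nominal
cross point**, is the NSA. Evaluating at the cross point rather than taking
the ICP translation component alone was a deliberate choice: if the
registration contains a rotational part, its effect at the location where
accuracy matters is captured; for a pure translation the two definitions
coincide. The displacement is also decomposed in the scan-plane frame
(`decompose_nsa()`): elevation (plane normal), azimuth (lateral in-plane)
and radial (depth), which is the natural frame for diagnosing calibration
errors.

Independent error sources combine stochastically, not additively:
\(E = \sqrt{\sum_i e_i^2}\) (`rss_error_budget()`). With the laboratory
chain (probe calibration 1.0 mm, tool tracking 0.5 mm, slice interpolation
0.1 mm) this gives 1.1 mm at one decimal; adding worst-case clinical terms
(sound speed 2.0 mm, anatomical shift 10.0 mm) gives 10.3 mm, and 1.1 mm at
their best case — reported with round-half-away-from-zero at one decimal.

## Models and conventions

* **Rigid transforms.** All lengths are mm, times ms, frames right handed.
  Transforms carry *checked* frame labels; composing across mismatched
  frames raises an error rather than a warning, because silently composing
  the wrong calibration chain is the classic failure mode of navigation
  software. Rotations are re-projected onto the rotation group by polar
  decomposition after long composition chains (more than 10 links) to bound
  floating-point drift.
* **Pose interpolation.** Translation is interpolated linearly and rotation
  by shortest-arc quaternion slerp (antipodal quaternions are sign-fixed).
  Queries outside the stream range are errors — poses are never
  extrapolated, and frames whose (temporally calibrated) timestamp leaves
  the pose stream are dropped with a logged count.
* **Image plane frame.** x = elevation (plane normal), y = azimuth
  (lateral), z = radial (depth). A pixel `(row, col)` maps to
  `(0, (col - origin_px[2]) * sp_col, (row - origin_px[1]) * sp_row)`; the
  sector mask clips pixels outside the lateral/angular half-width or depth
  range.
* **Reconstruction.** Pixel-nearest-neighbour (PNN) forward mapping with
  *averaging* compounding. Averaging (rather than last-write-wins) was
  chosen so the result is independent of frame order, which in turn makes
  the pipeline deterministic under re-ordering and testable. Holes —
  unfilled voxels with at least one filled neighbour within
  `hole_fill_radius` voxels (default 1, spherical neighbourhood, single
  pass) — are filled with the mean of their filled neighbours. The default
  output spacing is the largest in-plane pixel spacing, which avoids
  systematic aliasing holes. No sound-speed correction is applied in
  reconstruction; a sound-speed scale exists only in the simulator as an
  error source.
* **Segmentation and centerlines.** The wire cross is segmented at a
  threshold of 0.5 × the maximum originally-filled intensity (the source
  method does not publish its rule; 0.5 is a robust default for a bright
  wire against water) and reduced to the largest 26-connected component.
  Hole-filled voxels may join the segmentation, but the threshold reference
  uses only voxels that received data directly. Centerlines come from
  sequential 3D topological thinning: border voxels are deleted in six
  directional subiterations when they are *simple points* (deletion
  preserves both object and background topology) and not curve endpoints,
  leaving a unit-width skeleton that is traced into polylines split at
  branch points.
* **ICP.** Correspondences are point-to-*segment* (orthogonal projection
  onto the fixed polyline), so residuals do not depend on how finely the
  fixed line is sampled. Defaults: at most 100 iterations, stop when the
  rms change falls below 1e-6 mm. The "modified" ICP used for the NSA adds
  worst-10% correspondence trimming, which guards the fit against spurious
  skeleton branches; the original modification is not published in detail,
  so trimming is this package's documented interpretation. The residual
  sequence is kept non-increasing by construction (an uphill step — possible
  with trimming or gating — reverts and stops). The trajectory-to-airway
  variant adds an orientation gate: a candidate correspondence is rejected
  when the angle between the tip's pointing axis (sensor +z) and the local
  centerline running direction exceeds `max_angle_deg` (default 60°); the
  published method states that orientation is used but not how, so the gate
  formulation is likewise this package's interpretation.
* **Fast registration.** The minimal rotation carrying the reference axis
  onto the tool axis plus an exact landmark match; for anti-parallel axes
  the 180° rotation axis is chosen deterministically (the coordinate axis
  most perpendicular to the reference axis). Documented as rough — it is an
  initialiser, not an accuracy method.

## What the simulator emulates — and what it does not

`simulate_sweep()` renders a linear-array sweep over a 1-mm wire cross:
40 mm arms crossing at 90° centred 42 mm below the probe face in a water
tank, a 128 × 120 pixel raster at 0.2 mm/px imaging 30–55.4 mm depth, a
16 mm sweep (96 frames at 20 fps) either *along* one wire or *diagonal* to
the cross, in both sweep senses — the 3-repeats × 4-conditions design of the
physical study, with one seed per acquisition
(`standard_acquisition_specs()`). These sizes keep a 0.2 mm-voxel
reconstruction at roughly 100 × 130 × 140 voxels, small enough that the
full 12-acquisition design runs in a couple of minutes on one CPU.

The image formation model is deliberately geometric, not physical: wire
echo = 200 × a Gaussian cross-section profile (σ = wire radius in-plane,
σ = half the 1 mm elevation beam width out-of-plane) over a water background
of 5, plus seeded Gaussian noise (SD 2) — no speckle statistics, no
attenuation, no beam forming. Error injection covers the terms of the error
budget that are geometric: a calibration offset composed onto the true
image-to-sensor transform (the consumer of the acquisition sees only the
perturbed calibration — exactly the deception that creates NSA error in
practice), white per-sample tracking jitter, an apparent-depth scale for
sound-speed error, and a reporting latency between motion and poses.

Passing tests on this simulator therefore show that the *geometric pipeline*
is correct — that injected millimetre-scale errors are recovered as
millimetre-scale NSA in the right direction — not that the package
reproduces any particular hardware measurement. The physical study's
measured values (for example a mean NSA of about 1 mm over 12 acquisitions)
depend on a specific tracker, scanner and phantom and are out of reach of
simulation by design; the corresponding package-level checks are the
end-to-end *null test* (zero injection must give NSA below one voxel
diagonal, ≤ 0.35 mm at 0.2 mm spacing) and *parameter recovery* (injected
0.5–2.0 mm calibration translations recovered with mean absolute error
≤ 0.3 mm, elevation-dominant decomposition for elevation-axis offsets).

## Numerical choices and degenerate inputs

* Landmark registration uses the SVD (Arun-style) closed form with a
  determinant guard, so reflections are never returned even for
  near-mirrored data; fewer than three common names or collinear points are
  classed errors.
* The nominal cross centerline is sampled at 0.1 mm — below any tested
  voxel spacing, so sampling never limits registration accuracy.
* Orthonormality tolerances: constructors accept rotations within 1e-6 of
  orthonormal and re-project anything drifted beyond 1e-12.
* Volumes are axis-aligned with the reference frame (voxel-centre
  convention, origin = centre of voxel (1,1,1)); oblique output volumes are
  out of scope.
* MetaImage I/O is restricted to uncompressed little-endian 3D MET_UCHAR /
  MET_FLOAT with explicit size checking; pose CSV quaternions are
  normalised on read and rejected beyond a 1e-3 norm deviation, with the
  offending row named.

## Known limitations

* The thinning skeleton is voxel-resolution limited; sub-voxel centerline
  refinement (e.g. intensity-weighted) is not implemented, which contributes
  a fraction of a voxel to the null-test NSA.
* The simulator's wires are straight and its trajectories linear; curved
  phantoms, occlusion dropouts (beyond MISSING pose rows) and real speckle
  are not modelled.
* Only rigid registration is provided; deformable/brain-shift correction is
  out of scope, as are GPU reconstruction, DICOM/vtk/stl import and any
  real-time streaming.
* The command-line `register` subcommand covers landmark registration;
  external image-to-image tools can be scripted around the documented
  transform-file format (4 × 4 row-major text), which is the package's
  subprocess contract.
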