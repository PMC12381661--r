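---
title: "Rootlet-based registration: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rootlet-based registration: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rootletreg)
```

## The problem and the model

Template-based analyses of cervical spinal cord MRI need a map from each
subject's anatomy to a common straightened space. The conventional map is
driven by intervertebral discs, i.e. by vertebral levels; but the
functionally meaningful segmentation of the cord is into *spinal* levels,
defined by the entry zones of the nerve rootlets, and the two ladders of
levels slide relative to one another across individuals and with neck
flexion/extension — increasingly so toward C8. `rootletreg` registers on
the rootlets directly.

The pipeline's currency is the displacement field: a per-voxel 3-vector
of world-mm offsets on a stated reference grid, applied by pull-back (the
warped image at grid point $p$ samples the input at $p + v(p)$). All
volumes are reoriented at load so axes run left–right,
posterior–anterior, inferior–superior; the rostro-caudal axis is always
the third array dimension, and "more caudal" always means "smaller z".

Seven stages produce the final warps:

1. *Per-level landmarks.* Unweighted centers of mass of each rootlet
   label (2–8 = C2–C8), subject and template. Level z must strictly
   decrease with level code; violations signal a corrupt segmentation and
   are refused rather than repaired.
2. *Straightening.* The centerline is the per-slice center of mass of
   the cord mask, interpolated across empty slices, fitted by a cubic
   smoothing spline in x(z) and y(z). Slices are weighted by their voxel
   count so partial end-cap slices — whose centers are biased wherever
   the cord meets the field of view obliquely — cannot bend the fit. The
   straightened space is parameterized by arc length; each output slice
   samples the plane orthogonal to the tangent, with in-plane axes
   carried by minimal-rotation (parallel transport) frames to avoid
   in-plane spinning. Arc length along the cord is preserved by
   construction, and the map anchors arc length 0 at the caudal end of
   the segmentation so an already-straight, centered cord maps to itself.
3. *Level alignment.* A monotone 1D map sends template-space level z's
   to subject (straightened) level z's, interpolated between landmarks by
   a shape-preserving monotone cubic (Fritsch–Carlson) and extended with
   a constant shift beyond C2 and C8. Monotonicity forbids fold-over by
   construction; the constant extension avoids runaway deformation above
   C2 / below C8, where no landmark constrains the map. Subject landmark
   centers are carried into straightened space geometrically (foot-point
   projection onto the centerline), not by resampling the label volume,
   so single-voxel landmarks cannot vanish under nearest-neighbour
   regridding.
4. *Rostro-caudal refinement.* Both images are masked by their rootlet
   segmentations dilated by 3 voxels (6-connected), and a z-only
   displacement profile — a 1D cubic B-spline shared across the axial
   plane — maximizes masked normalized cross-correlation over a
   coarse-to-fine pyramid along z (shrink 4×, 2×, 1×), by gradient ascent
   with a monotone backtracking line search. The displacement is capped
   at 10 mm. A symmetric-normalization B-spline engine constrained to z
   and then averaged slice-wise (stage 5) has the same expressive power
   as this single shared profile, which is why the simpler transform is
   used; the in-plane variation the engine could have produced is
   deliberately left to the symmetrization.
5. *Symmetrization.* The refinement field's z-component is replaced, per
   axial slice, by the mean of its non-zero values (|dz| > 1e-9 mm),
   broadcast across the entire slice. Broadcasting (rather than writing
   the mean only where the field was non-zero) yields an exactly
   left–right-symmetric, per-slice-constant field; the operation is
   idempotent, and the mean is computed over sorted values so it is
   bit-identical under left–right grid flips.
6. *Axial scaling.* Cord calibre is matched to the template by per-slice
   isotropic scaling $s(z) = \sqrt{A_{tpl}(z) / A_{sub}(z)}$ about the
   template cord center, median-filtered along z with a 5-slice window
   and clamped to (0.2, 5). Isotropic area-ratio scaling is the minimal
   transform that adjusts cord size; anything shape-aware (gray/white
   matter) is out of scope. The step is skipped for morphometric
   analyses (`no_xy_scaling = TRUE`) so native cord morphology survives
   into template space.
7. *Concatenation.* Pull-back composition
   $w_{12}(p) = w_1(p + w_2(p)) + w_2(p)$ folds the four fields into one
   forward warp. The backward warp composes the geometric unstraightening
   map (computed by foot-point projection on the native grid, not by
   numeric inversion — straightening displacements can exceed the basin
   of a fixed-point solver) with fixed-point inverses of the small z-only
   fields (50 iterations, 0.05 mm tolerance).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `straighten_smoothing` | 1e-4 | spline penalty | sub-voxel fidelity; large values (≈10) recover straight lines from voxel-quantized centers |
| `straighten.pad_mm` | 10 | mm | grid margin beyond the segmented cord |
| `zreg$spacing_mm` | 10 | mm | B-spline control spacing; smooth at level scale (13–15 mm gaps) |
| `zreg$pyramid` | 4, 2, 1 | shrink | capture multi-mm offsets before refining |
| `zreg$metric` | NCC | — | robust to the phantom's (and MRI's) intensity scaling |
| `zreg$iterations` | 50 | steps/level | convergence with margin at these problem sizes |
| `zreg$cap_mm` | 10 | mm | hard bound; about two-thirds of a cervical level |
| `zreg$dilation` | 3 | voxels | the masking radius around the rootlets |
| `normalize_csa` window | 20 | slices | calibre normalization just above the enlargement |
| `smooth_and_localize` window | 22.5 | mm | enlargement localization scale |

## What the phantom emulates — and what it does not

`phantom_spec()` describes a 0.8 mm isotropic acquisition covering
~154 mm of cervical spine: a cord of 4 mm baseline radius with a 1 mm
Gaussian bulge (σ = 10 mm) centered at z = 75 mm, between the C5 and C6
spinal levels; paired dorsal rootlet blobs at anatomically spaced level
positions (C2 at 132 mm down to C8 at 47 mm, labels 2–8); single-voxel
disc labels offset caudally from the corresponding spinal levels; and a
T2w-like intensity image (bright CSF, intermediate cord, hypointense
rootlets) smoothed at voxel scale with seeded Gaussian noise (SD 2 at a
background/CSF contrast of 80). Neck positions map to curvature modes:
neutral is straight; flexion and extension bow the cord sagittally with
opposite signs (8 mm amplitude) while the cord — rootlets and enlargement
with it — slides 3 mm rostrally or caudally along the canal relative to
the fixed disc positions.

`generate_cohort()` adds per-level Gaussian jitter to the rootlet
positions (SD 2 mm at C2, scaled linearly to ×2 at C8, mirroring the
caudally growing spinal-vs-vertebral discrepancy) and gives each
subject's discs a constant offset (SD 4 mm) that decouples vertebral from
spinal landmarks — the anatomy that makes disc-driven registration
misplace spinal levels. Each subject's enlargement moves with the mean of
its C5/C6 jitter, since the enlargement belongs to those spinal levels.
Jitter draws that would disorder the levels or merge adjacent rootlet
blobs are redrawn (up to 10 times), which truncates the extreme tail of
the jitter distribution slightly.

The phantom is a geometric object, not an MR simulation: no bias fields,
no CSF pulsation or motion artifacts, no partial-volume modeling beyond
grid sampling, rootlets as compact blobs rather than branching fiber
bundles, and an idealized always-complete segmentation. Passing tests
therefore demonstrate the *registration machinery* — landmark recovery,
warp estimation and algebra, metric behavior — under known ground truth;
they do not certify segmentation robustness or contrast-dependent
behavior on clinical data.

## Numerical choices

- Label volumes are resampled with nearest-neighbour only (linear
  interpolation on labels is refused); images use trilinear
  interpolation; samples beyond the input grid are 0, while
  *field* lookups clamp to the edge so z-only fields extend as constants.
- Displacement fields are stored as 4D NIfTI (three world-mm components
  in the 4th dimension, float64 for bit-exact round trips) with a JSON
  sidecar naming direction (forward = template grid, offsets toward
  subject space), reference grid, and units. The host tools' 5D dialect
  is deliberately not reproduced; the container here is the simplest
  standard-compliant one.
- The overlap percentage normalizes by the template level's slice count
  (100% = the subject covers the template level exactly); a 1D Dice
  variant is reported alongside because both extents are informative.
  Group summaries use the population SD (divide by n).
- The moving-average smoother reflects at the profile boundaries;
  argmax ties break toward the more rostral slice.
- The enlargement localization window (22.5 mm) is applied to the
  *normalized* profile when present, raw CSA otherwise.
- Tests compare the one-shot concatenated warp against sequential stage
  application by transporting rootlet *center points* through each field
  (fixed-point solves), since rasterizing a label volume four times in
  the reference path adds nearest-neighbour shot noise of up to a voxel
  that says nothing about the composition itself.

## Problem sizes

The test suite and acceptance checks run the default study conditions —
48×48×192 voxels at 0.8 mm, 7 levels — for template self-registration,
20 seeded smooth-warp recoveries, a 10-subject decoupled cohort
registered with both landmark modes, and one subject in three neck
positions; unit tests use a 36×36×120 phantom at 1 mm with the same
anatomy. These sizes keep each full registration in tens of seconds on a
single core while leaving every level and stage non-degenerate.

## Known limitations

- The disc baseline shares the full downstream machinery, including the
  rootlet-masked refinement, so it is a *stronger* comparator than a
  traditional disc-only pipeline: the refinement partially rescues
  disc-induced misalignment when the offset is within its capture range.
  Head-to-head differences on the phantom are therefore compressed
  relative to what fully independent pipelines would show.
- Straightening assumes gentle curvature (tangents within ~45° of the
  grid axis); extreme kyphotic geometries would need a denser
  arc-length parameterization and a true 3D centerline fit.
- The 1D level alignment and the z-only refinement cannot express
  level-dependent in-plane deformation; in-plane correction is limited
  to the isotropic per-slice scaling of stage 6.
- Only 3D volumes are handled; 4D time-series and DICOM inputs are out
  of scope, as are segmentation models and vertebral labeling.
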