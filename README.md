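# rootletreg

Spatial normalization of cervical spinal cord MRI usually aligns subjects
to a straightened template via intervertebral discs. But spinal levels —
defined neuroanatomically by where nerve rootlets enter the cord — do not
sit at fixed positions relative to the vertebrae: the correspondence
varies substantially across individuals and with neck position,
especially at caudal levels. Group analyses that care about *spinal*
levels (spinal cord fMRI above all) therefore misalign when they register
on bony landmarks.

`rootletreg` implements rootlet-based template registration for R: it
takes a subject T2w volume, a binary cord segmentation and a level-labeled
dorsal-rootlet segmentation (labels 2–8 = C2–C8), and registers the
subject to a straightened template by aligning the rootlet levels
themselves. It also ships the disc-landmark baseline (same machinery,
disc point labels), the validation metrics used to compare the two, and a
synthetic cervical-cord phantom generator with known ground truth so the
entire pipeline is testable without any imaging data.

## Method

Registration runs in seven steps, all expressed as world-mm displacement
fields under pull-back resampling:

1. **Level landmarks** — per-level center of mass of the rootlet
   segmentation, subject and template.
2. **Straightening** — the cord centerline (count-weighted smoothing
   spline through per-slice mask centers) parameterizes a straightened
   space by arc length; each output slice samples the plane orthogonal to
   the centerline tangent, with minimal-rotation frame transport.
3. **Level alignment** — a monotone 1D map (shape-preserving cubic
   through matched landmark z's, constant shift beyond the outermost
   levels) sends subject level positions to the template's, as a z-only
   displacement field.
4. **Rostro-caudal refinement** — both images are masked by their rootlet
   segmentations dilated by 3 voxels, and a 1D cubic B-spline
   displacement profile dz(z) (control points every 10 mm, |dz| ≤ 10 mm)
   maximizes normalized cross-correlation over a coarse-to-fine z-pyramid
   with a monotone line search.
5. **Symmetrization** — the refinement field is averaged slice-wise
   (zeros excluded) and broadcast across each axial slice, making it
   exactly left–right symmetric.
6. **Axial scaling** — per-slice isotropic in-plane scaling
   s(z) = sqrt(area_template / area_subject) about the template cord
   center (median-filtered along z) matches the cord calibre to the
   template. Skippable (`no_xy_scaling`) for morphometry.
7. **Concatenation** — all fields compose into one forward
   (subject-to-template) warp; the backward warp combines the geometric
   unstraightening map with fixed-point inverses of the z-only fields.

Validation metrics: per-level rostro-caudal overlap with the template
rootlets (percent of the template level's slice extent, plus a 1D Dice
variant), and slice-wise cross-sectional area (CSA) profiles — normalized
over 20 slices at the C2–C3 disc, smoothed with a 22.5 mm moving average —
whose maximum localizes the cervical enlargement.

## Worked example

Generate a synthetic subject whose spinal levels are jittered away from
the template's (and whose discs are decoupled from its rootlets), then
register it:

```r
library(rootletreg)
co  <- generate_cohort(1, seed = 42)
s   <- co$subjects[[1]]
reg <- register_to_template(s$image, s$cord, s$rootlets, co$template,
                            compute_inverse = FALSE)
reg
#> <rootlet_registration> landmarks=rootlets
#>   forward warp |v|: mean 2.901 mm, max 6.857 mm
#>   level residuals (mm): C2 -0.27, C3 +0.30, C4 -0.16, C5 +0.21,
#>   C6 -0.33, C7 -0.88, C8 +1.12

rootlet_overlap(reg$warped_rootlets, co$template$rootlets)
#> Per-level rostro-caudal overlap with template rootlets
#>  level length_overlap length_pam50 length_sub percent dice1d missing_in_subject
#>      2              7            7          8   100.0  93.33              FALSE
#>      3              7            7          8   100.0  93.33              FALSE
#>      4              8            8          8   100.0 100.00              FALSE
#>      5              7            7          7   100.0 100.00              FALSE
#>      6              7            8          7    87.5  93.33              FALSE
#>      7              7            7         10   100.0  82.35              FALSE
#>      8              7            7         13   100.0  70.00              FALSE
#> mean 98.21%, SD 4.37% (population)
```

The forward warp absorbs the simulated level jitter (up to ~7 mm at
caudal levels); residuals of the warped rootlet centers stay near or
below one voxel, and the warped rootlets overlap the template's at
98% of the template slice extents on average.

A command-line wrapper with `register`, `metrics` and `phantom`
subcommands is installed under `inst/cli/rootletreg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rootletreg.R", package="rootletreg"))')" \
  phantom generate --seed 7 --out-dir phantom/
```

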