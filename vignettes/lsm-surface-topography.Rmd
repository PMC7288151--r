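---
title: "Surface topography from light-sheet laser triangulation: models and methods"
author: "lsmtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface topography from light-sheet laser triangulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmtopo)
```

## The measurement principle

A light-sheet profilometer illuminates an opaque surface with a thin laser
sheet and images the scattered light with a camera placed off the
illumination axis. The sheet appears as a bright, roughly vertical stripe;
where the surface is higher or lower than the flat reference plane, the
stripe shifts sideways on the sensor. Scanning the sample under the sheet
and recording one frame per stage step turns the per-frame stripe contour
into a full heightmap `z(x, y)`: `x` from the stage position, `y` from the
image row, `z` from the stripe's lateral displacement.

`lsmtopo` implements the computational chain of such an instrument:
triangulation geometry, speckle-robust stripe extraction, empirical
calibration, 3D reconstruction and metrology (step heights, groove depths,
curvature), plus a synthetic frame renderer so that every stage can be
validated without hardware.

## Triangulation geometry

With illumination at angle `alpha` to the surface normal, viewing at `beta`
on the other side, a camera tilted at `theta` to the viewing axis, a thin
imaging lens of focal length `f` at object distance `l` (image distance `d`
from `1/l + 1/d = 1/f`), a height offset `dz` maps to a camera-plane
displacement `dx` through

```
dz = dx sin(theta) cos(alpha) (l - f) /
     [ f sin(alpha + beta) ± dx sin(alpha + beta + theta) (1 - f/l) ]
```

(`delta_z_general()`). The sign in the denominator depends on whether the
surface lies above (`+`) or below (`-`) the reference plane; the package
makes this an explicit argument, since the displacement magnitude cannot
decide it. The mapping is validated in the test suite against an
independent thin-lens chief-ray construction: place the surface point,
trace the chief ray through the lens centre, image it, and intersect with
the tilted camera plane. Agreement is to machine precision over randomized
valid geometries.

In the orthogonal configuration (`alpha = beta = 45`, `theta = 90`) the
correction term vanishes (`sin 180 = 0`) and the mapping is exactly linear
(`delta_z_linear()`):

```
dz = dx cos(45) / sin(90) * (l - f) / f = dx (l - f) / (sqrt(2) f)
```

**A note on the linear constant.** The slope of this shortcut is sometimes
quoted as `(l - f) / (2 f)`. That is not the reduction of the oblique
formula: at 45 degree incidence, a height change `dz` moves the illuminated
spot by `dz` laterally *and* `dz` vertically, i.e. by `sqrt(2) dz`
perpendicular to the viewing axis, giving the `sqrt(2)` denominator. The
package uses the ray-trace-verified constant so that the general and linear
forms agree identically; the discrepancy is immaterial in practice because
quantitative work goes through the empirical calibration below, which
absorbs the true optical magnification. Consistently, typical instruments
of this class (a 4x objective with a 50 mm tube lens, i.e. magnification
near 1.1, and ~5.9 um pixels) measure calibration slopes that match the
`sqrt(2)` form and not the `1/2` form.

## Contour extraction

Laser speckle is the dominant noise source. Extraction runs in two steps:

1. **Guided-filter smoothing** (`smooth_image()`): a self-guided
   edge-preserving filter with window radius 4 px. The regularization
   default is `(0.2 * dynamic range)^2`. This is deliberately much larger
   than the `(0.01 * range)^2` default of general-purpose implementations:
   multiplicative speckle of contrast `c` has local variance
   `(c * intensity)^2`, which at a bright stripe crest is of order
   `(0.125 * range)^2` — a small regularization classifies the speckle
   itself as edges and passes it through. At the default, measured per-row
   peak-position variance drops by 10-50% with no added bias, while the
   stripe-background transition (local variance near `(0.4 * range)^2`)
   is preserved.
2. **Per-row brightest column** (`extract_contour()`): for every image row
   the position is the column of the maximum intensity; ties — common at
   limited bit depth where the stripe crest saturates the quantization —
   are resolved by averaging all tied columns, so positions may be
   fractional. Rows whose maximum falls below 5% of the dynamic range carry
   no sheet and are flagged invalid. Columns are 1-based.

Signed offsets against a reference column (`contour_offsets()`) follow the
convexity convention: rightward = above the reference plane. The reference
column defaults to the median stripe position of a designated flat frame.

Lateral resolution is estimated from a line target via the full width at
half maximum of its intensity peaks (`estimate_fwhm()`), with linear
interpolation between samples.

## Calibration

The instrument protocol raises a flat surface in fixed increments (default
301 frames at 2.5 um, spanning 750 um) and records the stripe column of
each frame. `calibrate_stack()` summarizes each frame by the median stripe
position over valid rows (robust to residual speckle; the mean is
available), subtracts the first frame, and fits

```
dn = c0 + c1 dz + ... + c5 dz^5
```

by least squares (`build_calibration()`, degree configurable, default 5;
degree 1 for the strictly linear regime). `c1` (pixels per micrometre) is
the physically meaningful slope; the higher orders absorb residual
distortion and are small next to the linear term. Goodness of fit is the
coefficient of determination `1 - SS_res / SS_tot`.

Two practical caveats, both encoded in the package:

* **A high-degree polynomial needs leverage.** Fitted on a short height
  range, the degree-5 `c1` is poorly constrained even when the curve fits
  the data well; the full-range protocol (hundreds of points over hundreds
  of micrometres) pins it to well under 1%.
* **Inversion** (`invert_offset()`) is by bracketed root-finding (absolute
  tolerance 1e-6 um) on the fitted polynomial, restricted to its largest
  increasing subinterval if the fit is non-monotone (a warning is raised).
  During reconstruction the inversion may extrapolate slightly beyond the
  calibrated range (default allowance 5% of the range): measurement noise
  scatters offsets symmetrically around the reference, and a hard floor at
  zero would rectify that noise into a positive bias on flat regions —
  about half a pixel quantum, which is significant against a 10 um step.

The guaranteed height resolution of the protocol is
`z_resolution_bound(step, k)`: if `k` increments always move the stripe by
at least one pixel, the resolution is at most `k * step` (10 um for 2.5 um
steps with `k = 4`).

## Reconstruction and metrology

`stack_to_pointcloud()` converts frame `k`, row `i` into
`x = (k-1) * scan_step`, `y = (i-1) * lateral_scale`,
`z = invert_offset(dn(i, k))`. The lateral scale (micrometres per image
row) is a required configuration input — it bundles objective magnification
and pixel pitch and is best measured from a ruled target. Scan direction is
`+x` with frame 1 at `x = 0`.

`grid_surface()` interpolates the scattered points onto a regular grid by
Delaunay triangulation with barycentric (linear) interpolation, which
reproduces the data at the data points, is exact for planes, and masks
cells outside the convex hull.

**Step heights** (`measure_step_height()`) are differences of summarized
heights over two rectangular regions. The default summary is a 10%-trimmed
mean, not the median: extracted positions are quantized to whole pixels
(~3.4 um of height at a 0.29 px/um slope), and the median of quantized
heights snaps to the pixel grid — a bias of up to half a quantum, 17% of a
10 um gauge. Speckle jitter acts as natural dither that the mean exploits
(measured plateau means are within ~0.1 px of truth where medians are off
by up to 0.4 px); trimming retains robustness to extraction outliers.

**Groove depths** (`measure_groove_depth()`) follow the per-frame indenture
protocol: in each frame take the extremal signed offset against the flat
reference line within a row window, average over frames, round to the
nearest whole pixel (instrument reports quote integer offsets; disable
with `round_offset = FALSE`), and convert the magnitude through the inverse
calibration. The rounding quantizes reported depths to the pixel quantum —
with a 0.29 px/um slope, to about 3.4 um.

**Curvature** (`select_arc()`, `fit_circle()`, `curvature_of()`): a
manually selected row range of a contour is mapped into physical `(y, z)`
micrometres using the lateral scale and the inverse calibration, and a
circle is fitted in two stages — an algebraic (Kasa) linear least-squares
stage, which is deterministic and needs no starting point, followed by
geometric refinement minimizing the sum of squared radial residuals (for a
fixed centre the optimal radius is the mean distance). The geometric result
is reported; curvature is `1/R` per millimetre. Arc selection is manual by
design: automatic segmentation of the curved section is out of scope.

## The synthetic scene renderer

`scene_spec()` / `render_frame()` implement the forward model the rest of
the package inverts: per row, a Gaussian stripe cross-section (default
sigma 6 px, consistent with a ~50 um sheet imaged at the default slope)
centred at `reference_column + pixels_per_um * z(x, y)`, on a constant
background, multiplied by clipped multiplicative Gaussian speckle
(`max(0, 1 + contrast * N(0,1))`, default contrast 0.15) and quantized to
the camera bit depth (default 12). The default forward height-to-pixel map
is linear at 0.29 px/um, a typical slope for this instrument class; frames
default to 1280 x 1936 and are rendered smaller in tests. Rendering is
deterministic given the scene seed and frame index, and leaves the global
RNG state untouched.

`preset_scene()` provides the validation targets: a flat plane; a stair of
stacked 10 and 20 um gauges (plateaus 0/10/30 um); a 70 um plateau cut by
three 180 um wide flat-bottomed grooves (gate-line style); a cylinder-edge
cap of radius 2605 um; and a 140 um hair-like cylinder resting on the
plane. Groove width is an absolute 90 um half-width rather than a fraction
of the field of view, so grooves remain physically plausible (and wider
than the smoothing window) at reduced test sizes.

**What the renderer does not emulate** — and therefore what passing tests
do not establish about real data: physically coherent speckle statistics
(the model is uncorrelated multiplicative Gaussian, real speckle is
correlated and non-Gaussian), defocus and sheet divergence away from the
focal plane, occlusion and shadowing at steep walls, secondary reflections,
and reflectance variation across the sample. Results on real stacks depend
on those effects; the synthetic results bound the algorithmic, not the
physical, error.

## Numerical and design choices

* Angles are accepted in degrees (instrument convention) and converted
  internally; all lengths are micrometres internally, with `f` and `l`
  accepted in millimetres.
* The sign branch of the oblique formula is an explicit argument, never
  inferred.
* Root-finding tolerance 1e-9 um internally (contract 1e-6 um); round-trip
  `invert(predict(z)) = z` holds to 1e-5 um across the calibrated range.
* Smoothing correlates neighbouring rows (shared filter windows), so
  region statistics carry roughly one independent sample per filter
  diameter per frame; frames carry independent speckle. Validation runs
  size their regions accordingly.
* Default problem sizes in the test suite and acceptance script are
  reduced frames (320 x 512 and smaller) with the full-length calibration
  protocol (301 frames) and a 100-frame scan — the full pipeline at sensor
  resolution behaves identically, only slower.
* Frame order for directory input is the manifest CSV when present, else
  lexicographic; all intermediate artifacts are plain formats (TIFF, CSV,
  JSON, XYZ, PLY). Heightmap TIFFs store samples normalized to the height
  range with the affine micrometre scale in a JSON sidecar (the TIFF
  writer used stores [0,1] samples); the CSV output carries exact
  micrometres.

## Known limitations

* Sub-pixel peak localization (e.g. Gaussian regression per row) is not
  implemented; the per-row argmax with tie averaging keeps the pixel
  quantum as the elementary height resolution, mitigated by averaging.
* Multi-stripe frames, automatic arc/indenture segmentation, mesh export
  and hardware control are out of scope.
* The calibration is global (one polynomial for the whole field); no
  per-row calibration maps or drift compensation.
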