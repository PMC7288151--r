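# lsmtopo

Surface topography from light-sheet laser-triangulation image stacks.

A light-sheet profilometer illuminates an opaque sample with a thin laser
sheet and images the scattered light from an oblique angle. The sheet forms
a bright stripe on the camera, and local surface height shifts the stripe
laterally: with illumination at angle α to the surface normal, viewing at β,
camera tilt θ, and a thin imaging lens (focal length *f*, object distance
*l*), a height offset Δz maps to a camera-plane displacement Δx as

    Δz = Δx sinθ cosα (l − f) / [ f sin(α+β) ± Δx sin(α+β+θ)(1 − f/l) ]

with the sign set by whether the surface lies above or below the reference
plane. In the orthogonal configuration (α = β = 45°, θ = 90°) this becomes
exactly linear, Δz = Δx·(l−f)/(√2 f), and in practice the mapping is
calibrated empirically: a flat surface is raised in known increments and a
polynomial Δn(Δz) = c₀ + c₁Δz + … + c₅Δz⁵ is fitted to the stripe's pixel
offset Δn, then inverted by root-finding during reconstruction. Scanning
the stage and stitching per-frame stripe contours yields a gridded
heightmap z(x, y) from which step heights, groove depths and curvature
(via least-squares circle fits) are measured.

The package is aimed at people building or analyzing line-scan / laser
triangulation profilometry systems: it implements the full computational
chain (geometry, speckle-robust contour extraction with guided-filter
smoothing, calibration with monotone inversion, point-cloud and heightmap
reconstruction, metrology, circle-fit curvature) together with a synthetic
light-sheet renderer so the pipeline can be validated end-to-end without an
instrument.

## Worked example

Simulate the classic stacked-gauge target (10 µm and 20 µm shims in a
stair), calibrate from a rendered flat stack, reconstruct, and measure both
step heights:

```r
library(lsmtopo)

# scene with ground-truth plateaus at 0 / 10 / 30 um
scene <- preset_scene("stair_10_20", extent_y_um = 160 * 5.58, seed = 42,
                      reference_column = 60)

# calibration protocol: flat surface raised in 151 steps of 5 um
cal_frames <- render_calibration_stack(scene, n_steps = 151, step_um = 5,
                                       image_shape = c(160, 320))
cal <- calibrate_stack(cal_frames, step_um = 5, degree = 5)
print(cal)
#> Light-sheet calibration: degree-5 polynomial dz (um) -> dn (px)
#>   coefficients (c0, c1, ...): -0.167, 0.2949, -3.621e-05, 1.117e-07, -1.526e-10, 7.631e-14
#>   linear slope c1 = 0.2949 px/um
#>   R-squared = 0.999976 on 151 points
#>   valid dz range: [0, 750] um

# 40-frame scan at 10 um steps -> point cloud -> gridded heightmap
stack <- render_scan_stack(scene, n_frames = 40, step_um = 10,
                           image_shape = c(160, 320), calibration = cal)
pc <- stack_to_pointcloud(stack)
surface <- grid_surface(pc, x_spacing_um = 10, y_spacing_um = 5.58)
print(surface)
#> lsm_heightmap: 40 x 160 cells (10 x 5.58 um), 100.0% valid
#>   z range: [-12.9768, 41.4456] um

b <- attr(scene, "ground_truth")$breaks_y_um
xr <- range(pc$x)
h10 <- measure_step_height(surface, c(xr, b[1] + 40, b[2] - 40),
                           c(xr, 0, b[1] - 40))
h20 <- measure_step_height(surface, c(xr, b[2] + 40, max(pc$y)),
                           c(xr, b[1] + 40, b[2] - 40))
sprintf("gauges: %.2f um (%.2f%%), %.2f um (%.2f%%)",
        h10, relative_error(h10, 10), h20, relative_error(h20, 20))
#> [1] "gauges: 9.51 um (4.93%), 19.79 um (1.03%)"
```

The fitted slope (0.2949 px/µm) recovers the renderer's programmed
0.29 px/µm within 2%, and both gauge heights come back within the
instrument class's typical worst-case error of 8%. The stripe positions are
quantized to whole pixels (≈3.4 µm of height per pixel at this slope), so
single-row heights carry that quantum; the region summaries average it
down with the speckle acting as dither.

A thin command-line wrapper over the same functions is installed at
`inst/cli/lsmtopo` (commands: `simulate`, `calibrate`, `extract`,
`reconstruct`, `measure-step`, `measure-groove`, `measure-curvature`), each
writing plain TIFF/CSV/JSON/XYZ/PLY artifacts plus a provenance log.

The methods vignette (`vignettes/lsm-surface-topography.Rmd`) documents the
models, the noise assumptions behind the synthetic renderer, and the
numerical choices.

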