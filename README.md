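# epidtrack

In-vivo quality assurance of marker-based **dynamic tumour tracking (DTT)**
radiotherapy from the portal images (EPID frames) a linac records during every
beam.

During gimbal-based DTT the MLC-shaped radiation aperture continuously follows
implanted gold fiducial markers through the respiratory cycle. How well it
follows them is exactly what the cine EPID sees: each frame shows both the
aperture and the dark marker shadows, so the residual targeting error can be
measured field by field, on the patient, with no extra imaging dose.
`epidtrack` implements that measurement chain:

1. **Aperture** — the in-field region is segmented at the 50% (half-maximum)
   edge convention and its boundary traced with a Moore-neighbour **Freeman
   chain-code** follower; the aperture centre is the area centroid of the
   enclosed region.
2. **Markers** — frames are filtered with a **Laplacian of Gaussian** (dark
   blobs of radius ≈ σ√2 give extremal responses), thresholded at a robust
   MAD-based level, and candidate blobs are labeled by **connected-neighbour**
   analysis, then filtered by size, elongation and distance from the field
   edge (default 1.24 mm). The marker surrogate position is the unweighted
   mean of the per-marker centroids (COM).
3. **Tracking error** — per frame, the pan/tilt offset of the marker COM
   relative to the aperture centre is converted to mm at the isocenter plane
   (1 px = 0.18 mm for the default geometry: SDD 221.2 cm, 1024², 2 Hz). The
   tracking error references the first usable frame of the series:

   E_T,pan(i) = |pan(i) − pan(baseline)|, likewise tilt, and
   E_T,2D(i) = √(E_T,pan² + E_T,tilt²).

4. **Statistics and margin** — per-field and per-patient mean / SD / 90th
   percentile / max; across patients the systematic error **Σ** (sample SD of
   the per-patient means) and random error **σ** (RMS of the per-patient SDs)
   feed the **Van Herk** planning-target-margin recipe

   margin = 2.5 Σ + 0.7 σ   (90% of patients, 95% CTV coverage).

A synthetic EPID phantom (`scene_config()` / `render_series()` /
`make_population()`) renders moving apertures, elliptical 3 mm × 1 mm marker
shadows, controllable residual tracking offsets, blur, noise and edge
occlusion — with exact ground truth — so the whole chain is testable without
clinical images.

## Worked example

```r
library(epidtrack)
set.seed(42)
geom <- geometry_config()                      # 1024 px, 0.18 mm/px, 2 Hz
# a 21-frame beam with a drifting residual tracking offset
drift <- cbind(rnorm(21, 0.4, 0.3), rnorm(21, 0.7, 0.3))
scene <- scene_config(tracking_offset = drift, noise_sd = 0.02, n_frames = 21)
series <- render_series(scene, geom)
series$metadata <- series_metadata("phantom", field_id = "B1", geometry = geom)

ts <- analyze_series(series)
#> Tracking series: 21 frames (21 analyzed), baseline frame #1
round(field_stats(ts)[, c("mean_pan_mm", "mean_tilt_mm", "mean_2d_mm",
                          "sd_2d_mm", "p90_2d_mm", "max_2d_mm")], 2)
#>   mean_pan_mm mean_tilt_mm mean_2d_mm sd_2d_mm p90_2d_mm max_2d_mm
#> 1        0.41         0.48       0.69     0.33      1.11      1.29
```

The per-field numbers are the baseline-referenced tracking errors in mm at
isocenter: this synthetic beam tracked its target to within 1.3 mm at worst,
0.69 mm on average (2D).

Population statistics and the margin contribution, using the bundled
eight-patient liver SBRT cohort summary:

```r
population_stats(liver_cohort_stats())
#> Population statistics over 8 patients:
#>   pan  Sigma = 0.08 mm, sigma = 0.42 mm, margin = 0.5 mm
#>   tilt Sigma = 0.19 mm, sigma = 0.73 mm, margin = 1.0 mm
#>   2d   Sigma = 0.20 mm, sigma = 0.79 mm, margin = 1.1 mm
```

So marker-based DTT contributes about **1.1 mm (2D)** to the PTV margin for
this cohort.

A thin command-line wrapper with `analyze`, `aggregate`, `margin` and
`simulate` subcommands lives at `inst/cli/epidtrack.R`.

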