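---
title: "Tracking-error QA for dynamic tumour tracking from portal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking-error QA for dynamic tumour tracking from portal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidtrack)
```

## The measurement

Gimbal-based dynamic tumour tracking (DTT) steers the MV beam so that the
MLC-defined aperture follows implanted gold fiducials through the breathing
cycle. The electronic portal imaging device (EPID) behind the patient records
cine frames of every beam, and each frame contains both sides of the tracking
loop: the aperture the machine actually delivered and the shadows of the
markers the machine was trying to follow. The residual displacement between
them, followed over the beam, is a direct in-vivo measurement of tracking
performance at zero extra dose.

`epidtrack` quantifies this as the **tracking error** E~T~. Per frame *i* of a
series, the pan (image-column) and tilt (image-row) offsets of the combined
marker centre-of-mass (COM) relative to the aperture centre are converted to
mm at the isocenter plane; the error is referenced to the series baseline
(the first frame with a usable detection, normally frame #1):

$$E_{T,\mathrm{pan}}(i) = |p(i) - p(b)|, \qquad
  E_{T,\mathrm{tilt}}(i) = |t(i) - t(b)|, \qquad
  E_{T,2D}(i) = \sqrt{E_{T,\mathrm{pan}}^2 + E_{T,\mathrm{tilt}}^2}.$$

Baseline referencing removes any constant aperture-to-COM calibration offset;
only the *variation* of the tracking loop is scored. The baseline frame's zero
error is a legitimate sample of the series and is retained in all statistics.
The 2D error is the Euclidean norm of the baseline-subtracted offset vector,
not the change of the scalar distance, so the per-frame triangle bounds
$E_{2D} \ge \max(E_\mathrm{pan}, E_\mathrm{tilt})$ and
$E_{2D} \le E_\mathrm{pan} + E_\mathrm{tilt}$ hold by construction and are
asserted on every analyzed series.

Population aggregation follows the standard error taxonomy: per patient, all
analyzed frames of all fields and fractions are pooled frame-weighted into one
mean and SD; across patients the **systematic error** Σ is the sample SD
(divisor $n-1$) of the per-patient means and the **random error** σ is the
plain RMS (divisor $n$) of the per-patient SDs. These conventions are pinned
deliberately — with the bundled eight-patient cohort summary, only the
$n-1$ form of Σ reproduces the reference values to the printed precision:

```{r cohort}
population_stats(liver_cohort_stats())
```

The planning-target-margin contribution uses the Van Herk coverage recipe
$2.5\,\Sigma + 0.7\,\sigma$ (90% of patients receive 95% CTV coverage),
reported to 0.1 mm with full precision retained internally.

## The detection pipeline

Each frame is a square grayscale matrix in the portal-image convention 0
(white, open beam) to 1 (black, blocked). Raw detector counts are min-max
normalized and polarity-inverted on read; normalization is affine-invariant,
so detector gain drifts between series do not matter. The raw byte layout
(header, bit depth, endianness) is configurable via `raw_dialect()` because
vendor cine formats vary; the default is headerless 16-bit little-endian.

**Aperture.** In this convention the open field is the *low*-valued region.
`segment_field()` thresholds at the radiotherapy half-maximum edge convention
— midway between the modal in-field and modal blocked gray levels — keeps the
largest connected region, and fills interior holes (the marker shadows) so
they cannot perturb the boundary. `trace_boundary()` then walks the boundary
with Moore-neighbour tracing, emitting Freeman 8-direction chain codes
clockwise from the top-most/left-most pixel, terminating on Jacob's criterion.
The enclosed area is recovered from the chain itself (shoelace over
boundary-pixel centres plus the lattice correction $L/2 + 1$), which equals
the interior pixel count exactly for rectilinear shapes and within 1.5 px²
on random rectilinear test apertures. The aperture centre is the **area
centroid of the enclosed region**, not the mean of boundary points: centroids
are insensitive to the staircase pixelation that MLC leaf steps imprint on
the contour.

**Markers.** Frames are filtered with a Laplacian of Gaussian,

$$L(x,y) = -\frac{1}{\pi\sigma^4}\Big(1 - \frac{x^2+y^2}{2\sigma^2}\Big)
  e^{-(x^2+y^2)/(2\sigma^2)},$$

mean-subtracted so the discrete kernel sums to zero (a constant frame filters
to exactly zero) and convolved with reflective padding via FFT. Dark marker
shadows produce extremal responses of one sign, so detection thresholds the
negated response at `median + k_sigma × MAD`. Candidates are labeled by
connected-neighbour analysis (8-connectivity by default) and filtered:
centroid inside the aperture, farther than `edge_margin_mm` from the traced
edge, area within bounds, elongation below a cap. Every rejection is recorded
with its reason, because detection rates below 100% must be auditable in a QA
tool. The marker COM is the *unweighted* mean of per-marker centroids — each
seed votes equally, so contrast differences from overlying anatomy do not
drag the surrogate position.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `pixel_mm_at_iso` | 0.18 | mm/px | detector pitch de-magnified to isocenter (SDD 221.2 cm) |
| `frame_rate_hz` | 2 | Hz | cine acquisition rate; 21 frames span 10 s = one 6 BPM cycle |
| `sigma_px` | 2.0 | px | LoG scale: σ√2 ≈ 2.8 px ≈ radius of a 1 mm seed shadow |
| `k_sigma` | 5 | robust SDs | detection threshold above the background median |
| `edge_threshold` | half-maximum | gray | 50% field-edge convention |
| `min_field_area_px2` | 400 | px² | smallest plausible aperture |
| `min_contrast` | 0.35 | gray | modal separation a genuine aperture must show (see below) |
| `edge_margin_mm` | 1.24 | mm | markers nearer the edge are penumbra-distorted or clipped |
| `min/max_area_px2` | 4 / 120 | px² | brackets the detected seed footprint: the projected 3 × 1 mm ellipse is ~73 px² and its thresholded LoG response extends one blur ring beyond |
| `max_elongation` | 6 | – | keeps seeds (axis ratio ~3), rejects edge ridges (≫6) |
| `require_complete` | TRUE | – | frames missing any expected marker are excluded from E~T~ |

The LoG scale and threshold are engineering defaults: portal-image pipelines
of this kind do not have a canonical σ, and both are exposed in the YAML
config (`preprocessing:`). The `min_contrast` guard exists because per-frame
min-max normalization stretches even a fully blocked, noise-only frame across
[0, 1]; for Gaussian noise the half-split modal separation of such a frame is
about $2\,E|x-\mu|/\mathrm{range} \approx 0.27$, so 0.35 cleanly separates
"two genuine modes" from "stretched noise" without rejecting real fields
(whose separation is ≈ 0.9).

## The synthetic phantom

`render_series()` emulates what the detection algorithms actually face: a
polygonal aperture translating with a respiratory trace (default 6
breaths/min sinusoid, 20 mm amplitude, applied along tilt), markers rendered
as constant-attenuation 3 × 1 mm ellipses that ride the same motion **plus**
a controllable residual tracking offset — the quantity the pipeline must
recover — 1 px Gaussian edge blur standing in for the detector point spread,
additive Gaussian grayscale noise, and optional partial occlusion of markers
clipped by the field edge. Ground truth (exact aperture centres, marker COM,
injected offsets) is returned per frame, and identical seeds give
bit-identical stacks.

What it deliberately does **not** emulate: anatomical background texture,
signal-dependent (Poisson-like) noise, MV beam pulsing artifacts, detector
MTF beyond the single blur kernel, and per-beam divergence of the marker
projection (sub-pixel at this geometry). Passing tests on synthetic scenes
therefore demonstrate the *geometry and statistics* of the chain — sub-pixel
recovery of injected offsets, correct error propagation into Σ/σ — not
robustness to anatomy-driven contrast loss, which is exactly the regime where
clinical detection rates drop below 100%.

`make_population()` builds multi-patient datasets for recovery studies. Its
generative model anchors each field's baseline frame at zero offset and draws
subsequent frames from N(bias, sd) per direction, with a patient-specific
bias. The anchoring is what makes a systematic component observable: E~T~ is
baseline-referenced, so a bias shared by the baseline would cancel
identically. Physically this represents the reference geometry captured at
beam-on plus patient-specific post-baseline drift. Because E~T~ is a folded
(absolute-valued) quantity and each field contributes one structural zero,
the recovered per-patient moments have closed forms
(`expected_patient_et()`): Monte-Carlo recovery tests compare against these,
not against naive bias/sd, and at the study scale used in the test-suite —
8 patients × 7 fields × 50 frames, rendered at a 160 px matrix with a static
24 mm aperture — recovered Σ and σ agree with the closed forms within three
standard errors. The reduced matrix and static aperture are deliberate: the
offsets under study, not the excursion, are the signal (aperture and markers
ride the same motion), and a static aperture makes its segmentation
quantization a constant that baseline referencing removes.

## Numerical conventions and degenerate inputs

* Pixel coordinates are 0-based (row, col); rows are tilt, columns pan.
  Millimetre conversion multiplies by `pixel_mm_at_iso`.
* The 90th percentile uses linear interpolation between order statistics
  (R quantile type 7); per-field and per-patient SDs use the sample form.
* Percentile/SD conventions, the Σ divisor and baseline handling are pinned
  in code and tested, because each would otherwise be a silent source of
  ±0.01 mm discrepancies.
* Degenerate inputs fail loudly with actionable messages: zero-contrast
  frames, byte-count mismatches in raw files, single-pixel regions
  (untraceable), empty marker sets (undefined COM), series with no usable
  frame, fewer than two frames (no field statistics), fewer than two patients
  (no Σ).
* If frame #1 of a series is unusable, the first usable frame becomes the
  baseline — the series is scored, but against a later reference.
* Blob moment matrices carry a 1/12 px² single-pixel inertia term so
  one-pixel blobs have a defined elongation of 1.
* Tie-breaking when more candidates survive than markers are expected is a
  deterministic total order: |mean response|, then area, then row, then
  column.

## Limitations

The tracking error measured here bundles the physical tracking residual with
the localization accuracy of the edge and marker detectors; on clinical
images it is therefore a (slight) overestimate of machine performance. The
per-direction Van Herk margins are a labeled extension — the 2D margin is the
clinically quoted quantity. Occluded or anatomy-obscured markers reduce the
analyzed-frame count rather than being imputed; detection-rate reporting
makes that loss visible, and `require_complete = FALSE` offers a permissive
mode whose COM is correspondingly less reliable.
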