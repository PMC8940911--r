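---
title: "Methods: online soma detection, tracking, and trace extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: online soma detection, tracking, and trace extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In vivo two-photon calcium imaging produces long stacks of noisy grayscale
frames (t-series) in which the somata of neurons expressing a genetically
encoded calcium indicator (GCaMP6/7, jRCaMP1a) appear as bright blobs of
roughly 10–15 µm diameter on a dim, fluctuating background. To use such data
in closed-loop experiments the analysis must run frame-by-frame while the
microscope is acquiring: cells must be found, kept identifiable over time,
segmented, and their fluorescence extracted and decontaminated from the
shared background — all without waiting for the full movie.

`somatrace` implements this pipeline around a pluggable box detector. The
detector contract is minimal: given a preprocessed image it returns
axis-aligned bounding boxes with confidence scores in [0, 1]. A classical
multiscale Laplacian-of-Gaussian (LoG) blob detector ships as the reference
implementation; a trained convolutional detector can be plugged in through
the same interface (`soma_detector()`), and the rest of the pipeline never
depends on which one is used.

## The processing model

**Detector input.** Frames are averaged to raise the input SNR before
detection, in one of two modes: a *sliding* mean of the last *n* frames
(an output per frame once *n* frames have arrived) or a *step* mean of
disjoint *n*-frame blocks (an output every *n* frames). The averaged image
is linearly rescaled to 8-bit using its own min/max, spatially upscaled by
a configurable factor with bilinear interpolation, and replicated into
three identical channels. The upscaling factor matters because detectors
have a preferred feature size; its optimal value is linear in
`sqrt(FOV area / mean box area)`, and `upscale_factor_heuristic()` applies
a calibration of that line (fit with `calibrate_upscale()` from
grid-search optima). The first detector input is available only after
`n / frame_rate` seconds (`buffer_lag()`); note that for a 20-frame window
this arithmetic gives 13.3 s at 1.5 Hz and 6.6 s at 3.03 Hz — when quoting
lags, the frame rate of the specific acquisition must be used consistently.

**Overlap measure.** Everywhere a 20%/25% overlap threshold appears, the
ratio is intersection area over the *sum* of the two box areas
(`sum_area_overlap()`), which is 0.5 for identical boxes and at most 0.5 in
general. This is deliberately not the standard intersection-over-union;
`standard_iou()` is provided for interoperability and the two are never
interchanged internally.

**Duplicate suppression.** Greedy non-maximum suppression by descending
score: a surviving box removes every box overlapping it above 0.2. Score
ties are broken toward smaller `(y_min, x_min)` so results are
deterministic and equal to the exhaustive oracle.

**Identity tracking.** Detections are matched one-to-one to existing
identities by descending overlap (greedy by default; a maximum-total-
overlap assignment via a Hungarian solver is available as
`matching = "optimal"` — the two differ only in deliberately ambiguous
configurations). Matched identities take the new coordinates and are
active; a detection whose overlap with *every* existing identity falls
below the new-identity threshold spawns a new identity; identities with no
match become inactive and are rigidly translated by the mean centre shift
of the matched identities (rounded to 0.1 px), clipped so a box never
leaves the field of view — frozen at the border rather than deleted.
Identity numbers are never reused. The new-identity threshold defaults to
0.2; 0.25 is kept as a documented alternative preset because both values
are plausible operating points and the choice is visible in the config
rather than hidden.

**Dynamic segmentation and traces.** For every frame and every identity
box (inactive ones included, at their last rigid-shifted position — a
frozen-position variant is a flag), the pixels whose intensities lie in
the closed band between the 80th and 95th percentile of the box's
intensity distribution *in that frame* form the soma mask; their
arithmetic mean is the soma signal. Percentiles use linear interpolation
between order statistics (R's type-7 quantile), pinned by a sort-based
oracle in the tests. The global background *bg* is the mean of all pixels
outside the union of current boxes, recomputed per frame because the box
set changes; *bg* is subtracted from every soma mean. A local variant
(mean over a concentric double-size box, excluding all boxes) exists as an
analysis utility; the main path uses the global background only, because
the two are highly correlated and the global form is much cheaper. Pixels
inside two overlapping boxes contribute to both cells; traces are missing
(never zero) before an identity's first detection.

**Offline mode.** With the whole movie available, the stack is optionally
rigid-registered (phase correlation against the median projection,
corrections clipped to ±13 px, sub-pixel quantised to 0.1 px; integer mode
available), collapsed onto its temporal median, detected once, and the
static box set is projected onto every frame for extraction. An online run
with step averaging and `n = T` coincides with the offline run wherever
both define outputs (the online trace starts at its first emission by
construction; a static noiseless movie makes the mean and median
projections identical, which the consistency test exploits).

**Scheduling contract.** The online loop is specified by its sequential
reference semantics; an interleaved scheduler that defers extraction to
chunk boundaries (using per-frame registry snapshots) must produce
bit-identical trace sets, which is asserted in the tests. True
multi-process deployment is an integration concern outside the library.

**Large fields of view.** Mesoscopic images are tiled (default 128 px
tiles, 28 px overlap) at stride `tile - overlap` with a final tile
anchored at `dim - tile` per axis so coverage is guaranteed; per-tile
boxes are translated back and deduplicated with the same suppression rule.
Batching is a throughput hint only — results are independent of batch
size.

## The synthetic benchmark

`generate_scene()`/`render_movie()` emulate a raster-scanned acquisition:
somata are hard disks with a 1-pixel Gaussian edge (crisp in-focus
percentile statistics), placed by rejection sampling with pairwise centre
spacing of at least three soma radii; each cell carries a Poisson spike
train rendered through a peak-normalised double-exponential indicator
kernel (rise 0.1 s, decay 1 s — GCaMP6-like); a shared neuropil signal
(low-pass-filtered Gaussian noise, identical at every pixel) and i.i.d.
per-pixel Gaussian noise are added on a constant baseline of 100 a.u.
Ground truth is exported as the tightest box around each disk, the
noiseless per-cell soma-mean trace (the cell's own signal; neuropil and
noise excluded), and — when drift is injected — the per-frame translated
boxes and the shift log. Rendering is bitwise deterministic given the
seed.

The default conditions are a 256 × 256 px field at 30 Hz, 300 frames,
20 cells of radius 5–7 px, resting brightness 40–80 a.u. above baseline and
transient amplitudes 40–80 a.u. at 0.2 Hz. For the noisy benchmark the
per-pixel noise sigma of 50 a.u. was chosen analytically so that the
movie-level SNR (mean over standard deviation of all pixel values) lands at
≈ 2; the rendered stack measures 1.99. Injected drift follows a linear
ramp of the cumulative displacement (sub-pixel bilinear warping, revealed
pixels filled with the baseline by default; cropping is an option), with
amplitude and duration exposed as free parameters rather than a fixed
grid.

What the generator deliberately omits: optical point-spread blur,
scan-line and bidirectional-scan artifacts, photobleaching, dendrites and
neuropil structure, overlapping somata, and activity-correlated motion.
Passing tests on this benchmark therefore demonstrate the correctness of
the pipeline's bookkeeping and its qualitative robustness properties —
not detection performance on real tissue, which depends on the detector
used.

## Numerical choices and degenerate inputs

- Box coordinates are 0-based half-open, `x` = column, `y` = row; VOC's
  1-based inclusive convention is converted only at the XML boundary.
  Detector boxes in upscaled coordinates are mapped back by dividing by
  the factor and rounding half-up, in one place.
- The enhancement used for annotation images sharpens with the 3 × 3
  kernel `[[−1,−1,−1],[−1,12,−1],[−1,−1,−1]]` under reflect padding
  (avoids dark rims that would distort the final rescale), clips to
  [0, 255], applies gamma 0.3 on [0, 1]-normalised values, and rescales to
  span the full 8-bit range; a constant image returns mid-gray with a
  warning.
- The sliding buffer keeps a running sum with add/subtract updates; its
  contract is equality with the brute-force window mean, which the tests
  assert to 1e-12.
- In tiny boxes the interpolated percentile band can contain no pixel
  (e.g. two pixels valued 0 and 100); the segmentation then falls back to
  the value(s) nearest the band midpoint rather than failing the frame.
- Boxes covering the whole field make the global background undefined —
  an error, not a silent zero. A constant trace makes the SNR undefined —
  likewise an error.
- Precision is defined as 0 when there are no predictions; recall as 1
  when there is no ground truth to find. The matching cutoff of 0.5 uses
  intersection over the *smaller* box area (the most permissive reading
  consistent with a 0.5 threshold); IoU matching is a config alternative.
  The reported `mean_iou` is literally the mean standard IoU over matched
  pairs; the conventional precision-averaged detection AP is a separate,
  clearly named function (`detection_ap()`), since the two can differ
  substantially.
- Event detection smooths with a second-order Savitzky–Golay filter over
  15 frames and keeps positive-going local maxima with prominence ≥ 7 and
  height ≥ 3. Peak prominence uses the standard topographic definition.
  In the event-recovery benchmark, a transient qualifies for the recovery
  statistic when its nearest neighbour spike is at least 2 s away (twice
  the decay constant): closer transients merge into a single peak and do
  not individually express the qualifying amplitude.
- Dendrogram sorting clusters correlation-matrix rows by Ward linkage on
  Manhattan distances (`hclust(..., "ward.D2")`).

## Problem sizes used by the tests and the acceptance script

Unit fixtures are 32–128 px movies of 3–40 frames. The end-to-end
benchmark runs the full online pipeline on 256 × 256 px, 300-frame,
20-cell movies (step averaging, n = 20 or 10); decorrelation uses a
128 × 128 px, 200-frame, 10-cell movie with neuropil amplitude 30 ≫ noise
2; event detection uses 8 cells over 600 frames at 10 Hz. These sizes keep
any single check within seconds on one CPU while leaving every code path
exercised at realistic geometry.

## Known limitations

- The reference LoG detector assumes roughly isotropic, well-separated
  bright somata; it is a correctness stand-in with honest but modest
  performance on hard data, and it reports relative (per-image
  normalised) confidence scores.
- No non-rigid registration; drift handling assumes lateral rigid motion.
- Identity merging after duplicate creation is out of scope, as are
  appearance-based re-identification, spike deconvolution, and ΔF/F
  normalisation (traces are raw background-subtracted fluorescence).
- Trace storage is CSV (text); very long mesoscopic runs may warrant a
  binary store outside this package.
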