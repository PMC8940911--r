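# somatrace

Online cell detection, identity tracking, and trace extraction for
two-photon calcium imaging.

`somatrace` is for experimenters and analysts who need frame-by-frame
processing of calcium imaging t-series — for closed-loop all-optical
experiments, for mesoscopic fields of view with thousands of neurons, or
simply for fast offline segmentation-free trace extraction. The package is
detector-agnostic: any object detector that returns scored bounding boxes
can drive the pipeline through a one-function interface, and a classical
multiscale Laplacian-of-Gaussian blob detector is built in as the
reference implementation.

## The method

Incoming frames are averaged (sliding window or disjoint *n*-frame
blocks), rescaled to 8-bit, upscaled so somata match the detector's
preferred feature size, and passed to the detector. Duplicate boxes are
removed by non-maximum suppression using the sum-of-areas overlap ratio

> ov(A, B) = |A ∩ B| / (|A| + |B|),

which is 0.5 for identical boxes and is thresholded at 0.2 throughout
(standard IoU is available separately). Detections are matched one-to-one
to persistent identities by descending overlap; an unmatched detection
whose overlap with every known identity is below 0.2 becomes a new
identity; identities without a match are kept — marked inactive and
rigidly translated by the mean shift of the matched ones — for the rest of
the run.

Every frame, each identity's box is segmented dynamically: the pixels
whose intensities fall between the 80th and 95th percentile of the box's
per-frame intensity distribution form the soma mask, and their mean is the
soma signal. All pixels outside every box form the global background *bg*,
whose per-frame mean is subtracted from each soma signal:

> F_i(t) = mean{ p ∈ box_i(t) : P80 ≤ I_p(t) ≤ P95 } − bg(t).

Detection metrics (precision, recall, F-1 = 2PR/(P+R), mean IoU over
matched pairs), consensus merging of two annotators, Savitzky–Golay-based
calcium-event detection (window 15, prominence 7, height 3), SNR
(mean/sd), lag-zero correlation matrices with Ward/Manhattan dendrogram
sorting, tiled detection for mesoscopic images (128 px tiles, 28 px
overlap), rigid registration by phase correlation (≤ 13 px), and a
synthetic movie generator with exportable ground truth complete the
toolkit.

## Worked example

```r
library(somatrace)

cfg <- scene_config(fov_shape = c(128, 128), n_cells = 10, n_frames = 150,
                    frame_rate = 10, noise_sigma = 30, neuropil_amplitude = 15)
scene <- generate_scene(cfg, seed = 42)
movie <- render_movie(scene)
print(movie$stack)
#> movie_stack: 128 x 128 px, 150 frames, 10 Hz, 1 um/px, 32-bit

run <- run_online(movie$stack,
                  pipeline_config(mode = "step", n_frames = 10,
                                  score_threshold = 0.15))
print(run$traces)
#> trace_set: 10 identities x 150 frames (10 Hz)

report <- match_detections(registry_boxes(run$registry), movie$gt_boxes)
print(report)
#> TP 10  FP 0  FN 0 | precision 1.000  recall 1.000  F-1 1.000  <IoU> 0.815

cc <- correlation_matrix(run$traces)
round(mean_pairwise_correlation(cc), 3)
#> [1] -0.057

nrow(detect_events(run$traces$traces[, 1]))
#> [1] 1
```

All ten synthetic cells are recovered exactly (10 true positives, no false
positives or negatives) despite per-pixel noise and a shared neuropil
signal; the mean pairwise trace correlation after background subtraction
is near zero because the common neuropil component has been removed; and
the first cell's trace contains one detected calcium transient.

The same operations are available from a shell via the bundled CLI
(`inst/cli/somatrace`): `simulate`, `run --online/--offline`, `evaluate`,
`gridsearch`, and `inject-motion`, all driven by a YAML config with a
`--seed` flag.

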