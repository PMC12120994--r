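---
title: "Quantifying DNA nanotube growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA nanotube growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubequant)
```

## The measurement problem

DX-tile DNA nanotubes are micrometer-long, ~20 nm-wide filaments that
polymerize from double-crossover tiles via sticky-end hybridization. Their
growth is followed by fluorescence microscopy of labelled, surface-adsorbed
tubes: each field of view contains dozens to hundreds of bright curvilinear
features on an unevenly illuminated, noisy background. Three quantities
summarize growth:

* the **average nanotube length** per timepoint, with an error bar given by
  the standard deviation of per-replicate means;
* **frequency and length-fraction histograms**, where the length fraction of
  a bin is the share of the *total summed length* contributed by tubes in
  that bin — a mass-weighted view in which growth appears as weight moving
  into longer bins;
* the **complementary cumulative distribution function (CCDF)**,
  `P(length > x)`. Growth by single-tile addition predicts exponentially
  distributed lengths, so the CCDF is a straight line on a semilog plot with
  slope `-1/mean`; divided by its sample mean, *any* exponential CCDF
  collapses onto the line of slope −1. Deviations are diagnostic: an excess
  of long tubes suggests end-joining of existing tubes, an excess of short
  ones frequent nucleation.

A separate, much simpler analysis locates melting temperatures from UV
absorbance at 260 nm: transitions appear as maxima of `dA/dT`. Two are
expected for DX-tile tubes — sticky-end disassembly (Tm¹) followed by tile
melting (Tm²).

## The segmentation pipeline

`run_pipeline()` executes, in order:

1. **Background estimation** — a median filter with a *disk* footprint
   (default radius 15 px, sensible range 10–20 px). The footprint must be
   larger than the tube width so that tubes are erased while the smooth
   illumination field survives. Edges are handled by reflection.
2. **Gaussian smoothing** of the raw image (default σ = 1 px) to keep pixel
   noise from fragmenting tube detections.
3. **Subtraction** of the background from the smoothed image. Negative
   residuals are clipped to 0: the histogram-based thresholds below assume a
   non-negative intensity distribution, and residual values below the
   background estimate carry no tube signal.
4. **Automatic thresholding** (Otsu by default; Yen and Triangle
   alternatives). Candidate thresholds are the cuts between adjacent
   distinct pixel values — the foreground mask `intensity > t` can only
   change there — and the returned value is the midpoint of the winning cut,
   so both classes sit strictly on either side. For Otsu the winning cut
   exactly maximizes the between-class variance; ties resolve to the lowest
   cut. Images with more than 256 distinct values are binned first. The
   threshold is computed per image; a constant residual image raises a
   degenerate-histogram condition and the image is skipped with a warning.
5. **Thinning** to a 1-px skeleton by Guo–Hall two-subiteration parallel
   thinning, run to convergence. The algorithm choice matters: simpler
   schemes (e.g. Zhang–Suen) leave single-pixel side nubs on ragged masks,
   and every nub becomes a spurious branch point that disqualifies an
   otherwise clean tube in step 7. Guo–Hall is spur-free on the same masks,
   idempotent, and preserves connected components.
6. **Short-feature removal**: skeleton components with fewer than
   `min_feature_px` pixels (default 3) are flagged `too_short` — such
   fragments cannot be identified as nanotubes.
7. **Branch-point pruning**: a skeleton pixel with more than two neighbors
   (8-connectivity by default) marks an intersection; since the individual
   lengths of crossing filaments cannot be resolved, the *entire* component
   is flagged `branched` and excluded.
8. **Length measurement** of retained features, in pixels and micrometers.

### Length metrics and their biases

Two metrics are provided, and neither is bias-free — the biases are
geometric facts of digital lines worth knowing:

* `pixel_count` (default): the number of skeleton pixels. This matches a
  region-properties measurement of a thinned feature, but *undercounts*
  oblique filaments — a 45° line of Euclidean length L occupies only
  `L/√2` pixels, and averaged over uniform orientations the metric reads
  about 10% short.
* `geodesic`: the step sum along the skeleton path with weight √2 per
  diagonal move. It tracks oblique filaments much better but *overcounts*
  straight digital lines by up to +8.2% at 22.5° orientation (the classic
  chain-code length bias). Averaged over orientations this is roughly +5%,
  partially cancelled by the few pixels of end retraction that thinning
  applies to a blob's extremities.

For accuracy studies — and for the package's own recovery benchmarks — the
geodesic metric is the right choice; `pixel_count` is kept as the default
because it is the closest match to a region-properties pixel count and keeps
single-image results comparable with that convention.

### Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `median_radius` | px | 15 | midpoint of the useful 10–20 px range; larger is smoother but slower |
| `gaussian_sigma` | px | 1 | suppresses pixel noise without widening tubes appreciably |
| `threshold_method` | — | otsu | robust on tube-on-background histograms; yen/triangle for skewed cases |
| `min_feature_px` | px | 3 | below 3 skeleton pixels a feature cannot be called a nanotube |
| `connectivity` | — | 8 | diagonal skeleton steps are genuine connectivity |
| `length_metric` | — | pixel_count | see above; use geodesic for accuracy work |

## The synthetic-data generator

No raw micrographs ship with the package; `render_scene()` generates scenes
with exact ground truth instead, so every stage is testable.

The scene model: each tube is a worm-like piecewise-linear polyline with
1-px steps and per-step heading changes drawn uniformly in ±`curvature`
degrees (default 8°, giving the gently curved look of stiff filaments with
a persistence length of several micrometers). Tubes are placed with uniform
random position and orientation; a polyline that would leave the frame is
re-drawn (up to 100 attempts), so boundary-clipped tubes never occur and
ground-truth lengths are exact to machine precision. Each polyline is
deposited as arc-length-uniform point masses quantized on a 4× supersampled
grid — sub-pixel, orientation-independent anti-aliased rendering without
materializing the supersampled canvas — then convolved with a Gaussian PSF
(default σ = 1.3 px ≈ 85 nm at the default 0.065 µm pixels, a realistic
diffraction width), scaled so an isolated tube peaks near `tube_amplitude`,
and added to a background plane with a fractional corner-to-corner
illumination gradient (default 20%). Poisson shot noise on signal plus
background and additive Gaussian read noise follow; the result is quantized
to 16-bit counts. Identical `scene_spec`s (including the seed) render
bit-identical images.

Default intensities (amplitude 8000 over background 2000, read noise 200
counts) emulate a bright Cy3-labelled preparation; recovery benchmarks use
deliberately dimmer tubes (amplitude/read-noise = 5).

Ground truth records each tube's exact polyline arc length and a
`crosses_another` flag computed by segment–segment intersection between
polylines. What the generator does **not** emulate: photobleaching,
out-of-focus light and 3-D structure, tube-width variation, aggregates, and
camera fixed-pattern noise. Passing the recovery benchmarks therefore
demonstrates correctness of the measurement chain on a faithful but
idealized image model — not performance on arbitrary real micrographs.

Melting curves are simulated as
`A(T) = baseline + Σ aᵢ σ((T − cᵢ)/wᵢ)` plus independent Gaussian noise per
replicate per temperature, on the standard 1 °C grid from 20 to 90 °C with
6 replicates; defaults place two transitions at 40 °C and 62 °C with widths
2 and 2.5 °C, amplitudes 0.05 and 0.12 AU and noise 0.004 AU — typical of a
benchtop UV-Vis instrument.

## Expected accuracy, and what the benchmarks measure

The recovery of a *population mean* length from synthetic scenes combines
several small, partly cancelling biases, all intrinsic to the measurement
(real experiments share them):

* tubes shorter than `min_feature_px × pixel_size` are removed; by the
  memorylessness of the exponential distribution this *raises* the measured
  mean by exactly that floor (≈ +6.5% at 0.065 µm pixels and a 3 µm mean);
* long tubes are more likely to leave the frame (excluded at generation) or
  to cross another tube (excluded by branch pruning), *lowering* the
  measured mean by a few percent each at the benchmark's density;
* the digital-length bias of the chosen metric (above).

The package's end-to-end benchmark — 6 scenes of 2048×2048 px at 0.065
µm/px with 200 tubes each, exponential mean 3 µm, geodesic metric — lands
within 5% of the nominal mean; the acceptance requirement is 10%. The
straight-tube benchmark (50 single-tube scenes, lengths 20–80 px, SNR 5)
checks the *ensemble mean* error of the geodesic metric to within 5% (and
the pixel-count metric to within 10%); per-tube errors necessarily spread
wider than this because the orientation-dependent digital-length bias can
reach ±8% on a single tube, whatever the implementation.

Problem sizes throughout the test-suite were chosen so the full suite runs
in minutes on one core while keeping statistical assertions comfortably
powered (10⁵ draws for distribution-level checks, ≥ 10³ measured tubes for
mean-recovery checks).

## Numerical conventions and degenerate inputs

* Coordinates are row/column; lengths are reported in px and µm.
* CCDF uses the strict convention `P(X > x)`; ties share the survival value
  of their last occurrence, so the curve is non-increasing by construction.
* The semilog CCDF fit excludes zero-survival points (log undefined) and by
  default restricts to the [0, 0.99] length-quantile range to keep the
  noisy extreme tail from dominating the least-squares fit.
* Replicate aggregation is the unweighted mean of per-replicate means; the
  error is the SD across replicate means, 0 by convention (and flagged)
  for a single replicate.
* `detect_tm()` ranks interior local maxima of dA/dT by height and enforces
  a minimum separation (default 5 °C) so that noise wiggles on a transition
  shoulder are not reported as a second transition. Derivatives use
  centered differences after an optional 3-point moving average; endpoints
  use one-sided differences and are never reported as peaks.
* Histograms use half-open bins `[lo, hi)`; data outside the edges raise an
  error rather than being silently clamped.

## Open choices made here

* Which region property the original measurement used as "length" is not
  specified anywhere; both plausible readings (`pixel_count`, `geodesic`)
  are implemented and the trade-off documented above.
* Thresholds are computed per image, not shared across a time series —
  illumination drifts between fields of view, and per-image thresholds are
  the safer default.
* The epifluorescence pixel size is treated as a free calibration
  parameter; 0.065 µm — a printed confocal value for this system — is used
  as the package default.
* Branch removal discards whole components rather than splitting them at
  branch points: splitting would require deciding which branch continues
  which tube, an assignment that cannot be made reliably from a binary
  skeleton.

## Limitations

* No gap-closing: a tube fragmented by a local intensity dip is measured as
  two shorter tubes.
* No sub-pixel tracing: lengths are skeleton-based and carry the digital
  metric biases described above.
* Crossing tubes are discarded, so dense fields underestimate both count
  and (because long tubes cross more) mean length; keep densities low or
  correct for the exclusion.
* The melting module detects transitions; it does not fit thermodynamic
  models (no van't Hoff analysis, no hyperchromicity baseline correction).
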