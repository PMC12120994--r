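# tubequant

Quantification of DNA nanotube growth from fluorescence micrographs, in R.

DX-tile DNA nanotubes polymerize from double-crossover tiles into
micrometer-long filaments. Their growth is followed by imaging labelled,
surface-adsorbed tubes and measuring every non-intersecting filament in each
field of view. `tubequant` implements that measurement chain and the
statistics built on it, for researchers studying DNA self-assembly kinetics
(or any sparse filamentous structures in 2-D fluorescence images):

* **Segmentation** (`run_pipeline()`): disk-footprint median-filter
  background estimation → Gaussian smoothing → background subtraction →
  automatic thresholding (Otsu / Yen / Triangle) → Guo–Hall thinning to
  1-px skeletons → removal of features < 3 px → branch-point pruning of
  intersecting filaments → per-filament length in px and µm.
* **Growth statistics**: average length as the mean of per-replicate means
  with the SD across replicate means as error; frequency and
  length-fraction histograms; the empirical CCDF `P(length > x)` with
  semilog line fit. For lengths following the exponential growth model
  `P(L > x) = exp(-x/λ)`, the CCDF is a straight semilog line of slope
  `-1/λ`, and after dividing lengths by their sample mean it collapses onto
  the line of slope **−1** — the package's central diagnostic for
  single-tile-addition growth versus end-joining.
* **Melting analysis** (`detect_tm()`): melting temperatures as maxima of
  `dA/dT` from 260 nm absorbance–temperature tables (6 replicates, 1 °C
  grid), resolving the sticky-end (Tm¹) and tile (Tm²) transitions.
* **Synthetic data** (`render_scene()`, `make_melting_curve()`): worm-like
  polyline tubes rendered through a Gaussian PSF onto an unevenly
  illuminated noisy background, with exact ground-truth lengths and
  crossing flags — every stage is testable without raw data.

## Worked example

Simulate a field of view with known ground truth, measure it, and compare:

```r
library(tubequant)

spec <- scene_spec(image_shape = c(512, 512), pixel_size = 0.065,
                   n_tubes = 25, length_distribution = dist_exponential(3),
                   seed = 42)
scene <- render_scene(spec)
mean(scene$ground_truth$true_length_um)
#> [1] 3.106983

seg <- run_pipeline(scene$micrograph,
                    pipeline_config(length_metric = "geodesic"))
seg
#> <tube_segmentation 'synthetic'> threshold 2275, 21 measured features
#>   length range 0.13 - 15.6 um (mean 3.27 um)
```

21 of the 25 tubes are measured (tubes crossing another tube, or shorter
than 3 skeleton pixels, are excluded by design) and the measured mean of
3.27 µm sits within ~5% of the 3.11 µm ground truth of this field of view.
The distribution-level diagnostic, here on a large sample so the asymptotic
behavior is visible:

```r
s <- length_sample(sample_lengths(dist_exponential(3), 1e5, seed = 7))
fit <- fit_semilog_slope(normalize_ccdf(empirical_ccdf(s)))
fit
#> <ccdf_fit> semilog slope -1.0001 (intercept 0.0003), 99000 points, normalized axis
```

A mean-normalized semilog CCDF slope of −1 is the signature of an
exponential length distribution, i.e. growth by tile addition; slopes from
measured fields of view are compared against it. Melting analysis works the
same way from CSV tables:

```r
tm <- detect_tm(make_melting_curve(seed = 1))   # two-transition simulation
tm
#> <tm_result>
#>   Tm1 = 40.0 C (dA/dT = 0.006595 AU/C)
#>   Tm2 = 61.0 C (dA/dT = 0.01122 AU/C)
```

(The simulated transitions sit at 40 °C and 62 °C; with realistic replicate
noise the detected peaks land within the 1–2 °C expected of a 1 °C grid.)

A full simulate → segment → summarize run with all CSV/TIFF/PNG artifacts
and a JSON report: `end_to_end(run_config(pixel_size = 0.065), "out/")`.
A thin command-line front end with `simulate` / `segment` / `stats` /
`melt` / `end-to-end` subcommands is installed at `inst/cli/tubequant.R`.

See the vignette (`vignettes/nanotube-quantification.Rmd`) for the model,
parameter rationale, metric biases, and the generator's scope.

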