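# octscreen

High-throughput drug screening on *ex vivo* tissue — retinal explants
cultured in multi-well plates being the motivating case — needs an imaging
readout that is fast, longitudinal and unbiased. Optical coherence
tomography (OCT) provides exactly that: depth-resolved reflectance volumes
from which tissue thickness, footprint area and volume can be measured
without sectioning the sample. `octscreen` implements the computational
side of a fully automated OCT plate-screening system in R:

- **plate-view detection** — locate the explant in a well image (bounding
  box + centroid, or an explicit *void* for empty wells), convert the
  centroid to stage voltages, and score detectors with IoU, mAP
  (IoU grid 0.50–0.95 in steps of 0.05) and centroid shift;
- **depth sweep** — pick the optimal axial stage position as the argmax of
  mean B-scan intensity over a sweep;
- **segmentation** — a deterministic B-scan tissue segmenter robust to
  saturated specular columns, reflectance drift and the thin bright
  culture-insert membrane, plus recall/precision/Dice metrics and paired
  image/mask augmentation utilities;
- **morphometry** — en-face thickness maps (per-column voxel count × axial
  pitch), central mean thickness (mean over columns at or above the median
  of the tissue columns), footprint area (mm²) and volume (mm³);
- **assay statistics** — pooled-SD repeatability and reproducibility,
  Z′-factor and SSMD with quality flags, percent change, and a Welch
  two-group comparison;
- **phantom simulation** — a seeded generator of well images, OCT volumes,
  depth stacks and grouped screen tables, each paired with exact ground
  truth, so every stage is testable end-to-end without instrument data;
- **orchestration** — `run_screen()` drives a simulated plate pass
  (detect → move → sweep → acquire → segment → measure → QC) with a full
  motion/stage log and byte-reproducible output.

The two assay-quality statistics at the core of screen validation are

```
Z′  = 1 − 3 (σ⁺ + σ⁻) / |μ⁺ − μ⁻|          (≥ 0.5 rated excellent)
β   = (μ⁺ − μ⁻) / sqrt(σ⁺² + σ⁻²)          (|β| > 2 rated excellent)
```

with μ±, σ± the mean and SD of the positive/negative control groups.

## Worked example

Simulate one explant volume, segment it, and reduce it to readouts:

```r
library(octscreen)
spec <- phantom_spec(n_alines = 96, n_bscans = 20, axial_px = 160)
acq  <- make_oct_volume(spec, seed = 1)
seg  <- segment_volume(acq$volume)
measure_readouts(seg, sample_id = "A1", timepoint = "baseline",
                 repetition = 1L)
#> # A tibble: 1 × 6
#>   sample_id timepoint repetition thickness_um area_mm2 volume_mm3
#> 1 A1        baseline           1          180       15       2.70
```

The phantom is a 180 µm uniform slab over a 2.2 mm-radius footprint, so
the central mean thickness of 180 µm, area of 15 mm² (analytic π·2.2² ≈
15.2 mm², discretised on a 96 × 20 lateral grid) and volume of 2.70 mm³
are recovered from the segmentation despite speckle, specular columns and
the membrane (`seg_metrics(seg, acq$truth$mask)` reports Dice 0.9996).

QC of a simulated two-group screen (baseline 191.8 ± 11.5 µm thickness;
−30.3% in the negative arm, +30% in the positive arm, 5 repeated volumes
per sample — 4 negative vs 8 positive samples):

```r
scr <- make_screen_dataset(seed = 1)
assay_quality(scr, "thickness_um", timepoint = "day10")
#> <assay_quality> readout: thickness_um @ day10
#>   positive: 245.874 +/- 18.446 (n=8)   negative: 137.061 +/- 8.266 (n=4)
#>   Z' = 0.264 (below-threshold)   SSMD = 5.383 (excellent)
#>   repeatability = 0.3565   reproducibility = 16.08   p = 6.41e-08
```

At n = 4 + 8 the sample Z′ is noisy (the population value under these
group parameters is ≈ 0.40); SSMD flags the separation as excellent, and
the Welch p-value shows the groups are clearly distinguished. Direct
evaluation of reference control statistics (191.8 ± 11.5 vs 133.7 ± 8.4
µm) gives `percent_change(191.8, 133.7)` = −30.3%, Z′ = −0.028 and
β = 4.08.

A full simulated plate pass:

```r
res <- run_screen(screen_config(seed = 42))
res$qc        # Z'/SSMD/repeatability/reproducibility per readout
res$log       # detect → move → sweep → acquire → measure per well
```

A thin CLI over the same functions is installed at
`inst/scripts/octscreen` (`octscreen simulate|detect|sweep|segment|
measure|qc|run`).

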