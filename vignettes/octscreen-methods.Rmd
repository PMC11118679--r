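---
title: "Models and methods behind octscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind octscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octscreen)
```

`octscreen` implements the computation of an automated OCT plate-screening
workflow: find the explant in a plate-view well image, drive a (simulated)
stage to it, pick the optimal axial position, acquire a volume, segment
the tissue in every B-scan, reduce the segmentation to morphometric
readouts, and score the screen with assay-quality statistics. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic phantoms do and do not establish about
real data.

## The phantom model

Every stage is validated against a seeded generator whose outputs carry
their own exact ground truth. A phantom OCT volume contains, from the top
of each A-line downward: dark background, a tissue slab whose thickness
follows a configurable profile (uniform, paraboloid dome, or a bimodal
step), a clear gap, and a thin bright supporting-membrane layer — the
geometry of an explant resting on a culture insert. Default acquisition
geometry is a 6 × 6 mm field sampled at 500 A-lines × 500 B-scans, two
repeated acquisitions averaged per stored B-scan, and an axial grid of
512 px at 2 µm. The axial pitch and bit depth of a real scanner are
instrument-specific, so both are configurable; 2 µm × 512 px covers more
than a millimetre of depth, ample for explants up to ~300 µm.

The intensity model is deliberately statistical, not physical-optics:

* tissue reflectance = base level × (1 + drift field) × speckle, where the
  drift field is a smooth low-order sinusoidal surface with amplitude
  `reflectance_drift` (default 0.2) and speckle is log-normal with unit
  mean and `sdlog = speckle_sd` (default 0.3);
* a fraction `specular_column_rate` (default 2%) of lateral positions is
  replaced by fully saturated columns — the specular-reflection failure
  mode that defeats naive thresholding;
* the membrane renders at a bright fixed level (default 0.9) and is never
  part of the ground-truth tissue mask;
* `n_repeats` independent speckle realisations are averaged per stored
  B-scan, the natural reading of repeated-A-scan acquisition; with
  `speckle_sd = 0` the phantom is exactly noise-free, which gives the
  pixel-exact oracles used throughout the tests.

There is no interferometry, dispersion or sensitivity roll-off in the
model. Consequently, passing tests show that the algorithms are correct
on the stated geometry and robust to the three modelled artifact classes;
they do not certify performance on real scanner data, whose noise is
correlated and whose membrane/tissue contrast varies.

The grouped screen-table generator draws per-sample true readouts from
`Normal(group mean, group SD)` per timepoint, adds
`Normal(0, repeat_sd)` repetition noise, and sets follow-up group means
to `baseline × (1 + change_frac)` with SDs scaled by `|1 + change_frac|`
(a constant coefficient of variation, the usual behaviour of
morphometric readouts). Thickness defaults describe a degenerating
retinal-explant screen: baseline 191.8 ± 11.5 µm, −30.3% negative-arm change, +30%
positive-arm change, repetition SD 0.4 µm, five repeated volumes per
sample, 4 negative and 8 positive samples. Area (15.2 ± 0.755 mm²) and
volume (2.92 ± 0.107 mm³) defaults are chosen to be consistent with a
~2.2 mm explant radius and the reported ~5% between-sample variation;
their negative-arm changes (−20% area; volume compounding thickness and
area changes) follow the reported longitudinal behaviour.

## Detection

The reference detector is classical and fully deterministic: Gaussian
smoothing (scale `smooth_mm`, default 0.25 mm), a robust background model
(median of the smoothed image; deviations beyond `k_mad` MADs and at
least `min_contrast` are foreground), connected components, an area floor
of `min_area_mm2` (default 1 mm² — an explant is centimetre-scale, dust
is not), and the largest surviving component (ties: smaller top-left
corner in row-major order). If nothing survives, the result is an
explicit *void*, which is what prevents empty wells from being imaged.
The centroid is intensity-weighted by the deviation map rather than the
box centre — for an asymmetric explant the mass centre is the better
stage target; this is a documented choice, and the box centre can be
derived from the returned box if preferred.

Conventions, stated once: boxes are half-open and 0-based with x = column
and y = row; mm coordinates originate at the image's top-left corner;
pixel `(r, c)` has centre `((c − ½)·s, (r − ½)·s)` mm at pitch `s`.
Detector scoring uses all-point-interpolated average precision with
greedy confidence-ordered matching (each truth matched at most once,
highest-IoU unmatched truth wins), averaged over IoU thresholds 0.50 to
0.95 in steps of 0.05 — the standard single-class protocol, spelled out
so scores are comparable. Stage conversion is the affine map
`volts = reference + (centroid + offset) / mm_per_volt`, exactly
invertible by `stage_to_centroid()`.

The detection stage of the original instrument is a trained single-shot
multi-scale detector; its training images and weights are not available,
and no deep-learning stack is a dependency of this package, so the
classical detector is the reference path here.
The same applies to the hybrid residual/transformer segmentation network:
the package implements the deterministic classical segmenter and the
full metric/augmentation tooling a network would be trained and scored
with, not the network itself.

## Segmentation

`segment_classical()` addresses the three artifact classes in order:

1. **Specular columns** — a column at least half of whose pixels sit at
   the frame's intensity cap (the 0.995 quantile) is flagged and excluded
   from all estimation. A frame whose every column is flagged raises a
   distinct `unsegmentable` condition rather than returning garbage.
2. **Reflectance drift / affine gain** — the frame is min-max normalised
   and thresholded with Otsu's method, making the rule invariant to
   global affine intensity rescaling (asserted by test). The threshold is
   *estimated* on a Gaussian-smoothed copy (stable under speckle) but
   *applied* to the raw frame, so noise-free frames segment
   pixel-exactly while hole-filling absorbs isolated speckle
   misclassifications.
3. **Membrane** — any component whose axial extent never exceeds
   `membrane_max_thickness_um` (default 30 µm) anywhere is removed. An
   extent rule rather than a position prior survives tissue sag and is
   testable by construction on phantoms (the membrane is generated at
   10 µm, tissue at ≥ 100 µm).

The largest surviving component is kept, holes are filled, and flagged
columns are in-painted by row-wise linear interpolation of the mask
between their nearest clean neighbours. The membrane gap (default 20 µm)
is what keeps tissue and membrane as separate components; explants that
rest in optical contact with the membrane would need the gap parameter
(and possibly the extent rule) revisited — a known limitation.

Metric conventions on empty masks: both empty → all three metrics are 1;
exactly one empty → all 0. This keeps recall/precision/Dice bounded and
symmetric; the identity `dice = 2PR/(P+R)` is asserted on random masks.

## Morphometry

Thickness is *voxel count × dz*, not top-minus-bottom span: it is the
direct reduction of the binary segmentation, it is additive, and it is
robust to interior holes. The span variant is available as
`thickness_map_span()` for cross-checking. Area counts support columns
(thickness > 0) times the lateral pixel area; volume integrates the map.
The central thickness readout averages columns whose thickness is at
least the median of the *tissue* columns: including the zero background
in the median would make the rule degenerate for a small explant in a
wide field, and the inclusive `≥` keeps the central region nonempty on
perfectly uniform maps (a strictly-greater variant is behind
`strict = TRUE`). These two resolutions of the rule's ambiguity are
asserted by worked cases: a half-100/half-200 µm map yields 200 µm and a
1..100 µm ramp yields 75.5 µm.

## Depth sweep

The sweep metric is the plain mean over every pixel of the frame; the
optimum is the argmax, ties broken by the lowest index, and indices are
1-based as everywhere in R. A `restrict_range` window implements
narrow-range sweeping once a plate's approximate optimum is known; the
pipeline-level cache (`sweep$skip_after_first`) implements skipping the
sweep entirely within one plate, since the optimal position is constant
across wells of a plate. The phantom stack generator centres each frame's
noise so the frame mean equals its designed unimodal profile exactly —
that is what makes 100/100 recovery a construction-guaranteed property
rather than a statistical one. No sub-position interpolation is
performed.

## Assay statistics

Z′ and SSMD are implemented in their standard forms
`Z′ = 1 − 3(σ⁺+σ⁻)/|μ⁺−μ⁻|` and `β = (μ⁺−μ⁻)/√(σ⁺²+σ⁻²)`, with the
absolute value in the Z′ denominator so group labelling order cannot
flip the score. Both raise explicit errors in their degenerate cases
(equal means; both SDs zero). Sample SDs use the n−1 denominator
throughout. Group statistics average repetitions per sample first, so
repetition noise does not masquerade as between-sample separation.

Repeatability is the pooled SD of within-sample repetitions over all
samples; reproducibility first averages repetitions per sample, then
pools the SD of sample means across conditions (group × timepoint). The
alternative reading — a one-way variance-component estimate — is not
used; the chosen reading is switchable in effect by passing a single
condition filter. The two-group comparison is a two-sided Welch t-test,
an interpretation choice (only a p-value criterion is conventional for
such screens); it is cross-checked against a permutation oracle in the
tests.

The parameter-recovery experiment for these estimators uses a design
with effect fractions set to zero, so that all four group × timepoint
conditions share the configured between-sample SD and the pooled
estimator uses the full design (96 df, sampling SD ≈ 7%). Pooling a
single condition (48 df) would put the estimator's own sampling noise at
the same scale as the 10% recovery band — a badly powered check of a
correct implementation.

## Pipeline and problem sizes

`run_screen()` visits wells row-major from A1, logs one line per stage
per well (no well is ever silently dropped), and derives every random
stream from the master seed, making a screen byte-reproducible — the
rerun identity is asserted at file level. Stage physics is idealised
(exact moves, no backlash); the motion log is the interface a hardware
driver would implement. The default simulated acquisition grid is
64 × 24 × 224 voxels, a deliberate reduction from the 500 × 500 × 512
production geometry chosen so that simulated screens and the test suite
run in seconds; the morphometry oracles are additionally exercised at
the full 500 × 500 lateral grid (where discretisation error of an
elliptical footprint falls below 1%), and all generators are
resolution-agnostic. Volumes are stored as 16-bit multi-page TIFF (exact
on the 16-bit grid), masks as 8-bit {0, 255}, spacings in JSON sidecars;
screen tables as CSV; configs as YAML/JSON with unknown keys warned and
ignored.

## Known limitations

* The phantom's speckle is spatially independent; real OCT speckle is
  correlated at the resolution-cell scale, so real Dice scores will be
  lower than phantom scores at equal parameter settings.
* The membrane model assumes a clear gap beneath the tissue; explants in
  contact with the insert may require retuning the membrane rules.
* The classical detector assumes a roughly uniform bright background;
  wells with strong vignetting or debris fields would need the robust
  threshold parameters revisited.
* No plate-effect normalisation, dose-response fitting or
  multiple-testing correction is provided; the assay statistics cover a
  single two-arm comparison per readout.
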