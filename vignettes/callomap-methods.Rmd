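---
title: "Methods: callosal parcellation, ROI sampling and cross-modal statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: callosal parcellation, ROI sampling and cross-modal statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`callomap` quantifies and compares myelin-sensitive modalities — LFB
optical density from stained post-mortem sections, and volumetric MRI
maps such as the T1w/T2w ratio, myelin water fraction (MWF) and
quantitative susceptibility (QSM) — over a common sampling scheme on the
midsagittal corpus callosum. This vignette explains the model behind each
stage, the parameters that matter, the numerical conventions, and what
the synthetic phantom does and does not establish about real data.

## Geometry: parcellation and the 92-ROI template

All images are matrices indexed `[row, col]`, row 1 dorsal, column 1
anterior; continuous coordinates are 0-based, so pixel `[i, j]` has
center `(x, y) = (j − 0.5, i − 0.5)`.

**Witelson parcellation.** The antero-posterior (AP) extent is the
bounding box of the mask along the column axis. Each foreground pixel is
assigned a normalized AP coordinate `u = (col − col_min + 0.5)/width`
(its *center* position within the extent) and classified against the
five boundary fractions, by default `1/6, 1/3, 1/2, 2/3, 4/5`. The
geometric scheme fixes the posterior four boundaries; the split between
rostrum/genu and rostral body within the anterior third is a convention,
set here at 1/6 and fully configurable. Intervals are half-open and
anterior-closed: a pixel center exactly on a fraction belongs to the
posterior region. Classifying pixel centers (rather than flooring
fraction × width) makes the rule exact under integer rasterization and
scale-invariant: doubling the mask resolution changes no pixel's region.
The rostrum is not separated from the genu. The AP axis is the image
axis, not a PCA axis — inputs are assumed axis-aligned, as midsagittal
sections and MNI-space volumes are in practice.

**The template.** The AP extent is divided into 46 equal-width columns;
within each column the dorsoventral span of the mask (min to max
foreground row among the column's pixels) is split into 2 equal rows,
giving 92 cells; the product `columns × rows` is validated to equal 92
for any configured grid. Each cell receives an inscribed circle of
radius `0.8 × min(cell width, cell height)/2`. The 0.8 ratio keeps the
circle clear of cell edges (where partial-volume and boundary pixels
live) while retaining enough pixels for a stable mean; radii below 1 px
raise a resolution error rather than silently sampling single pixels.
ROIs are ordered anterior→posterior, dorsal before ventral. Each ROI is
labeled by the macro-region of its circle-center pixel; a center falling
outside the mask is an error (it indicates the mask is not a single
contiguous arch), as is a grid column containing no mask pixels.

## Histology: the 1–7 optical-density scale

RGB sections are collapsed to a 256-level grey image with Rec. 709
luminance weights (`0.2126, 0.7152, 0.0722`), rounded half-to-even; the
unweighted channel mean is available as an option since acquisition
software rarely documents its conversion. The optical-density proxy is
the linear inversion `d = 255 − grey` — darker stain means more myelin —
and the density scale is the affine map `density = 1 + 6 d / 255`, so
grey 255 and 0 land exactly on 1 and 7. The divisor is 255, not 256,
precisely so both endpoints are attainable. A logarithmic option
(`mode = "log"`, `d = −log10((grey + 1)/256)` normalized over its fixed
range) is provided for absorbance-style workflows. With one light
calibration across acquisitions the fixed 0–255 range is the right
default; per-image min–max calibration is available via the
`calibration` argument but re-centres each section and should be used
deliberately.

The continuous density is kept for statistics; the 7-level binning
(edges at `1 + 6k/7`, purple→blue→cyan→green→yellow→orange→dark red) is
applied only when rendering maps, because correlations over 92 ROIs need
more than 7 distinct values to be informative.

## Volumetric maps: parasagittal sampling

For a 3D map the two slices at ±`offset_mm` (default 4 mm) from the
midline are extracted at indices `midsagittal_index ±
round(offset_mm/spacing)` — a warning fires when the rounding error
exceeds 25% of a voxel — and averaged voxelwise. Averaging the two
slices before ROI sampling or averaging the two per-ROI means afterwards
gives identical values (the ROI mean is linear); the voxelwise-first
order is implemented because it also yields a single 2D map for
rendering. ROI sampling takes the mean of pixels whose centers lie
strictly inside the circle (a deterministic, resolution-stable test),
intersected with the mask; the median is available behind a flag.
Cross-modality registration is out of scope: maps are assumed
co-registered to the mask's grid.

Per modality, the 92-ROI vector (all samples pooled) is min–max rescaled
onto `[1, 7]` for reporting. The rescale is affine, hence provably
neutral for Pearson correlations; a constant vector raises a
degenerate-scale error rather than dividing by zero.

## Statistics

**Variance decomposition.** For a modality with `S ≥ 2` samples,
`sd_across_regions` is the mean over samples of the SD of that sample's
92 ROI values, and `sd_across_samples` is the mean over ROIs of the SD
of that ROI across samples — regional heterogeneity vs between-sample
disagreement at a fixed location. Both use the unbiased (n−1) estimator.
The function accepts raw or rescaled units (the definition is
scale-equivariant); reported values are conventionally on the 1–7 scale.

**Correlations.** Multi-sample modalities are first averaged across
samples per ROI; then each requested pair gets the product-moment `r`,
`r²`, and a two-sided p from `t = r√((n−2)/(1−r²))` on `n−2` df — the
exact small-sample inference for Pearson's r. Signed `r` is always
reported alongside `r²`, since `r²` alone is ambiguous about direction.
A seeded permutation test (default 10,000 shuffles) is available as a
robustness check. ROIs with missing values propagate as
pairwise-complete deletion with a warning and an honest `n`.

## The synthetic phantom

No public dataset pairs callosal histology with co-registered
quantitative MRI at this scale, so validation uses a phantom with known
ground truth.

**Mask.** A concave-down half-annulus whose thickness follows a
piecewise-linear profile of `u`: a genu-like anterior bulb (×1.4 of the
mid-body thickness by default), a thinner posterior midbody (×0.8), and
a splenium-like posterior bulb (×1.7). Only the AP topology matters for
the template, so no attempt is made at anatomical fidelity. The annulus
is drawn slightly larger than the nominal arch length and truncated by
vertical end caps at the anterior/posterior tips: a pure half-annulus
tip curves away from the grid and can leave an end column whose cell
center falls outside the mask, whereas the caps guarantee one solid
vertical span per column and an exact AP extent. Defaults: 460 px arch,
42 px base thickness, 0.5 mm/px in-plane, 4 mm sagittal spacing.

**Modalities.** Each modality is a strictly positive piecewise-linear
profile of `u`. The defaults encode the qualitative regional patterns
reported for the three modalities — LFB low in the rostrum/genu rising
to a posterior plateau; T1w/T2w highest anteriorly with a
posterior-midbody trough and partial splenial recovery; MWF slightly
elevated at the genu, dipping in the anterior body and rising through
the posterior midbody/splenium — which is exactly the configuration
under which the cross-modal sign structure (T1w/T2w vs LFB negative,
MWF vs LFB positive) is expected. Profiles are functions of `u` only:
dorsoventral contrast (e.g. a superior-vs-inferior splenium gradient) is
deliberately not modelled.

**Noise and samples.** Pixel noise is additive Gaussian, truncated to
the valid range ([0,1] for stain fractions, ≥0 for MRI), with SD
defaulting to 5% of the profile range — a mid-range choice for digitized
sections and averaged group maps, made once; no empirical noise model is
claimed. Histology modalities get 3 samples by default (mirroring a
typical set of post-mortem specimens); MRI modalities represent averaged
maps and get 1. Sample `i`'s profile is the shared profile plus a smooth
random field: a 3-harmonic random Fourier series with i.i.d. `N(0,1)`
coefficients scaled so the pointwise SD is *exactly* the configured
jitter (default 10% of the profile range). The stationary-variance
construction was chosen over spline interpolation of random knots, whose
between-knot variance dip would bias the cross-sample SD calibration by
up to ~10%. Histology samples render as white→dark-blue blends quantized
to 8 bits, so stained sections pass through the same grey-conversion and
quantization path as real images.

**Engineered correlations.** `make_correlated_pair()` exploits the
linearity of the ROI-truth operator: mixing two basis profiles with
Gram–Schmidt coefficients computed *in ROI space* yields a second
profile whose noise-free truth vector has any requested correlation with
the first, exactly, before shifting into a positive range (an affine
change that preserves the correlation). This gives the pipeline a
correlation-recovery oracle that is independent of the sampling code
path.

**What phantom-based tests do not show.** Passing them demonstrates that
the geometry, OD conversion, sampling and statistics are implemented
correctly and recover known structure through quantization and noise.
They do not validate performance against real tissue: staining
inhomogeneity, sectioning artefacts, registration error, partial-volume
effects at the callosal boundary and dorsoventral contrast are all
outside the phantom's model.

## Problem sizes and determinism

The default phantom (460 px arch) runs the full pipeline in about a
second. The simulation-heavy validation suites — correlation recovery at
ρ ∈ {−0.8, 0, 0.8} over 50 seeds, the 50-seed sign-structure check, and
the 200-sample jitter calibration — use a 300 px arch with 30 px base
thickness, the smallest geometry that keeps every circle radius
comfortably above the 1 px floor; per-ROI circles still contain ~20
pixels, and the template logic is identical in kind to the default.
All randomness flows from the integer seed in `phantom_spec()`;
regenerating with the same spec is byte-identical, and `run_pipeline()`
writes a provenance sidecar carrying the config hash and seed so any
output directory can be reproduced from scratch.

## Known limitations

- The parcellation follows the image axes; heavily rotated masks need
  prior re-orientation (a PCA pre-alignment is intentionally not applied
  by default, to keep the template identical to the one drawn on
  axis-aligned sections).
- The 46 × 2 grid is the default realization of the 92-ROI scheme;
  other factorizations of 92 are accepted, but rows must divide the
  local dorsoventral span sensibly (very thin masks will hit the radius
  floor).
- Histology and MRI inputs must already be co-registered to the mask;
  no registration is performed.
- The variance decomposition treats samples as exchangeable replicates;
  it is not a mixed-effects model and makes no inference about
  population variance components.
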