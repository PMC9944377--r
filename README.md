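# callomap

Cross-modal myelin mapping of the midsagittal corpus callosum.

## The problem

Several MRI contrasts are used as in vivo proxies for myelin — the
T1-weighted/T2-weighted ratio (T1w/T2w), the myelin water fraction (MWF)
from multi-echo T2, and quantitative susceptibility mapping (QSM) — while
histological luxol-fast-blue (LFB) staining of post-mortem tissue remains
the reference readout of myelin density. Deciding whether these modalities
actually measure the same thing requires sampling them on a *common*
anatomical scheme and comparing the resulting regional profiles
quantitatively. `callomap` implements that comparison for the corpus
callosum, the largest white-matter tract and the one with the
best-characterised antero-posterior fibre composition. It is aimed at
neuroimaging and neuropathology groups who have a segmented midsagittal
callosal mask, digitized stained sections and/or co-registered volumetric
maps, and want reproducible region-wise statistics across modalities.

## What it computes

1. **Witelson parcellation.** The binary midsagittal mask is divided into
   six macro-regions (rostrum/genu, rostral body, anterior midbody,
   posterior midbody, isthmus, splenium) by the normalized
   antero-posterior position `u` of each pixel center, with boundary
   fractions `{1/6, 1/3, 1/2, 2/3, 4/5}` of the callosal length
   (configurable). Intervals are half-open and anterior-closed.

2. **92-ROI template.** The AP extent is split into 46 columns; the local
   dorsoventral extent of the mask in each column is split into 2 rows;
   a circle (diameter 0.8 of the shorter cell side) is inscribed in each
   of the 92 cells. Because every bound is a fraction of the mask's own
   extents, the template adapts to individual callosal size.

3. **LFB optical density.** RGB sections are collapsed to grey
   (Rec. 709 luminance), inverted (`d = 255 − g`, darker stain = more
   myelin) and rescaled linearly to the 1–7 arbitrary-unit myelin scale:
   `density = 1 + 6 d / 255`. Colour-coded maps use 7 discrete bins from
   purple (lowest) to dark red (highest).

4. **Volumetric sampling.** For each 3D map, the two parasagittal slices
   at ±4 mm from the midline are extracted and averaged voxelwise; the
   resulting 2D map (and any histology density map) is averaged inside
   each of the 92 circles.

5. **Statistics.** Per modality the 92-ROI vectors are min–max rescaled
   to 1–7 (an affine map, so correlations are unaffected). The package
   reports, for multi-sample modalities, the variance decomposition
   `SD_regions` (mean over samples of the SD across the 92 ROIs) vs
   `SD_samples` (mean over ROIs of the SD across samples), and for each
   modality pair the Pearson correlation `r` (with `r²` and a two-sided
   p-value from `t = r√((n−2)/(1−r²))`, df = n−2) after averaging
   multi-sample modalities across samples.

A synthetic phantom module generates arch-shaped callosal masks, RGB
"stained sections" and 3-slice volumes with known per-ROI ground truth —
including pairs of modalities engineered to have an exact truth
correlation — so the whole chain can be validated end to end.

## Worked example

```r
library(callomap)

spec <- phantom_spec(seed = 7)           # default 3-modality phantom
mask <- generate_mask(spec)
mask
#> <callosal_mask> 266 x 476 px, 30693 foreground px, AP extent 460 px (230.0 mm)

ds  <- generate_modality_images(mask, spec)      # LFB x3, T1wT2w, MWF
tab <- rescale_to_units(sample_dataset(ds))      # 92-ROI table, 1-7 a.u.

correlate_all(tab, list(c("T1wT2w", "LFB"), c("MWF", "LFB"), c("T1wT2w", "MWF")))
#>  modality_a modality_b      r r_squared p_two_sided  n
#>      T1wT2w        LFB -0.796     0.633    2.74e-21 92
#>         MWF        LFB  0.739     0.546    4.12e-17 92
#>      T1wT2w        MWF -0.422     0.178    2.75e-05 92

variance_decomposition(tab, "LFB")
#> <variance_decomposition> LFB (3 samples x 92 ROIs)
#>   SD across regions: 1.734
#>   SD across samples: 0.561
```

The phantom's default profiles encode the qualitative regional patterns
of the three modalities (LFB low anteriorly and high posteriorly; T1w/T2w
highest in the rostrum/genu with a posterior-midbody trough; MWF elevated
at the genu and rising posteriorly). The output shows what those patterns
imply: T1w/T2w *anti*-correlates with histological myelin density over
the 92 ROIs, MWF correlates strongly and positively with it, and the
regional profile is far more variable along the callosum (SD 1.73) than
between samples at a fixed location (SD 0.56) — i.e. the pattern is
reproducible.

`run_pipeline(pipeline_config(phantom = spec, out_dir = "out"))` writes
the template and ROI tables (CSV), correlations and variance results
(JSON), colour-coded ROI maps and scatter plots (PNG), a provenance
sidecar with the config hash and seed, and a markdown report. The same
stages are scriptable via the `exec/callomap` command-line tool
(`phantom`, `parcellate`, `od`, `sample`, `correlate`, `run`
subcommands), so real masks, sections and NIfTI maps can enter at any
stage.

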