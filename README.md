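# proxygrow

Proxy-bridged hierarchical region growing for 3D CT organ segmentation.

`proxygrow` segments large abdominal organs (liver, spleen) in 3D CT
volumes without dense training data. The only supervision it needs is a
handful of annotated volumes to calibrate an organ intensity histogram;
everything else is classical image analysis made robust by a superpixel
proxy representation.

## Method

Given a preprocessed volume (HU clip to [-240, 360], per-slice 3×3 median
filter, volume z-normalization), the pipeline runs five stages:

1. **Key interval.** Pool a gray-value histogram of organ voxels from the
   calibration volumes (bin width 0.05 z-units) and take the convex hull of
   the smallest set of top-probability bins reaching 50% mass: the
   organ-typical intensity interval.
2. **Key slice.** Score every axial slice by its count of in-interval
   pixels; the argmax is the key slice — for a compact organ, its maximal
   cross-section.
3. **Seed localization.** Place a growing seed on the key slice: from the
   in-interval centroid (training-free), from a fixed oracle position, or
   from a small patch-level transformer classifier trained on synthetic
   slices (pure-R implementation with analytic, test-verified gradients).
4. **Proxy-bridged region growing.** Replace each slice by its SLIC
   superpixel *proxy image* (every pixel carries its superpixel's mean),
   which suppresses noise while preserving organ edges. Grow from the seed
   with an adaptive interval [μ − 3σ, μ + 3σ] computed from accumulated
   seed statistics, and propagate slice by slice (up, then down) until one
   of three termination rules fires: all seeds left the key interval, the
   grown mask has fewer than 10 voxels, or the mask center jumped more
   than 50 pixels.
5. **Refinement.** Morphological closing per slice (disk, r = 3) and over
   the volume (ball, r = 2).

Localization is scored by patch accuracy and expected Euclidean distance
(EED) in patch units; masks by DSC, JSC, recall, specificity, precision
and the 95th-percentile Hausdorff distance. A synthetic CT phantom
generator with exact ground truth (ellipsoidal organs, Gaussian noise,
optional vessel and adhesion confusers) makes every stage testable without
clinical data. See the vignette
(`vignettes/proxy-bridged-region-growing.Rmd`) for the full model,
parameter rationale and numerical conventions.

## Worked example

Segment the liver of a noisy synthetic phantom, calibrating the key
interval on three *other* phantoms and localizing the seed with the
training-free histogram backend:

```r
library(proxygrow)

ph  <- generate_phantom(phantom_config(), seed = 7)   # 64 x 128 x 128, noisy
pre <- preprocess_volume(ph$volume)

calib <- lapply(1:3, function(i) {
  p <- generate_phantom(phantom_config(), seed = 900 + i)
  list(volume = preprocess_volume(p$volume), mask = p$masks$liver)
})
iv <- key_interval(organ_histogram(calib))
iv
#> key_interval: [2.5, 3.05]

grid <- make_patch_grid(128, 128, 32)
seg <- segment_organ(pre, iv, backend_histogram(iv, grid), slic_params(50))
seg
#> organ_segmentation: key slice 34, 85954 voxels,
#>   stop: up=seeds_out_of_range down=seeds_out_of_range

evaluate_masks(seg$mask, ph$masks$liver)
#>         dsc      jsc    recall specificity precision hd95
#> 1 0.9940412 0.988153 0.9973299   0.9991767 0.9907741    1
```

The selected key slice (34) sits next to the true maximal cross-section
(33), both termination reasons are the intended "organ ended" rule, and
the mask agrees with ground truth at DSC 0.994 with a sub-2-voxel HD95.

Across a 20-phantom suite (seeds 601–620, oracle seeding, intervals
calibrated on separate phantoms) the mean DSC is 0.994 for the liver and
0.988 for the spleen. Disabling the proxy (`growth_config(use_proxy =
FALSE)`) drops the mean liver DSC to 0.556 (worst case below 0.001): raw
noisy pixels fragment the in-interval region, which is the point of the
proxy bridge. The same comparison is asserted in
`tests/testthat/test-acceptance.R`.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","proxygrow.R",package="proxygrow"))')" \
  phantom --out demo --seed 42
```

Subcommands: `phantom`, `key-slice`, `segment` (YAML run config),
`evaluate`, `train-locator`. Each accepts `--seed` and `--log-level`; see
`--help` per subcommand.

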