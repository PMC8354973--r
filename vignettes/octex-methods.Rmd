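---
title: "Texture-based OCT tissue classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based OCT tissue classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octex)
```

## The problem

Optical coherence tomography (OCT) images brain tissue at micrometer
resolution and could help a neurosurgeon tell metastatic tumor tissue from
healthy cortex at the resection margin, where MRI and ultrasound lack
resolution. Raw B-scans of healthy cortex look smooth and layered, vital
(living) tumor looks heterogeneous, and necrotic tumor tissue is pocked
with dark voids — but the differences are too subtle for reliable visual
classification. `octex` implements an automated chain that turns each
B-scan into a texture signature and classifies it:

1. **Segmentation** — median filtering, Canny edge detection and Otsu
   thresholding locate the air/tissue interface and the region of
   interest (ROI) beneath it.
2. **Tiling** — the B-scan is cut into non-overlapping 32 × 32 pixel
   sub-images; the top three tile rows are discarded (reconstruction
   artifacts at the image top) and a tile is kept only if at least 90% of
   its pixels lie inside the ROI.
3. **Texture features** — four families per tile, averaged over the
   B-scan: 256 local-binary-pattern (LBP) histogram bins, 7 gray-level
   run-length statistics (RL), 5 Haralick co-occurrence features (H) and
   8 Laws texture energies (L); 276 features in total.
4. **Classification** — optional z-score normalization, PCA
   dimensionality reduction, and a radial-basis-function SVM whose cost
   `c` and kernel width `gamma` are tuned by exhaustive grid search under
   tenfold cross-validation; accuracy is the fraction of correctly
   classified B-scans.

Because clinical scans cannot be redistributed, the package ships a
synthetic phantom generator that reproduces the geometry and the
qualitative class contrasts the pipeline relies on, providing ground
truth for every stage.

## Segmentation choices

The segmentation chain has several knobs the underlying procedure leaves
open; the defaults are:

* **Median filter 5 × 5.** Large enough to suppress speckle so the Canny
  stage sees a smooth interface, small enough not to displace the surface
  by more than a pixel or two at megapixel B-scan scale.
* **Canny:** Gaussian pre-smoothing with sigma = 2 px, Sobel gradients,
  non-maximum suppression over four quantized directions, hysteresis at
  0.1/0.2 of the maximum suppressed gradient. The fractions make the
  detector invariant to global intensity scaling.
* **Otsu on the median-filtered image.** The threshold maximizes
  between-class variance of the intensity histogram; splits are evaluated
  at occupied intensity levels and the reported threshold is the midpoint
  to the next occupied level (so a two-valued image thresholds strictly
  between its values). A constant B-scan has no threshold; the caller
  treats it as an empty ROI.
* **ROI fusion.** Per column the surface is the topmost Canny edge pixel,
  falling back to the topmost Otsu-foreground pixel; gaps (columns where
  neither exists) are bridged by linear interpolation between flanking
  columns and the profile is smoothed with a 9-column running median.
  The mask is then the largest 8-connected foreground component at or
  below the surface. This concrete fusion rule is what makes the chain
  robust when the edge map is discontinuous or detects multiple edges.
* **Tiling** is anchored at the image origin on a fixed 32-pixel grid
  with no overlap; trailing partial tiles are dropped. The "top three
  tile rows" are image rows 1–96 regardless of where the surface lies,
  because the artifacts they guard against (the DC component of the
  inverse FFT used in image formation) are fixed at the image top. On a
  full-ROI 1024 × 1024 B-scan this leaves (32 − 3) × 32 = 928 candidate
  tiles.

## Texture features

* **LBP**: radius-1, 8-neighbor codes (neighbor ≥ center, clockwise from
  the top-left neighbor as the most significant bit), histogrammed over
  the 30 × 30 interior pixels and normalized to sum 1. The raw 256-bin
  variant is used — uniform/rotation-invariant variants have at most 59
  bins and would not produce 256 features. Ties at equality are counted
  as 1, so a constant tile concentrates all mass in bin 255.
* **Quantization** for the co-occurrence and run-length families maps the
  tile's min–max range uniformly onto `min(16, number of distinct
  intensities)` levels. Capping at the number of distinct values makes a
  two-valued tile occupy two *adjacent* levels, which keeps contrast-type
  statistics on the natural integer scale and makes both families
  invariant under positive affine intensity maps.
* **RL**: run-length matrices along 0° and 90°, averaged, yielding
  Galloway's SRE, LRE, GLN, RLN, RP plus Chu's LGRE and HGRE — the
  canonical way to reach seven run-length statistics.
* **H**: symmetric co-occurrence matrices for offsets (0,1) and (1,0),
  averaged; features energy, contrast, correlation, homogeneity, entropy
  (natural log). Correlation is defined as 0 when a marginal variance
  vanishes (constant tile).
* **L**: the tile mean is removed, eight 5 × 5 separable Laws masks
  (E5L5, S5L5, R5L5, W5L5, E5E5, S5S5, R5R5, S5E5) are applied, and the
  mean absolute response over the 28 × 28 valid interior is the "texture
  energy". All masks are built from symmetric or antisymmetric vectors,
  so correlation vs convolution only flips signs and the energies are
  unambiguous.

The exact member statistics of the RL/H/L families are configurable;
the defaults above are the canonical reduced sets matching the family
sizes 7/5/8. Every family implementation is checked against an
independent brute-force oracle (per-pixel enumeration, explicit run
scanning, pairwise co-occurrence counting, direct 2-D convolution) to
1e-10 on random tiles.

## Statistical layer

Feature tables carry one row per B-scan (the mean of each feature over
the B-scan's kept tiles). Classification is always two-class: necrosis
vs healthy, vital tumor vs healthy, or both tumor classes pooled
("tumorous") vs healthy.

* **z-score** centers each feature to mean 0 / sd 1; zero-variance
  columns map to zero. Both the normalized and unnormalized paths are
  supported, as the grid search is run with and without it.
* **PCA** retains the smallest number of components reaching 95% of the
  variance by default.
* **Cross-validation** uses ten stratified folds at the B-scan level,
  mirroring a design in which all B-scan feature vectors are allocated to
  either training or test data. A `fold_level = "sample"` mode keeps all
  B-scans of one tissue sample in the same fold; B-scan-level folds are
  optimistic when scans from one sample land on both sides of the split,
  and the sample-level mode quantifies that.
* **No leakage:** z-score statistics and the PCA basis are fitted on the
  training rows of each fold and applied to the held-out rows. A global
  (deliberately leaky) mode exists only so tests can demonstrate that the
  two differ. Whether to refit per fold is a genuinely open choice; the
  per-fold default is the conservative one.
* **Grid search** covers cost `c` in decade steps over 1…1e16 and
  `gamma` over 1e-8…1e2 (17 × 11 = 187 points) with the fold assignment
  fixed across points; ties for the best accuracy resolve to the
  smallest `c`, then the smallest `gamma` (the least complex model). The
  result carries the full accuracy grid plus the region at or above a
  90% threshold, which is how such grids are read: a broad
  high-accuracy plateau is more trustworthy than a single spike.
* **Accuracy** is the overall fraction correct (the class imbalance in a
  6 + 4 collective is mild), averaged over folds, in percent.

The 15-subset sweep runs the grid search for every non-empty subset of
{LBP, RL, H, L}, with and without z-score, tabulating best accuracies
and the per-subset average across comparisons.

## The phantom generator

The generator emulates what the pipeline needs from real scans, not the
instrument physics:

* geometry: 1024 × 1024 B-scans by default (3.5 mm lateral field, 2 mm
  depth), surface line within rows 80–200, scaled proportionally at
  other sizes;
* a bright specular line at the air/tissue interface, near-noise-floor
  background above it;
* class texture below the surface — healthy: sinusoidal depth layering
  (period ≈ rows/12, amplitude 0.35); vital tumor: Gaussian-correlated
  heterogeneity (blob sigma 3 px, amplitude 0.6); necrosis: coarser
  heterogeneity (sigma 5 px) plus dark elliptical voids (≈ 25 voids per
  256² of tissue, radii 4–14 px, 85% reflectivity loss);
* multiplicative gamma speckle (shape 2, mean 1 — the standard
  multiplicative OCT speckle model);
* exponential depth attenuation (rate 3.3/rows per pixel, i.e. a 1/e
  depth of ≈ 0.6 mm at default geometry, consistent with ~2 mm
  penetration in brain tissue);
* log compression of reflectivity into a fixed 40 dB display range, as
  in processed OCT B-scans. This step matters: on linear intensities the
  speckle dynamic range defeats histogram thresholding, while
  log-compressed phantoms segment the way real displayed B-scans do.

Volumes interpolate the heterogeneity field smoothly along the stack and
redraw speckle per B-scan from seeds hashed from the master seed, so
adjacent B-scans correlate more than distant ones and any single B-scan
is reproducible in isolation. `texture_contrast` scales all
class-specific amplitudes: at 0 the classes are statistically identical
(pipeline accuracy falls to chance), at 1 (the default study condition)
they separate cleanly — the tests verify the monotone trend between.

A generated study mirrors a small surgical collective: 6 necrosis, 4
vital tumor and 4 healthy samples by default, with within-class jitter
of contrast and speckle shape and manifest percentages drawn to satisfy
the inclusion rule (≥ 60% of one tumor tissue, or ≥ 90% healthy).

What the phantoms do **not** model: coherent point-spread functions,
refraction, polarization, shadowing under voids, motion artifacts, and
real histological texture. Passing the end-to-end tests therefore shows
the chain is implemented correctly and can recover planted class
structure — it does not certify clinical accuracy on real scans, whose
texture statistics are unknown here.

## Problem sizes and numerics

The test and acceptance workloads run at reduced scale, chosen as the
smallest sizes at which every stage still operates in its intended
regime: end-to-end studies use 6 + 4 volumes of 64 B-scans at 256 × 256
(a 256² B-scan keeps ~30–40 valid tiles after the top-row rule), grid
searches in tests use 5 × 5 decade sub-grids of the full 17 × 11
lattice, and oracle-equivalence checks use 100 random tiles per family.
Full paper-scale geometry (1024 × 1024 × 1024 volumes, 187-point grids)
is available through the same interfaces.

Numerical conventions worth knowing: feature tables round-trip through
CSV at 17 significant digits; LBP histograms sum to 1 within 1e-9;
degenerate inputs (constant tiles, constant B-scans, empty ROIs,
single-class training folds) are defined cases, not crashes — constant
B-scans yield empty tile sets, B-scans with zero valid tiles are
excluded and logged, single-class folds are skipped with a warning.

## Known limitations

* B-scan-level folds overestimate accuracy relative to leave-sample-out
  validation when per-sample correlation is strong; both modes are
  provided.
* The phantom surface is a single-valued function of the lateral
  coordinate; real interfaces can fold or shadow.
* The RL/H/L member sets match the family sizes but the exact historical
  feature selections behind those counts are not recoverable from the
  source material; they are configurable.
* Accuracies obtained on phantoms say nothing quantitative about real
  tissue (see above).
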