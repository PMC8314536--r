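---
title: "ECV-guided LGE scar quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECV-guided LGE scar quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvlge)
```

## The problem

Late gadolinium enhancement (LGE) imaging identifies myocardial scar as
hyperintense tissue, and the standard semi-automatic quantification defines
scar as pixels whose signal intensity (SI) exceeds the remote-myocardium
mean by *n* standard deviations (the n-SD threshold), or as pixels above
half the maximal scar intensity (FWHM). Both work well for dense ischemic
scar. In non-ischemic disease the fibrosis is diffuse, patchy and
low-contrast, no single fixed *n* fits all patients, and manual delineation
is poorly reproducible and tends to overestimate the scar burden.

The method implemented here resolves the per-case ambiguity with a second,
co-registered piece of information: the extracellular volume fraction (ECV)
map at the mid-left-ventricular slice. ECV rises with replacement fibrosis
and is robust across scanners and field strengths, so the ECV value at the
*high-SI region of interest* — the spot on the LGE slice most likely to be
scar if any is — can arbitrate whether that region is real scar or bright
non-scar (artifact, partial volume, through-plane motion). The decision then
dictates how the n-SD threshold is chosen for that case.

## The decision rule and threshold optimization

1. **ECV mapping.** From pre/post-contrast T1 of myocardium and blood pool
   and the hematocrit:
   \[
   \mathrm{ECV} = (1-\mathrm{Hct})\,
   \frac{1/T1_{\mathrm{myo,post}} - 1/T1_{\mathrm{myo,pre}}}
        {1/T1_{\mathrm{blood,post}} - 1/T1_{\mathrm{blood,pre}}}.
   \]
   Computation is in fractions, reporting in percent. Non-physical pixel
   values (outside 0–100%) are flagged but deliberately not clipped:
   clipping would bias ROI means under noise.

2. **ROI detection.** On the mid-LV slice the myocardial ring (rasterized
   from epi/endocardial contours by pixel-center inclusion) is divided into
   60 angular sectors; every circularly contiguous arc of 5 sectors is
   scored by its mean SI. The minimal-mean arc is the remote ROI, the
   maximal-mean arc disjoint from it is the high-SI ROI. The commercial
   detector this emulates is proprietary, so the sector-arc extremal-mean
   procedure is this package's documented surrogate: it is deterministic,
   shift-invariant in SI, and parameterized only by the sector count and
   arc width (both configurable for sensitivity analysis, since the
   original ROI sizes are unreported).

3. **Classification.** The mean ECV over the high-SI ROI is compared with
   the cutoff (default 31.5%), boundary inclusive: at or above the cutoff
   the ROI is scar, below it non-scar. The ROI *mean* (rather than a single
   pixel) is used for robustness to map noise. A native-T1 criterion
   (default cutoff 1317 ms) is available as an alternative decision rule
   in `classify_roi()`, reflecting its use as a fallback when contrast
   cannot be given; it is not a separate full pipeline.

4. **Threshold selection, scar scenario.** The reference workflow picks
   *n* visually so that the thresholded area matches the scar extent on
   the ECV map. The automated surrogate maximizes the Dice overlap between
   the n-SD mask and the mask of myocardial pixels with ECV at or above
   the cutoff, over a grid of candidate *n* (default 1–20 in steps of 0.5;
   observed per-case thresholds span roughly 3–18 SD, and reported values
   are integers, so the default grid is finer than practice with headroom
   on both sides). Ties break toward the **larger** *n*: the more
   conservative (smaller) scar estimate, and deterministic.

5. **Threshold selection, non-scar scenario.** The smallest grid *n* whose
   mask highlights at most `nonscar_tolerance_px` pixels (default 0) of
   the high-SI ROI — "the closest threshold that does not highlight" the
   brightest region. If even the largest *n* fails, it is returned with a
   warning flag.

6. **Propagation and reporting.** The selected *n* is applied to every
   slice. By default remote statistics are re-estimated per slice
   (`per_slice_remote = TRUE`), which makes the masks invariant to
   per-slice SI rescaling — appropriate for signed PSIR reconstructions
   whose scale varies by slice; propagating the mid-slice absolute SI
   threshold is retained as an option because it is not documented which
   variant the original software used. In-slice connected components
   smaller than 5 pixels are removed (8-connectivity) as the automated
   stand-in for manual artifact erasure; the size is configurable since
   the original erasure was visual. Scar mass is pixels × pixel volume ×
   1.05 g/mL (the standard CMR myocardial density, which the source
   workflow does not state), scar percent is mass over LV mass, and the
   segmental report uses the AHA 17-segment model with pixel counts within
   the segment as the denominator (the segmental denominator is likewise
   not stated elsewhere). A case classified non-scar at the mid slice can
   still show scar after propagation when other slices contain
   supra-threshold lesions — an expected behavior of the method, not an
   error.

Inequality conventions are fixed for reproducibility where the field is
silent: strict `>` for n-SD masks, `>=` for FWHM, cutoff-inclusive `>=`
for the ECV criteria. Remote SD uses the sample (n−1) estimator because
reference ROIs are small.

## Comparator methods

* **Fixed n-SD** (`run_quant(..., method = "nsd", n = 2)` for the classic
  low threshold): same machinery with a fixed multiple. The 2-SD setting
  doubles as the package's emulation of permissive manual over-reading in
  benchmark experiments.
* **FWHM** (`method = "fwhm"`): threshold at half the maximal SI within
  the high-SI seed ROI. The baseline-corrected variant,
  \(\mu_{remote} + 0.5\,(S_{max}-\mu_{remote})\), is the default in the
  pipeline because the synthetic (and PSIR) SI scale has a nonzero remote
  offset, under which the naive \(S_{max}/2\) threshold falls below the
  remote level and floods the mask. FWHM propagates the mid-slice absolute
  threshold rather than re-detecting a seed per slice: per-slice maxima on
  lesion-free slices are pure noise and would hallucinate scar.

## The phantom generator

`generate_phantom()` builds the study conditions every test runs under: a
ring-shaped myocardium (endocardial radius 16 mm, epicardial 26 mm, 1 mm
pixels, 8 slices of 8 mm, values chosen as typical adult short-axis
geometry), remote SI 100 with nominal SD 10, and additive Gaussian noise
whose SD defaults to the nominal remote SD — so remote pixels are
N(100, 10²) by default, while `noise_sd = 0` produces exactly flat images
for analytic tests. Gaussian noise is a stated simplification: PSIR images
are signed, so no Rician magnitude floor is modeled.

* **Non-ischemic mode** places Gaussian-bump fields at random positions in
  the mid-wall/epicardial half of the ring and thresholds the field to the
  target pixel count: irregular patchy blobs, the typical non-ischemic
  pattern. Per-patch SI contrast *k* (in nominal SDs) defaults to a
  uniform draw over 3–18, matching the range of per-case thresholds seen
  in practice (per-lesion SI distributions are not published, so the
  threshold range is the anchor). Per-patch ECV defaults to a uniform
  draw over 31.5–40.6% — the reported non-ischemic high-SI ROI band
  (34.0 ± 6.6%) truncated at the cutoff for true-scar patches.
* **Ischemic mode** grows one contiguous wedge subendocardium-first inside
  a random angular window (default 90°; widen to ~150° for scar fractions
  above ~25% of the myocardium), with ECV drawn from 49.1–54.3%, the
  reported ischemic interquartile band around 52.2%.
* **Clean mode** has no lesions.

Only the mid slice carries the T1/ECV pair, mirroring single-slice mid-LV
T1 acquisition. The T1 pair is synthesized by fixing native myocardial T1
(1200 ms), blood T1 (1900/380 ms) and hematocrit (0.42), then solving the
ECV formula per pixel for post-contrast myocardial T1 — guaranteeing that
`compute_ecv()` reproduces the specified ECV map to machine precision,
which is itself one of the package's invariant tests. The myocardium used
for lesion placement is rasterized from the emitted contours, so truth
masks are exact subsets of the contour-derived masks used downstream.

What the phantom does *not* emulate: real cardiac anatomy, k-space/PSIR
reconstruction physics, surface-coil shading, through-plane motion, or
LGE–T1 misregistration. Passing phantom tests therefore demonstrates the
correctness and internal consistency of the algorithms under controlled
contrast and noise, not clinical performance on real images.

## Worked diagnostics from printed summaries

`table_from_summary()` and `table_from_rates()` reconstruct the 2×2 table
implied by a printed cohort summary (total N, class sizes, sensitivity
and/or specificity, test-positive count) with `tp = round(sens × n_pos)`
etc.; an implied negative cell is an inconsistency error naming the cell.
`diag_stats()` keeps full precision internally and rounds to one decimal
in percent only for display, matching the usual reporting convention.

## Statistical components

* **ROC** (`roc_curve()`): curve at every unique score, trapezoidal AUC
  (equal to the Mann–Whitney pair statistic with half credit for ties —
  verified against brute-force pair counting in the tests), optimal cutoff
  by Youden's J. The source analyses say only that the cutoff came "from
  the ROC curve"; Youden's J is the standard choice and ties resolve
  toward higher sensitivity, then the lower threshold. An auto direction
  flips the rule when the marker is inverted.
* **Lin's CCC** (`lin_ccc()`): population (1/n) moments per Lin's original
  definition — documented because sample-moment variants differ slightly.
  Interpretation bands: < 0.40 poor, 0.40–0.75 fair to good, > 0.75
  excellent.
* **Bland–Altman** (`bland_altman()`): bias ± 1.96 × sample SD of the
  paired differences.
* Wilcoxon tests, chi-square, Spearman correlation and simple linear
  regression used in cohort analyses are ordinary `stats` routines
  (`wilcox.test`, `chisq.test`, `cor.test`, `lm`) and are intentionally
  not re-implemented here.

## Numerical and degenerate-input policy

* Remote SD of exactly 0 (noise-free or constant ROI) is a degenerate
  threshold error in `nsd_mask()`; propagation falls back to the absolute
  threshold with a warning when a slice's remote ROI is unusable.
* Two empty masks have Dice 1 (identical), one empty mask Dice 0.
* If no candidate n-SD mask contains any pixel in the scar scenario, the
  smallest grid *n* is returned with a warning flag; the mirrored
  non-scar degenerate case returns the largest.
* All-equal SI in ROI detection resolves by the documented tie-break
  (lowest starting sector).
* Randomness is confined to `generate_phantom()` and is fully determined
  by the spec seed; the analysis pipeline itself is deterministic, and
  generation restores the caller's RNG state.

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run on 96×96×8 phantoms at the
default geometry (ring of ~1.3×10³ pixels per slice), with populations of
50 patchy and 20 ischemic phantoms for the inter-method comparisons and 20
phantoms for the threshold-monotonicity sweep; unit tests use a reduced
64×64×4 variant of the same geometry. These sizes were chosen as the
smallest at which the arc-based ROI detector and the patch statistics
behave like their full-resolution counterparts.

## A small end-to-end example

```{r example}
spec <- phantom_spec(mode = "non-ischemic", n_patches = 2, patch_contrast_k = 8,
                     target_scar_fraction = 0.05, scar_ecv_pct = 58.3, seed = 42)
ph <- generate_phantom(spec)
ph$truth_scar_percent

report <- suppressWarnings(
  run_ecv_guided(ph$lge, ph$contours, compute_ecv(ph$t1pair)))
report
```

The report's scenario, selected threshold and global scar percent are the
quantities a reader would compare against the ground truth above.

## Known limitations

* The visual n-SD choice is replaced by Dice maximization against the
  supra-cutoff ECV mask; this is a surrogate, and other overlap metrics
  could be plugged in behind `agreement_metric`.
* ECV classification uses the ROI mean; a strongly diluted ROI (small
  lesion inside a large arc) can fall below the cutoff even when the
  lesion's own ECV is above it, which lowers the detection rate on subtle
  lesions — consistent with the method's conservative behavior on patchy
  disease.
* T1 fitting, motion correction and contour segmentation are out of scope:
  T1 maps and contours are inputs.
* Segment 17 (apical cap) is assigned only when a cap slice is explicitly
  flagged; short-axis-only stacks rarely contain one.
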