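# ecvlge

Extracellular-volume-guided late gadolinium enhancement (LGE) scar
quantification for short-axis cardiac MRI.

## The problem

Quantifying myocardial scar on LGE images means choosing a
signal-intensity threshold. The usual semi-automatic rule — scar is
everything more than *n* standard deviations above the remote-myocardium
mean (the *n*-SD threshold), or above half the maximal scar intensity
(FWHM) — works for dense ischemic infarcts but breaks down on the diffuse,
patchy, low-contrast fibrosis of non-ischemic cardiomyopathy, where no
fixed *n* fits every patient and manual delineation is poorly reproducible
and tends to overestimate.

`ecvlge` implements an ECV-guided analysis that uses the co-registered
extracellular volume fraction (ECV) map at the mid-left-ventricular slice
to drive a per-case choice of *n*:

1. compute the ECV map from pre/post-contrast T1 and hematocrit,
   `ECV = (1 − Hct) · ΔR1_myo / ΔR1_blood` with `ΔR1 = 1/T1_post − 1/T1_pre`;
2. auto-detect the remote and high-SI regions on the mid-LV LGE slice
   (extremal-mean angular arcs of the myocardial ring);
3. classify the high-SI ROI as **scar** when its mean ECV ≥ cutoff
   (default 31.5 %), otherwise **non-scar**;
4. *scar scenario*: pick the *n* (grid 1–20, step 0.5) whose *n*-SD mask
   best matches (Dice) the supra-cutoff ECV area;
   *non-scar scenario*: pick the smallest *n* that does **not** highlight
   the high-SI ROI;
5. propagate the selected threshold to all slices (remote statistics
   re-estimated per slice), filter small components, and report scar mass
   (g), scar percent of LV mass, and AHA 17-segment percentages.

Fixed *n*-SD and FWHM comparators, ROC/Youden cutoff derivation, Lin's
concordance correlation, Bland–Altman limits of agreement, and a synthetic
short-axis phantom generator (patchy non-ischemic or wedge-shaped ischemic
lesions with co-registered ground-truth ECV/T1 maps) are included, so the
whole pipeline is testable end to end without any image download.

Who it is for: imaging researchers who want a reproducible, scriptable
reference implementation of ECV-guided LGE quantification, comparator
thresholding experiments, or the agreement statistics around them.

## Worked example

```r
library(ecvlge)

spec <- phantom_spec(mode = "non-ischemic", n_patches = 2, patch_contrast_k = 8,
                     target_scar_fraction = 0.05, scar_ecv_pct = 58.3, seed = 42)
ph <- generate_phantom(spec)
ph$truth_scar_percent
#> [1] 5.015198

report <- suppressWarnings(
  run_ecv_guided(ph$lge, ph$contours, compute_ecv(ph$t1pair)))
report
#> <ecv_guided_report> high-SI ROI ECV 37.6% -> scar (cutoff 31.5%)
#>   selected threshold: 5.0-SD (mid-slice Dice 1.000)
#>   global scar: 4.44 g / 88.44 g LV = 5.02%
```

Reading: the brightest region of the mid-LV slice has a mean ECV of 37.6 %,
above the 31.5 % cutoff, so it is judged scar; the 5-SD threshold best
reproduces the supra-cutoff ECV area (Dice 1.000); after propagation and
filtering the global scar burden is 5.02 % of an 88.4 g left ventricle —
against a simulated truth of 5.02 %.

Diagnostic arithmetic from printed cohort summaries works the same way:

```r
diag_stats(table_from_summary(n_total = 80, n_positive = 50,
                              n_test_positive = 49, sensitivity = 0.90))
#> <diag_stats> sens 90.0%, spec 86.7%, PPV 91.8%, NPV 83.9%
```

A thin command-line wrapper with `simulate`, `ecv`, `quantify` and
`benchmark` subcommands ships in `inst/cli/ecvlge.R`.

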