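Package: ecvlge
Title: Extracellular-Volume-Guided Late Gadolinium Enhancement Scar Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies left-ventricular myocardial scar on short-axis late
    gadolinium enhancement (LGE) cardiac MRI using extracellular volume
    fraction (ECV) criteria to drive per-case optimization of the n-SD
    signal-intensity threshold. Includes per-pixel ECV map computation from
    pre/post-contrast T1 and hematocrit, contour-based myocardial ring masks,
    automatic remote and high-signal-intensity ROI detection, AHA 17-segment
    labeling, comparator thresholding methods (fixed n-SD, full-width
    half-maximum), scar mass and percent reporting, diagnostic and agreement
    statistics (ROC with Youden cutoff, Lin's concordance correlation,
    Bland-Altman limits of agreement), and a synthetic short-axis phantom
    generator with ground-truth lesions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
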