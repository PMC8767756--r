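Package: vesselforge
Title: Ensemble Pixel Classification for Coronary Vessel Segmentation in X-Ray Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Segments coronary vessels in gray-scale X-ray coronary angiography
    frames by per-pixel classification. Builds a multi-scale feature stack
    (Frangi, matched-filter, smoothed gradient-magnitude and Gabor responses
    summarized by Z-profile statistics, a vessel confidence measure, and
    granulometric residues of a top/bottom-hat enhanced image), optionally
    augmented with activation maps from a small encoder-decoder network, then
    balances vessel and background pixels with a four-stage under-sampling
    cascade (uniform lattice, intensity-based, Tomek links, cluster centroids)
    before training gradient-boosted trees or a cascade forest. Includes a
    synthetic angiogram generator for end-to-end testing, Otsu binarization
    with morphological post-processing, the standard segmentation metrics, and
    permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    xgboost,
    ranger,
    igraph,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
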