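Package: gazecompare
Title: Comparing Human Visual Attention and Classifier Saliency on Facial Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing human visual attention, measured by
    fixation-level eye tracking, with the occlusion-sensitivity saliency maps
    of an image classifier. Builds duration-weighted gaze heat maps from
    Tobii-style fixation exports, subtracts group-level common face-viewing
    attention, binarizes attention maps at dual quantile thresholds, and
    compares masks with the intersection-over-union metric. Per-stimulus
    effects carry bootstrap standard errors and are pooled across stimuli with
    a DerSimonian-Laird random-effects model. Includes cohort accuracy
    contingency analysis, area-of-interest fixation timing metrics, a
    pluggable classifier adapter with occlusion saliency, and a synthetic
    study generator so the full pipeline can be exercised without access to
    restricted facial image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    metafor,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
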