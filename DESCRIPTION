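Package: hepalign
Title: Mask-Driven Affine Registration of 3D Liver Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated two-step affine registration for longitudinal
    3D liver imaging. Liver masks (from a pluggable segmenter with a
    classical threshold fallback) drive a 12-parameter affine optimization
    over a multi-resolution pyramid; the estimated transform maps the
    entire moving series onto the static grid. Includes Jaccard overlap,
    mutual information and landmark intra-observation distance metrics, an
    emulator of manual slice-landmark plus rigid registration for
    comparison studies, and a synthetic liver phantom generator with exact
    affine ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
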