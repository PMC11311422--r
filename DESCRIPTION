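Package: fundusbf
Title: Luminosity and Contrast Enhancement of Fundus Images with Binomial Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhancement of color retina (fundus) photographs affected by
    uneven illumination and boundary reflection. The background brightness of
    each color channel is estimated inside the eye region with a
    boundary-aware, per-pixel renormalized binomial filter; the luminosity of
    every pixel is then levelled to a common baseline, contrast is improved by
    a constrained region-wide histogram equalization, and color is restored
    from stored per-pixel channel ratios. Includes the evaluation metrics
    (mean CIELAB lightness and a three-resolution global contrast factor),
    Gaussian and histogram-median baseline filters for benchmarking, and a
    deterministic synthetic fundus phantom generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
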