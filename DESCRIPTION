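Package: netdamage
Title: Quantifying Physical Damage to Insecticidal Bed Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the physical condition of long-lasting
    insecticidal bed nets (LLINs) by three complementary methods: the WHOPES
    field protocol that bins holes into thumb/fist/head size classes and
    imputes circle midpoint areas, image analysis of net-side photographs
    (scale calibration, binarization, connected-component labelling, and
    per-hole shape measurement), and ruler-style elliptical measurement.
    Includes a synthetic net-image generator with planted elliptical holes
    and ground truth for validation, paired-method comparison statistics
    (Wilcoxon signed rank, Spearman correlation, simple linear regression,
    Kruskal-Wallis, Bland-Altman limits of agreement), and spatial analysis
    of hole locations via composite rasters and Getis-Ord Gi* hot spot
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
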