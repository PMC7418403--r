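Package: micromorph
Title: Microglial Burden, Activation and Dystrophy Morphometry for DAB-Stained Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microglia in DAB-stained, haematoxylin
    counterstained brightfield sections. Implements random-square region
    sampling, HSV colour-threshold segmentation of DAB-positive cells with a
    minimum-diameter exclusion, per-cell morphometry (areal fraction burden,
    circularity, perimeter), a skeleton-based operationalisation of an ordinal
    1-5 microglial dystrophy score with rod-shaped and hypertrophic presence
    calls, and hierarchical nonparametric group comparisons (Kruskal-Wallis
    with Dunn post hoc, rank-sum, paired Wilcoxon signed-rank and Fisher exact
    tests) with significance heat-map matrices. A synthetic histology module
    renders section images with planted cells of known morphology class,
    areal fraction and dystrophy severity so the full pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
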