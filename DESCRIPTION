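Package: silform
Title: Chemical Formula Degeneracy and Stable Isotope Labeling Constraints
    for Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the degeneracy of chemical space in accurate-mass
    metabolomics: enumerates all CHNOPS chemical formulae within a ppm mass
    window (unfiltered brute force or with configurable element-ratio and
    ring/double-bond-equivalent heuristics), simulates exact isotopologue
    distributions by per-element multinomial convolution, and compares how
    natural isotopic-abundance peak ratios versus stable-isotope-labeling
    derived C and N atom counts reduce the number of candidate formulae.
    Also identifies metabolites and chemical formulae unique to single
    metabolic pathways in a pathway database, and provides seeded synthetic
    generators for formula libraries, pathway databases, and noisy
    measured features.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
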