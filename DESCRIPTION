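Package: clonalpair
Title: Clonal Relatedness Testing for Pairs of Tumor Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for deciding whether two tumor lesions from the
    same patient arose from a common ancestral clone. Implements marker
    averaging and circular-binary-segmentation-style partitioning of
    copy-number log-ratio profiles, chromosome-arm gain/loss calling against a
    median-absolute-deviation threshold, an array quality gate, a
    frequency-weighted copy-number concordance statistic benchmarked against
    cross-patient lesion pairs, a likelihood-ratio test for clonality from
    shared somatic mutations with reference-cohort marginal probabilities,
    derivation of copy-number profiles from tumor/normal exome coverage with
    LOESS GC correction, a believe-the-positive pair classification rule
    (clonal / equivocal / independent), clonal-versus-private mutation
    spectrum tabulation, and a synthetic-cohort generator for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
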