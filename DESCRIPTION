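Package: rrfews
Title: Two-Stage Epigenome-Wide Association Analysis with Recursive
    Random-Forest Feature Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-stage epigenome-wide association studies of
    Illumina 450K-style DNA methylation data. Stage 1 reduces hundreds of
    thousands of CpG probes to a small candidate set by recursive Random
    Forest elimination: forests with balanced per-class bootstrap sampling
    are grown repeatedly, probes are ranked by mean-decrease-Gini
    importance, the bottom half is discarded, and the iteration minimising
    the focal-class out-of-bag misclassification rate (or the one before
    its first increase) is selected. Stage 2 tests the selected CpGs with
    covariate-adjusted logistic regression on M-values under Bonferroni
    control, and an independent-cohort replication filter checks direction
    and nominal significance. Includes quality-control filters (detection
    p-value, sex-chromosome and SNP-probe exclusion), beta/M-value
    transforms, a location-scale batch adjuster, reference-based cell-type
    deconvolution by constrained least squares, and a synthetic 450K-like
    data generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
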