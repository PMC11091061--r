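Package: amfpheno
Title: Quantifying Arbuscular Mycorrhizal Colonization from Instance
    Segmentations with Hierarchical Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput phenotyping of arbuscular
    mycorrhizal fungus (AMF) colonization in plant roots from
    instance-segmentation output. Parses and tiles polygon annotations in
    the VGG Image Annotator export dialect, aggregates per-image instance
    records into slide-level colonization phenotypes (percent
    colonization, count density, average structure size, proportion of
    nutrient-exchange structures), fits two-level mixed linear models
    (random intercept, optional random slope) and derives
    variance-partition diagnostics (intraclass correlation, proportional
    change in variance, variance partition coefficients, marginal and
    conditional R-squared), runs a lasso/forward/likelihood-ratio
    variable-selection workflow with Tukey region contrasts, evaluates
    instance segmentations by COCO-style average precision, and simulates
    hierarchical datasets with known parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
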