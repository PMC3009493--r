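Package: sfssclass
Title: Simultaneous Feature and Sample Selection for miRNA-Based Tumor
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiclass tumor-of-origin classification from miRNA expression
    profiles by the SFSSClass approach: SAMBA-style biclustering of the
    standardized expression matrix selects features (miRNAs) and samples
    (tissues) simultaneously, a literature-derived bipartite cancer-miRNA
    association network marks biclusters with experimental support, and the
    reduced training set is classified with the uncorrelated shrunken
    centroid (USC) classifier, whose shrinkage (delta) and correlation (rho)
    thresholds are tuned by repeated stratified fourfold cross-validation.
    Includes readers and writers for GCT expression matrices, CLS label
    files and network edge tables, seeded synthetic-data generators for
    every stage, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
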