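Package: lcmsqc
Title: Quality Control and Cleaning of Untargeted LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition cleaning of untargeted LC-MS metabolomics
    feature tables exported in the Workflow4Metabolomics (W4M) triplet
    format (dataMatrix, sampleMetadata, variableMetadata). Implements
    noise imputation of missing intensities, removal of unwanted
    between-batch variation anchored on repeated pooled-QC injections
    with scree-based selection of the number of components, retention
    time region-of-interest and blank-based contaminant filtering,
    species fingerprint construction by a minimum detection rule, and
    Mahalanobis-distance validation of individual samples. Includes a
    model of a factorial field-sampling design with a blocked injection
    sequence and a synthetic-data generator that emulates its
    statistical structure (sparse species fingerprints, pooled QCs,
    blank contaminants, multiplicative batch effects) so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
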