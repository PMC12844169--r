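Package: normsvr
Title: QC-Driven Drift and Batch Correction for Single-Cell ToF-SIMS
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage correction of single-cell time-of-flight secondary ion
    mass spectrometry (ToF-SIMS) feature tables: per-feature Z-score
    normalization against quality-control (QC) sample statistics, followed by
    support-vector-regression modelling of the technical-error surface over
    acquisition covariates (acquisition order, collection region, batch),
    fitted on QC samples only and subtracted from every sample. Includes the
    conventional total-ion (total area per pixel) normalization as a baseline,
    a diagnostic suite (relative standard deviation distributions, principal
    component analysis, Pearson and Spearman correlation reports, LOESS ion
    trends, silhouette-based batch-mixing scores), and a synthetic-data
    generator producing ToF-SIMS-like single-cell tables with known region,
    batch and drift ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    cluster,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
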