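Package: methtempo
Title: Temporal DNA Methylation Dynamics Across Tissues and Their
    Association with Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for reduced-representation bisulfite
    sequencing (RRBS) time-course data. Ingests per-CpG methylation count
    tables, filters sites by coverage and variability, annotates CpG sites
    to strand-aware TSS, promoter, gene-body and 10 kb flank regions,
    tests per-site differential methylation with binomial likelihood-ratio
    models (pairwise time contrasts and an omnibus time effect with a
    temperature covariate), quantifies cross-tissue concordance of
    z-scored methylation change, fits a simplified negative-binomial
    time-effect model to pooled gene expression counts, and associates
    methylation change with expression change through quadrant assignment
    and Fisher's exact enrichment of TSS versus downstream-flank regions.
    Includes a fully seeded synthetic-data generator with ground truth for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
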