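Package: strataXY
Title: Sex Chromosome Differentiation, Y Degeneration, and Dosage
    Compensation Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects sex-linked regions and evolutionary strata from
    male/female genomic coverage and SNP density with a bootstrapped
    autosomal null, identifies sex-specific k-mers (Y-mers) within and
    across species, quantifies Y gene-activity decay via allele-specific
    expression at heterozygous sites, and tests for chromosome-wide
    dosage compensation from male/female expression contrasts. Ships a
    synthetic XY-system simulator with ground truth (pseudoautosomal
    region, young stratum with elevated X-Y divergence, old degenerate
    stratum with large-scale Y loss) for calibration and parameter
    recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
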