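Package: trioCAPS
Title: Trio-Based Introgression Mapping, CAPS Marker Design and Nodule
    Occupancy Genotyping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising plant introgression lines and the
    rhizobial strains occupying their nodules. Assigns parental origin to
    variants from a donor/recipient/line trio VCF, classifies variants
    against gene models (UTR/exon/intron/flank), delineates donor-derived
    chromosomal blocks and summarises their span and gene content.
    Designs and validates CAPS (cleaved amplified polymorphic sequence)
    markers by in-silico PCR, IUPAC-degenerate restriction-site scanning
    and digest-fragment prediction. Classifies per-nodule PCR/digest
    assays into occupancy categories, aggregates per-group percentages
    and provides the accompanying count statistics. A synthetic-data
    generator produces trio VCFs with planted donor blocks, gene models,
    marker template pairs with a planted discriminating site, and nodule
    assay tables with known category proportions, so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, VariantAnnotation, Visualization
RoxygenNote: 7.3.3
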