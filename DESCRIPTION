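Package: srnaplast
Title: Wound-Responsive Small RNA Loci and Transgenerational Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for small-RNA sequencing studies of
    transgenerational plasticity. Calls small-RNA loci as merged coverage
    islands from mapped reads, classifies them into miRNA, dicer-derived
    siRNA size classes and non-dicer sRNA by read-length composition,
    annotates tRNA-derived fragments (tRFs) by their position relative to
    the anticodon, screens loci for wound-responsive abundance shifts with
    negative-binomial likelihood-ratio tests (class-stratified FDR, nested
    maternal-line designs for offspring generations), and fits the
    association models that link sRNA plasticity to differentially
    methylated regions and differentially expressed genes. A synthetic-data
    module generates annotations, reads, count matrices and DMR/DEG tables
    with planted effects so that every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
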