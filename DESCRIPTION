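Package: budmetrics
Title: Digital Bud Phenotyping and Trait Genetics for Tea Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scanner-image morphometrics and downstream trait genetics for
    tea (Camellia sinensis) apical buds. Segments buds from dark-background
    flatbed scans and measures calibrated length, width, perimeter and area;
    computes germplasm diversity statistics (coefficient of variation,
    Shannon-Wiener index, broad-sense heritability from clonal replicates);
    clusters accessions on trait means; screens genes whose expression tracks
    bud size across extreme accessions (Pearson correlation with a
    fold-change filter); and builds merged candidate intervals around
    multi-trait association signals with gene annotation and lead-SNP
    genotype stratification. A synthetic-data module generates scanner
    scenes with closed-form ground truth, replicate phenotype tables,
    expression matrices with planted trait-linked genes, and association
    scans with planted peaks, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    grDevices,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
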