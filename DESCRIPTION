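Package: freebed
Title: Convert TCGA-Style Cancer Genomics Files to a One-Based Free BED Repository
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ETL toolkit that transforms TCGA-style level-2/3 cancer
    genomics files of six experiment types (copy number segments, DNA
    methylation probes, somatic mutation MAF tables, miRNA-seq and RNA-seq
    V1/V2 quantifications) into a "free" BED format: four mandatory columns
    (chrom, chromStart, chromEnd, strand) with one-based closed coordinates
    plus an unlimited schema-defined attribute tail. Records can also be
    written as CSV, GTF, JSON and XML. Missing genomic coordinates and
    strands are recovered through four local ID-mapping chains (Entrez Gene
    coordinates, HGNC symbol to Entrez, UCSC transcript to Entrez, miRBase
    miRNA loci). Clinical and biospecimen documents are flattened to
    attribute-value .meta files, and outputs are laid out in an
    aliquot-oriented repository with header.schema and metadata-dictionary
    side files. A deterministic synthetic-cohort generator emulates the
    source directory tree so the full pipeline runs without any download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    xml2,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
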