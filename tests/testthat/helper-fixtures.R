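# Shared in-code fixtures: random barcodes, a tiny hand-built annotation
# store, and random record sets for round-trip properties.

random_barcodes <- function(n) {
  pick <- function(chars, k) {
    replicate(n, paste(sample(chars, k, replace = TRUE), collapse = ""))
  }
  an <- c(0:9, LETTERS)
  dg <- as.character(0:9)
  sprintf("TCGA-%s-%s-%s%s-%s%s-%s-%s",
          pick(an, 2), pick(an, 4), pick(dg, 2), pick(LETTERS, 1),
          pick(dg, 2), pick(LETTERS, 1), pick(an, 4), pick(dg, 2))
}

tiny_store <- function() {
  annotation_store(
    entrez_coords = data.frame(
      entrez_id = c("100", "200"),
      chrom = c("chr1", "chr2"), start = c(1000L, 5000L),
      end = c(2000L, 9000L), strand = c("+", "-"),
      stringsAsFactors = FALSE),
    symbol_to_entrez = data.frame(
      symbol = c("GENE1", "GENE2", "ORPHAN"),
      entrez_id = c("100", "200", "999"),
      stringsAsFactors = FALSE),
    ucsc_to_entrez = data.frame(
      ucsc_id = c("uc001aaa.3", "uc002bbb"),
      entrez_id = c("100", "200"),
      stringsAsFactors = FALSE),
    mirna_coords = data.frame(
      mirna_id = c("hsa-mir-21", "hsa-mir-7", "hsa-mir-7"),
      chrom = c("chr17", "chr1", "chr2"),
      start = c(59841266L, 100L, 700L),
      end = c(59841337L, 171L, 771L),
      strand = c("+", "+", "-"),
      stringsAsFactors = FALSE)
  )
}

# Random but schema-conforming record set; floats carry at most 6
# significant digits (the serializers' rendering precision).
random_records <- function(schema, n, na_rate = 0.1) {
  chrom <- sample(c("chr1", "chr2", "chr10", "chrX", "chrM"), n, replace = TRUE)
  start <- sample.int(1e6, n, replace = TRUE)
  end <- start + sample.int(5000, n, replace = TRUE)
  strand <- sample(c("+", "-", "*"), n, replace = TRUE)
  attrs <- lapply(seq_len(nrow(schema$columns) - 4L), function(j) {
    kind <- schema$columns$kind[j + 4L]
    x <- switch(kind,
      integer = sample.int(10000, n, replace = TRUE),
      float = signif(stats::runif(n, -100, 100), 6),
      string = sprintf("val_%d", sample.int(500, n, replace = TRUE)),
      char = sample(c("Y", "N"), n, replace = TRUE))
    if (na_rate > 0) x[stats::runif(n) < na_rate] <- NA
    x
  })
  names(attrs) <- setdiff(schema$columns$name,
                          c("chrom", "chromStart", "chromEnd", "strand"))
  bed_records(chrom, start, end, strand,
              as.data.frame(attrs, stringsAsFactors = FALSE), schema)
}

records_df <- function(records, schema) {
  df <- as.data.frame(records)[, c("seqnames", "start", "end", "strand")]
  df <- data.frame(lapply(df, as.character), stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(records))
  cbind(df, data.frame(lapply(mc, as.character), stringsAsFactors = FALSE))
}

# Convert one generated cohort and return everything downstream tests need.
convert_fixture_cohort <- function(seed = 11, n_patients = 2,
                                   miss_fraction = 0,
                                   formats = "bed", types = NULL) {
  spec <- cohort_spec(seed = seed, n_patients = n_patients,
                      miss_fraction = miss_fraction,
                      types = types %||% c("cnv", "dnamethylation", "dnaseq",
                                           "mirnaseq", "rnaseq", "rnaseqv2"))
  root <- tempfile("cohort")
  gen <- generate_cohort(spec, root)
  jobs <- lapply(spec$types, function(t) {
    list(source = file.path(root, "tcga_original", "BRCA"), tumor = "BRCA",
         type = t, formats = formats,
         annotations = file.path(root, "annotations"),
         out = file.path(root, "out"))
  })
  report <- run_convert(jobs, quiet = TRUE)
  list(spec = spec, root = root, out = file.path(root, "out"),
       gen = gen, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
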