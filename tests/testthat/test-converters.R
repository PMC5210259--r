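expect_report_conserves <- function(res) {
  expect_identical(res$report$rows_in,
                   res$report$records_out + res$report$dropped)
}

test_that("CNV segments map to starless records and bad rows are dropped", {
  rows <- data.frame(Sample = "s", Chromosome = c("3", "3", "X"),
                     Start = c(1000, 8000, 100), End = c(5000, 2000, 900),
                     Num_Probes = c(52, 5, 7),
                     Segment_Mean = c(-0.31, 0.1, 0.2),
                     check.names = FALSE, stringsAsFactors = FALSE)
  res <- convert_records(rows, "cnv")
  expect_identical(res$report$rows_in, 3L)
  expect_identical(res$report$dropped, 1L)  # end < start
  expect_report_conserves(res)
  df <- records_df(res$records, bed_schema("cnv"))
  expect_identical(df$seqnames, c("chr3", "chrX"))
  expect_identical(as.character(GenomicRanges::strand(res$records)), c("*", "*"))
  expect_identical(df$num_probes, c("52", "7"))
  expect_identical(df$segment_mean, c("-0.31", "0.2"))

  empty <- convert_records(rows[0, ], "cnv")
  expect_identical(empty$report$rows_in, 0L)
  expect_length(empty$records, 0L)
})

test_that("methylation probes become single-base regions with symbol-derived strand", {
  rows <- data.frame(
    `Composite Element REF` = c("cg00000029", "cg00000108", "cg00000109"),
    Beta_value = c("0.42", "NA", "0.9"),
    Gene_Symbol = c("GENE1", "UNKNOWN", "GENE2"),
    Chromosome = c("1", "1", "2"),
    Genomic_Coordinate = c("1500", "1600", "7000"),
    check.names = FALSE, stringsAsFactors = FALSE)
  res <- convert_records(rows, "dnamethylation", store = tiny_store())
  expect_identical(res$report$dropped, 0L)
  expect_report_conserves(res)
  df <- records_df(res$records, bed_schema("dnamethylation"))
  i <- which(df$composite_element_ref == "cg00000029")
  expect_identical(df$start[i], "1500")
  expect_identical(df$end[i], "1500")        # single-base closed interval
  expect_identical(df$strand[i], "+")        # via GENE1 -> 100 -> +
  # unresolvable symbol: record kept with * strand, miss recorded
  j <- which(df$composite_element_ref == "cg00000108")
  expect_identical(df$strand[j], "*")
  expect_length(res$report$misses, 1L)
  expect_identical(res$report$misses[[1L]]$id_value, "UNKNOWN")
  # NA beta survives as missing and serializes as the null token
  f <- tempfile()
  write_bed(res$records, bed_schema("dnamethylation"), f)
  expect_match(readLines(f)[j], "\tnull\t")
})

test_that("MAF mutations pass through with normalized chromosomes", {
  maf_row <- function(chrom, start, end) {
    data.frame(Hugo_Symbol = "GENE1", Entrez_Gene_Id = "100",
               Chromosome = chrom, Start_position = start, End_position = end,
               Strand = "+", Variant_Classification = "Missense_Mutation",
               Variant_Type = "SNP", Reference_Allele = "C",
               Tumor_Seq_Allele1 = "C", Tumor_Seq_Allele2 = "T",
               dbSNP_RS = "novel", Tumor_Sample_Barcode = "TCGA-02-0021-01A-01D-0002-04",
               Matched_Norm_Sample_Barcode = "TCGA-02-0021-10A-01D-0002-04",
               Mutation_Status = "Somatic", Sequencer = "Illumina",
               Validation_Status = "Valid", stringsAsFactors = FALSE)
  }
  rows <- rbind(maf_row("17", 7577120, 7577120), maf_row("MT", 100, 100))
  res <- convert_records(rows, "dnaseq")
  df <- records_df(res$records, bed_schema("dnaseq"))
  expect_setequal(df$seqnames, c("chr17", "chrM"))
  expect_identical(df$strand, c("+", "+"))
  # attribute order equals schema order
  expect_identical(names(df)[5:17],
                   setdiff(bed_schema("dnaseq")$columns$name,
                           c("chrom", "chromStart", "chromEnd", "strand")))
  # missing mandatory coordinate columns are a hard input error
  expect_error(convert_records(rows[, setdiff(names(rows), "Start_position")],
                               "dnaseq"),
               class = "freebed_malformed_input")
})

test_that("miRNA conversion expands multi-locus ids and drops unknowns", {
  rows <- data.frame(miRNA_ID = c("hsa-mir-21", "hsa-mir-7", "hsa-mir-0"),
                     read_count = c(5000, 10, 3),
                     `reads_per_million_miRNA_mapped` = c(812.5, 1.5, 0.1),
                     `cross-mapped` = c("N", "Y", "N"),
                     check.names = FALSE, stringsAsFactors = FALSE)
  res <- convert_records(rows, "mirnaseq", store = tiny_store())
  expect_identical(res$report$rows_in, 3L)
  expect_identical(res$report$dropped, 1L)           # unknown id
  expect_identical(res$report$records_out, 3L)       # 1 + 2 loci
  expect_length(res$report$misses, 1L)
  df <- records_df(res$records, bed_schema("mirnaseq"))
  expect_identical(sum(df$mirna_id == "hsa-mir-7"), 2L)
  expect_identical(unique(df$read_count[df$mirna_id == "hsa-mir-7"]), "10")
})

test_that("gene quantifications resolve coordinates from the Entrez id", {
  rows <- data.frame(gene_id = c("GENE1|100", "?|200", "LOST|999"),
                     raw_count = c(1523, 10, 5),
                     scaled_estimate = c(0.000012, 1e-6, 2e-6),
                     normalized_count = c(820.1, 4.2, 1.1),
                     stringsAsFactors = FALSE)
  res <- convert_records(rows, "rnaseqv2", "gene", tiny_store())
  expect_identical(res$report$dropped, 1L)  # 999 has no coordinates
  expect_report_conserves(res)
  df <- records_df(res$records, bed_schema("rnaseqv2", "gene"))
  i <- which(df$entrez_gene_id == "100")
  expect_identical(df[i, c("seqnames", "start", "end", "strand")],
                   data.frame(seqnames = "chr1", start = "1000", end = "2000",
                              strand = "+", row.names = i))
  # "?" symbol becomes missing but coordinates still resolve via the id
  j <- which(df$entrez_gene_id == "200")
  expect_true(is.na(df$gene_symbol[j]))
  expect_identical(df$seqnames[j], "chr2")
  expect_identical(res$report$misses[[1L]]$id_kind, "entrez")

  v1 <- data.frame(gene = "GENE1|100", raw_counts = 57,
                   median_length_normalized = 0.43, RPKM = 3.1,
                   stringsAsFactors = FALSE)
  resv1 <- convert_records(v1, "rnaseq", "gene", tiny_store())
  expect_identical(records_df(resv1$records, bed_schema("rnaseq", "gene"))$rpkm, "3.1")
})

test_that("exon keys embed the region; reversed minus-strand keys normalize", {
  rows <- data.frame(exon = c("chr1:1000-2000:+", "chr1:900-500:-"),
                     raw_counts = c(57, 3),
                     median_length_normalized = c(0.43, 0.2),
                     RPKM = c(3.1, 0.5), stringsAsFactors = FALSE)
  res <- convert_records(rows, "rnaseq", "exon")
  df <- records_df(res$records, bed_schema("rnaseq", "exon"))
  i <- which(df$strand == "-")
  expect_identical(df$start[i], "500")
  expect_identical(df$end[i], "900")
  expect_identical(df$exon[i], "chr1:900-500:-")  # original key preserved
  bad <- data.frame(exon = "chr1:1000", raw_counts = 1,
                    median_length_normalized = 0, RPKM = 0)
  expect_error(convert_records(bad, "rnaseq", "exon"),
               class = "freebed_malformed_input")
})

test_that("splice junctions span their anchors with ad-hoc donor/acceptor attrs", {
  rows <- data.frame(junction = c("chr1:12227:+,chr1:12595:+",
                                  "chr1:900:-,chr1:500:-",
                                  "chr1:100:+,chr2:200:+"),
                     raw_counts = c(12, 4, 9), stringsAsFactors = FALSE)
  res <- convert_records(rows, "rnaseqv2", "spljxn")
  expect_identical(res$report$dropped, 1L)  # cross-chromosome junction
  expect_report_conserves(res)
  df <- records_df(res$records, bed_schema("rnaseqv2", "spljxn"))
  plus <- which(df$raw_counts == "12")
  expect_identical(df[plus, c("start", "end", "donor_pos", "acceptor_pos")],
                   data.frame(start = "12227", end = "12595",
                              donor_pos = "12227", acceptor_pos = "12595",
                              row.names = plus))
  minus <- which(df$strand == "-")
  expect_identical(df$start[minus], "500")   # region normalized
  expect_identical(df$donor_pos[minus], "900")  # orientation preserved
})

test_that("isoforms resolve through the UCSC chain; same-gene isoforms share a region", {
  rows <- data.frame(isoform_id = c("uc002bbb.1", "uc002bbb.7", "uc009zzz.9"),
                     raw_count = c(10, 20, 5),
                     scaled_estimate = c(1e-6, 2e-6, 0),
                     normalized_count = c(4.2, 8.4, 0), stringsAsFactors = FALSE)
  res <- convert_records(rows, "rnaseqv2", "isoform", tiny_store())
  expect_identical(res$report$dropped, 1L)
  expect_identical(res$report$misses[[1L]]$id_kind, "ucsc")
  df <- records_df(res$records, bed_schema("rnaseqv2", "isoform"))
  # both versioned ids fall back to the unversioned table key of gene 200
  expect_identical(unique(df$start), "5000")
  expect_identical(sort(df$isoform_id), c("uc002bbb.1", "uc002bbb.7"))
  expect_identical(unique(df$entrez_gene_id), "200")
})

test_that("converting the same input twice yields byte-identical output", {
  set.seed(31)
  rows <- data.frame(Sample = "s", Chromosome = sample(c("1", "2", "X"), 50, TRUE),
                     Start = sample.int(1e6, 50), End = 0, Num_Probes = 5,
                     Segment_Mean = signif(rnorm(50), 6), stringsAsFactors = FALSE)
  rows$End <- rows$Start + sample.int(1e4, 50)
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(convert_records(rows, "cnv")$records, bed_schema("cnv"), f1)
  write_bed(convert_records(rows, "cnv")$records, bed_schema("cnv"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the six schemas share exactly the four mandatory fields", {
  keys <- bed_schema_keys()
  cols <- lapply(keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    bed_schema(parts[1L], if (length(parts) > 1L) parts[2L])$columns$name
  })
  expect_identical(Reduce(intersect, cols),
                   c("chrom", "chromStart", "chromEnd", "strand"))
  # and they are the first four, in order, of every schema
  for (cs in cols) expect_identical(cs[1:4],
                                    c("chrom", "chromStart", "chromEnd", "strand"))
})

test_that("unknown converter keys are a config error", {
  expect_error(convert_records(data.frame(), "rnaseqv3"),
               class = "freebed_config_error")
})
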