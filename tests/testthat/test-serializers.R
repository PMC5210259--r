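test_that("BED lines are headerless tab-joined fields in schema order", {
  s <- bed_schema("dnamethylation")
  r <- bed_records("chr1", 1500, 1500, "+",
                   data.frame(composite_element_ref = "cg00000029",
                              beta_value = 0.42, gene_symbol = "GENE1"), s)
  f <- tempfile()
  write_bed(r, s, f)
  expect_identical(readLines(f), "chr1\t1500\t1500\t+\tcg00000029\t0.42\tGENE1")
  # empty record set -> empty file (0 bytes)
  write_bed(r[0], s, f)
  expect_identical(file.size(f), 0)
})

test_that("numeric rendering is stable: bare integers, 6 significant digits", {
  s <- bed_schema("cnv")
  r <- bed_records(rep("chr1", 4), 1:4, 2:5, rep("*", 4),
                   data.frame(num_probes = c(52L, NA, 7L, 1L),
                              segment_mean = c(-0.3123456789, 0.5, 1e-5, 123456.789)),
                   s)
  f <- tempfile()
  write_bed(r, s, f)
  fields <- do.call(rbind, strsplit(readLines(f), "\t"))
  expect_identical(fields[, 5], c("52", "null", "7", "1"))
  expect_identical(fields[, 6], c("-0.312346", "0.5", "1e-05", "123457"))
})

test_that("BED/CSV/JSON round trips reproduce randomized record sets exactly", {
  set.seed(2024)
  for (key in c("cnv", "dnaseq", "mirnaseq", "rnaseqv2.gene")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    s <- bed_schema(parts[1L], if (length(parts) > 1L) parts[2L])
    r <- random_records(s, 60)
    fb <- tempfile(); fc <- tempfile(); fj <- tempfile()
    write_bed(r, s, fb); write_bed_csv(r, s, fc); write_bed_json(r, s, fj)
    expect_identical(records_df(read_bed(fb, s), s), records_df(r, s))
    expect_identical(records_df(read_bed_csv(fc, s), s), records_df(r, s))
    expect_identical(records_df(read_bed_json(fj, s), s), records_df(r, s))
    # cross-format: JSON -> (records) -> BED -> records equals the original
    back <- read_bed_json(fj, s)
    f2 <- tempfile()
    write_bed(back, s, f2)
    expect_identical(readLines(f2), readLines(fb))
  }
})

test_that("CSV quoting follows RFC 4180 for embedded commas and quotes", {
  s <- bed_schema("dnaseq")
  attrs <- as.data.frame(as.list(stats::setNames(
    rep("x", 13), setdiff(s$columns$name, freebed:::MANDATORY_FIELDS))),
    stringsAsFactors = FALSE)
  attrs$hugo_symbol <- 'GENE,1'
  attrs$sequencer <- 'Illumina "HiSeq"'
  r <- bed_records("chr1", 1, 2, "+", attrs, s)
  f <- tempfile()
  write_bed_csv(r, s, f)
  line <- readLines(f)[2]
  expect_match(line, '"GENE,1"', fixed = TRUE)
  expect_match(line, '"Illumina ""HiSeq"""', fixed = TRUE)
  expect_identical(records_df(read_bed_csv(f, s), s), records_df(r, s))
})

test_that("every BED line of a type has the header.schema field count", {
  set.seed(12)
  for (key in c("cnv", "rnaseq.spljxn")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    s <- bed_schema(parts[1L], if (length(parts) > 1L) parts[2L])
    f <- tempfile()
    write_bed(random_records(s, 40), s, f)
    nfields <- lengths(strsplit(readLines(f), "\t", fixed = TRUE))
    expect_identical(unique(nfields), nrow(s$columns))
  }
})

test_that("header.schema validates against the shipped XSD and round-trips", {
  for (key in bed_schema_keys()) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    s <- bed_schema(parts[1L], if (length(parts) > 1L) parts[2L])
    f <- tempfile(fileext = ".schema")
    write_header_schema(s, f)
    doc <- xml2::read_xml(f)
    fields <- xml2::xml_attr(xml2::xml_find_all(doc, "field"), "name")
    expect_identical(fields[1:4], c("chrom", "chromStart", "chromEnd", "strand"))
    expect_identical(read_header_schema(f), s)
  }
  # two subtypes differ beyond position 4
  g <- bed_schema("rnaseqv2", "gene")$columns$name
  i <- bed_schema("rnaseqv2", "isoform")$columns$name
  expect_identical(g[1:4], i[1:4])
  expect_false(identical(g[-(1:4)], i[-(1:4)]))
  # a corrupted descriptor fails XSD validation
  f <- tempfile()
  writeLines('<bedSchema experimentType="cnv" subtype=""><field name="chrom" type="bogus"/></bedSchema>', f)
  expect_error(read_header_schema(f), class = "freebed_malformed_input")
})

test_that("GTF output keeps coordinates and renders attributes as key-value pairs", {
  s <- bed_schema("dnamethylation")
  r <- bed_records("chr1", 1500, 1500, "+",
                   data.frame(composite_element_ref = "cg00000029",
                              beta_value = 0.42, gene_symbol = "GENE1"), s)
  f <- tempfile()
  write_bed_gtf(r, s, f)
  fields <- strsplit(readLines(f), "\t")[[1L]]
  expect_identical(fields[1:8],
                   c("chr1", "freebed", "methylation_site", "1500", "1500",
                     ".", "+", "."))
  expect_identical(fields[9],
                   'composite_element_ref "cg00000029"; beta_value "0.42"; gene_symbol "GENE1";')
  # unknown strand maps to GTF's "."
  s2 <- bed_schema("cnv")
  r2 <- bed_records("chr3", 10, 20, "*",
                    data.frame(num_probes = 1L, segment_mean = 0), s2)
  write_bed_gtf(r2, s2, f)
  expect_identical(strsplit(readLines(f), "\t")[[1L]][7], ".")
  expect_identical(strsplit(readLines(f), "\t")[[1L]][3], "cnv_segment")
})

test_that("XML serialization carries one element per record and field", {
  s <- bed_schema("cnv")
  r <- bed_records(c("chr1", "chr2"), c(1, 5), c(2, 9), c("*", "*"),
                   data.frame(num_probes = c(1L, 2L), segment_mean = c(0.5, NA)), s)
  f <- tempfile()
  write_bed_xml(r, s, f)
  doc <- xml2::read_xml(f)
  recs <- xml2::xml_find_all(doc, "record")
  expect_length(recs, 2L)
  expect_identical(xml2::xml_name(xml2::xml_children(recs[[1L]])),
                   s$columns$name)
  expect_identical(
    xml2::xml_text(xml2::xml_find_first(recs[[2L]], "segment_mean")), "null")
})
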