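test_that("direct Entrez lookup returns the stored region or a typed miss", {
  store <- tiny_store()
  reg <- coords_by_entrez(store, 100)
  expect_identical(reg, list(chrom = "chr1", start = 1000L, end = 2000L,
                             strand = "+"))
  miss <- coords_by_entrez(store, 12345)
  expect_true(is_annotation_miss(miss))
  expect_identical(miss$id_kind, "entrez")
  expect_identical(miss$stage, "entrez_coords")
})

test_that("symbol chain composes HGNC and Entrez links and reports the failed stage", {
  store <- tiny_store()
  expect_identical(strand_by_symbol(store, "GENE1"), "+")
  expect_identical(strand_by_symbol(store, "GENE2"), "-")
  m1 <- strand_by_symbol(store, "NOSUCH")
  expect_identical(m1$stage, "symbol_to_entrez")
  # ORPHAN maps to Entrez 999, which has no coordinates
  m2 <- strand_by_symbol(store, "ORPHAN")
  expect_identical(m2$stage, "entrez_coords")
  expect_identical(m2$id_kind, "symbol")
})

test_that("UCSC chain resolves transcripts with version fallback", {
  store <- tiny_store()
  hit <- coords_by_ucsc(store, "uc001aaa.3")
  expect_identical(hit$chrom, "chr1")
  expect_identical(hit$entrez_id, "100")
  # table only has unversioned uc002bbb; versioned query falls back
  fb <- coords_by_ucsc(store, "uc002bbb.7")
  expect_identical(fb$chrom, "chr2")
  expect_true(is_annotation_miss(coords_by_ucsc(store, "uc009zzz.1")))
})

test_that("miRNA lookup is case-insensitive and multi-locus", {
  store <- tiny_store()
  one <- coords_by_mirna(store, "hsa-mir-21")
  expect_length(one, 1L)
  expect_identical(one[[1L]]$start, 59841266L)
  expect_identical(coords_by_mirna(store, "HSA-MIR-21"), one)
  two <- coords_by_mirna(store, "hsa-mir-7")
  expect_length(two, 2L)
  expect_identical(vapply(two, `[[`, "", "chrom"), c("chr1", "chr2"))
  expect_true(is_annotation_miss(coords_by_mirna(store, "hsa-mir-0")))
})

test_that("chain lookups equal a brute-force two-step oracle over raw tables", {
  set.seed(101)
  n <- 1000
  raw_entrez <- data.frame(
    entrez_id = as.character(sample.int(1e6, n)),
    chrom = sample(c("chr1", "chr5", "chrX"), n, replace = TRUE),
    start = sample.int(1e6, n), end = integer(n), strand = sample(c("+", "-"), n, TRUE),
    stringsAsFactors = FALSE)
  raw_entrez$end <- raw_entrez$start + sample.int(1e4, n)
  # half the symbols/transcripts point at known genes, half at unknown ids
  raw_sym <- data.frame(
    symbol = sprintf("SYM%05d", seq_len(n)),
    entrez_id = c(sample(raw_entrez$entrez_id, n / 2),
                  as.character(seq_len(n / 2) + 2e6)),
    stringsAsFactors = FALSE)
  raw_ucsc <- data.frame(
    ucsc_id = sprintf("uc%06d.1", seq_len(n)),
    entrez_id = c(sample(raw_entrez$entrez_id, n / 2),
                  as.character(seq_len(n / 2) + 3e6)),
    stringsAsFactors = FALSE)
  store <- annotation_store(entrez_coords = raw_entrez,
                            symbol_to_entrez = raw_sym,
                            ucsc_to_entrez = raw_ucsc)
  # independent oracle: explicit nested subscript over the raw data frames
  for (i in sample.int(n, 1000, replace = TRUE)) {
    sym <- raw_sym$symbol[i]
    eid <- raw_sym$entrez_id[raw_sym$symbol == sym]
    j <- which(raw_entrez$entrez_id == eid)
    got <- strand_by_symbol(store, sym)
    if (length(j)) expect_identical(got, raw_entrez$strand[j]) else {
      expect_true(is_annotation_miss(got))
    }
    tid <- raw_ucsc$ucsc_id[i]
    eid2 <- raw_ucsc$entrez_id[raw_ucsc$ucsc_id == tid]
    k <- which(raw_entrez$entrez_id == eid2)
    got2 <- coords_by_ucsc(store, tid)
    if (length(k)) {
      expect_identical(got2[c("chrom", "start", "end", "strand")],
                       list(chrom = raw_entrez$chrom[k],
                            start = raw_entrez$start[k],
                            end = raw_entrez$end[k],
                            strand = raw_entrez$strand[k]))
    } else {
      expect_true(is_annotation_miss(got2))
    }
  }
})

test_that("cache save/load preserves a randomized store exactly", {
  set.seed(55)
  n <- 1000
  starts <- sample.int(1e7, n)
  store <- annotation_store(
    entrez_coords = data.frame(entrez_id = as.character(sample.int(1e8, n)),
                               chrom = sample(freebed:::KARYOTYPE, n, TRUE),
                               start = starts, end = starts + sample.int(1e4, n),
                               strand = sample(c("+", "-"), n, TRUE)),
    symbol_to_entrez = data.frame(symbol = sprintf("S%06d", sample.int(1e6, n)),
                                  entrez_id = as.character(sample.int(1e8, n))),
    ucsc_to_entrez = data.frame(ucsc_id = sprintf("uc%06d.2", sample.int(1e6, n)),
                                entrez_id = as.character(sample.int(1e8, n))),
    mirna_coords = data.frame(mirna_id = sprintf("hsa-mir-%d", sample.int(1e5, n, TRUE)),
                              chrom = sample(freebed:::KARYOTYPE, n, TRUE),
                              start = starts, end = starts + 71L,
                              strand = sample(c("+", "-"), n, TRUE)))
  f <- tempfile()
  save_annotation_cache(store, f)
  reloaded <- load_annotation_cache(f)
  expect_identical(reloaded, store)
  # lookups after the round trip equal lookups before
  some <- sample(store$entrez_coords$id, 50)
  expect_identical(lapply(some, coords_by_entrez, store = reloaded),
                   lapply(some, coords_by_entrez, store = store))
})

test_that("empty tables give an empty store where every lookup misses", {
  store <- annotation_store()
  expect_true(is_annotation_miss(coords_by_entrez(store, 1)))
  expect_true(is_annotation_miss(strand_by_symbol(store, "A")))
  expect_true(is_annotation_miss(coords_by_ucsc(store, "uc000001.1")))
  expect_true(is_annotation_miss(coords_by_mirna(store, "hsa-mir-1")))
})

test_that("table loading reports format errors with line numbers and handles duplicates", {
  f <- tempfile()
  writeLines(c("entrez_id\tchrom\tstart\tend\tstrand",
               "100\tchr1\t10\t20\t+",
               "200\tchr2\t30"), f)
  err <- tryCatch(load_annotation_store(entrez_coords = f),
                  freebed_table_format = function(e) conditionMessage(e))
  expect_match(err, ":3:")

  writeLines(c("symbol\tentrez_id", "A\t1", "A\t2"), f)
  expect_warning(store <- load_annotation_store(symbol_to_entrez = f),
                 class = "freebed_duplicate_key")
  expect_identical(unname(store$symbol_to_entrez["A"]), "2")  # last wins
})

test_that("lookups do not mutate the store", {
  store <- tiny_store()
  before <- store
  invisible(coords_by_entrez(store, 100))
  invisible(strand_by_symbol(store, "GENE1"))
  invisible(coords_by_ucsc(store, "uc001aaa.3"))
  invisible(coords_by_mirna(store, "hsa-mir-7"))
  expect_identical(store, before)
})
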