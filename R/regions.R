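#' One-based closed genomic coordinates
#'
#' The whole toolkit uses the one-based (base-counted) coordinate
#' representation adopted by TCGA: the first base of a sequence is position 1
#' and a region is a closed interval, so the 3rd through 7th bases are
#' `[3, 7]`. `to_one_based_closed()` converts from the UCSC-style 0-based
#' half-open convention; `to_zero_based_half_open()` is its inverse. Both are
#' length-preserving bijections between non-empty intervals.
#'
#' @param start0 Integer vector, 0-based inclusive starts.
#' @param end0 Integer vector, 0-based exclusive ends (`start0 < end0`).
#' @return A list with integer components `start` and `end` (one-based,
#'   both inclusive).
#' @examples
#' to_one_based_closed(2, 7)   # bases 3..7 -> [3, 7]
#' to_zero_based_half_open(3, 7)
#' @export
to_one_based_closed <- function(start0, end0) {
  start0 <- as.integer(start0); end0 <- as.integer(end0)
  bad <- is.na(start0) | is.na(end0) | start0 < 0L | start0 >= end0
  if (any(bad)) {
    fb_stop("freebed_empty_interval",
            sprintf("empty or invalid 0-based half-open interval [%s, %s)",
                    start0[bad][1L], end0[bad][1L]))
  }
  list(start = start0 + 1L, end = end0)
}

#' @rdname to_one_based_closed
#' @param start1,end1 Integer vectors, one-based inclusive endpoints
#'   (`1 <= start1 <= end1`).
#' @export
to_zero_based_half_open <- function(start1, end1) {
  start1 <- as.integer(start1); end1 <- as.integer(end1)
  bad <- is.na(start1) | is.na(end1) | start1 < 1L | start1 > end1
  if (any(bad)) {
    fb_stop("freebed_empty_interval",
            sprintf("invalid one-based closed interval [%s, %s]",
                    start1[bad][1L], end1[bad][1L]))
  }
  list(start = start1 - 1L, end = end1)
}

# Karyotype chromosome order: chr1..chr22, chrX, chrY, chrM. Deterministic,
# diffable output ordering (not lexicographic, where chr10 < chr2).
KARYOTYPE <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

#' Normalize chromosome names
#'
#' TCGA platforms mix naming conventions ("17", "chr17", "MT", "chrMT", "x").
#' All are normalized to the "chr"-prefixed form with the mitochondrion as
#' "chrM". Unrecognizable names yield `NA`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names (`NA` where unrecognized).
#' @examples
#' normalize_chrom(c("17", "chr17", "MT", "x"))
#' @export
normalize_chrom <- function(chrom) {
  if (length(chrom) == 0L) return(character(0))
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x <- toupper(x)
  x[x == "MT"] <- "M"
  out <- paste0("chr", x)
  out[!out %in% KARYOTYPE] <- NA_character_
  out
}

#' Construct a set of free-BED records
#'
#' A record set is a [GenomicRanges::GRanges] (natively one-based closed,
#' strand in `{+,-,*}` with `*` as the unknown/not-applicable placeholder)
#' whose metadata columns are exactly the schema's attribute columns, in
#' schema order and with the schema's value kinds. The schema itself is kept
#' in `S4Vectors::metadata(gr)$schema`.
#'
#' @param chrom,start,end,strand Parallel vectors for the four mandatory
#'   fields. Chromosome names are normalized with [normalize_chrom()].
#' @param attrs A data.frame of attribute columns matching the schema's
#'   names and order (coerced to the schema's value kinds).
#' @param schema A [bed_schema()].
#' @return A sorted `GRanges` conforming to `schema`.
#' @export
bed_records <- function(chrom, start, end, strand, attrs, schema) {
  stopifnot(inherits(schema, "bed_schema"))
  n <- length(chrom)
  chrom <- normalize_chrom(chrom)
  start <- as.integer(start); end <- as.integer(end)
  strand <- as.character(strand)
  if (any(is.na(chrom))) {
    fb_stop("freebed_malformed_input", "unrecognized chromosome name in records")
  }
  if (any(is.na(start) | is.na(end) | start < 1L | start > end)) {
    fb_stop("freebed_malformed_input",
            "region coordinates must satisfy 1 <= start <= end")
  }
  if (!all(strand %in% c("+", "-", "*"))) {
    fb_stop("freebed_malformed_input", "strand must be one of +, -, *")
  }
  want <- attribute_names(schema)
  attrs <- as.data.frame(attrs, optional = TRUE, stringsAsFactors = FALSE)
  if (n == 0L && nrow(attrs) == 0L && length(want) > 0L && ncol(attrs) == 0L) {
    attrs <- as.data.frame(stats::setNames(rep(list(character(0)), length(want)), want))
  }
  if (!identical(names(attrs), want)) {
    fb_stop("freebed_schema_mismatch",
            sprintf("attribute columns (%s) do not match schema '%s' (%s)",
                    paste(names(attrs), collapse = ","), schema_key(schema),
                    paste(want, collapse = ",")))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = KARYOTYPE),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  GenomeInfoDb::seqlevels(gr) <- KARYOTYPE
  for (nm in want) {
    S4Vectors::mcols(gr)[[nm]] <- coerce_kind(attrs[[nm]], attribute_kind(schema, nm))
  }
  S4Vectors::metadata(gr)$schema <- schema
  sort_bed_records(gr)
}

# Total deterministic order: karyotype chrom, start, end, strand, then every
# attribute column rendered as text. Shuffled input always serializes
# byte-identically.
#' Sort free-BED records into canonical order
#'
#' @param gr A `GRanges` record set from [bed_records()].
#' @return The same records, ordered by (karyotype chromosome, start, end,
#'   strand, attribute values).
#' @export
sort_bed_records <- function(gr) {
  keys <- list(
    as.integer(match(as.character(GenomeInfoDb::seqnames(gr)), KARYOTYPE)),
    GenomicRanges::start(gr),
    GenomicRanges::end(gr),
    as.character(GenomicRanges::strand(gr))
  )
  mc <- S4Vectors::mcols(gr)
  for (nm in colnames(mc)) keys[[length(keys) + 1L]] <- as.character(mc[[nm]])
  o <- do.call(order, c(keys, list(method = "radix")))
  gr[o]
}

coerce_kind <- function(x, kind) {
  switch(kind,
    integer = {
      x <- suppressWarnings(as.integer(as.character(x)))
      x
    },
    float = suppressWarnings(as.numeric(ifelse(as.character(x) %in% NULL_TOKENS,
                                               NA, as.character(x)))),
    string = , char = {
      x <- as.character(x)
      x[x %in% NULL_TOKENS] <- NA_character_
      x
    },
    fb_stop("freebed_schema_error", sprintf("unknown value kind '%s'", kind))
  )
}

# Tokens treated as missing when reading original TCGA tables.
NULL_TOKENS <- c("NA", "null", "NULL", "", ".")
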