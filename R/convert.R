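#' Convert original TCGA-style rows to free-BED records
#'
#' One converter per (experiment type, subtype) maps rows of the original
#' tab-delimited layouts to free-BED records, invoking the annotation store
#' where the source files lack coordinates or strand:
#'
#' * `cnv`: segment coordinates are already present; no strand exists for a
#'   copy-number segment, so the `*` placeholder is written.
#' * `dnamethylation`: probe position is present (a single-base region,
#'   legal under the closed-interval convention); the strand is recovered
#'   from the gene symbol through the HGNC -> Entrez chain, falling back to
#'   `*` with a recorded miss (position being present, the record is kept).
#' * `dnaseq`: MAF mutations carry full coordinates; 13 MAF columns are
#'   carried into the attribute tail.
#' * `mirnaseq`: coordinates come entirely from the miRBase table; a miRNA
#'   mapping to k loci yields k records, an unknown miRNA id drops the row
#'   (there is no region to emit).
#' * `rnaseq`/`rnaseqv2` `gene`: coordinates come from the Entrez Gene
#'   table via the id in the composite `symbol|entrez` key.
#' * `exon`/`spljxn`: coordinates are embedded in the composite row key;
#'   splice junctions additionally get ad-hoc donor/acceptor attributes.
#' * `rnaseqv2` `isoform`: UCSC transcript id -> Entrez id -> coordinates.
#'
#' Rows whose missing datum is the region itself are dropped (and counted);
#' rows missing only strand are kept with `*`. Every converter returns the
#' sorted records plus a conversion report with `rows_in`, `records_out`,
#' `dropped` and the list of annotation misses; `rows_in = records_out +
#' dropped` for all single-record-per-row types (miRNA expands loci).
#'
#' @param rows A data.frame as returned by [read_tcga_table()].
#' @param type,subtype Experiment type and subtype (see [bed_schema()]).
#' @param store An [annotation_store()]; optional for types that never
#'   consult it.
#' @return A list with elements `records` (a `GRanges`, see
#'   [bed_records()]) and `report`.
#' @examples
#' rows <- data.frame(Sample = "s", Chromosome = "3", Start = 1000,
#'                    End = 5000, Num_Probes = 52, Segment_Mean = -0.31,
#'                    check.names = FALSE)
#' convert_records(rows, "cnv")$records
#' @export
convert_records <- function(rows, type, subtype = NULL, store = annotation_store()) {
  key <- schema_key_parts(type, subtype)
  fun <- .converter_registry[[key]]
  if (is.null(fun)) {
    fb_stop("freebed_config_error",
            sprintf("no converter registered for '%s'", key))
  }
  fun(rows, store)
}

#' Read an original TCGA-style tab-delimited file
#'
#' One header line; MAF files may carry leading `#` comment lines. Column
#' names are preserved verbatim (TCGA headers contain spaces). Each row
#' remembers its source line number for error reporting.
#'
#' @param path File path.
#' @return A data.frame of character columns with attributes `file` and
#'   `lines` (original line number of each row).
#' @export
read_tcga_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) skip <- skip + 1L
  if (length(lines) <= skip) {
    fb_stop("freebed_malformed_input", sprintf("%s: no header line", path))
  }
  header <- strsplit(lines[skip + 1L], "\t", fixed = TRUE)[[1L]]
  body_idx <- seq.int(skip + 2L, length.out = length(lines) - skip - 1L)
  body <- lines[body_idx]
  body_idx <- body_idx[nzchar(body)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    fb_stop("freebed_malformed_input",
            sprintf("%s:%d: expected %d tab-separated fields, found %d",
                    path, body_idx[bad], length(header), nf[bad]))
  }
  if (length(parts) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(header)),
                                         header), check.names = FALSE)
  } else {
    mat <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
    out <- as.data.frame(mat, stringsAsFactors = FALSE, check.names = FALSE)
    names(out) <- header
  }
  attr(out, "file") <- path
  attr(out, "lines") <- body_idx
  out
}

new_report <- function(rows_in, records_out, dropped, misses = list()) {
  list(rows_in = as.integer(rows_in), records_out = as.integer(records_out),
       dropped = as.integer(dropped), misses = misses)
}

require_columns <- function(rows, cols) {
  missing <- setdiff(cols, names(rows))
  if (length(missing)) {
    fb_stop("freebed_malformed_input",
            sprintf("%s: missing mandatory column(s): %s",
                    attr(rows, "file") %||% "<rows>",
                    paste(missing, collapse = ", ")))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

row_line <- function(rows, i) {
  ln <- attr(rows, "lines")
  if (is.null(ln)) i else ln[i]
}

finish <- function(chrom, start, end, strand, attrs, schema,
                   rows_in, dropped, misses) {
  records <- bed_records(chrom, start, end, strand, attrs, schema)
  list(records = records,
       report = new_report(rows_in, length(records), dropped, misses))
}

convert_cnv <- function(rows, store) {
  schema <- bed_schema("cnv")
  require_columns(rows, c("Chromosome", "Start", "End", "Num_Probes", "Segment_Mean"))
  chrom <- normalize_chrom(rows$Chromosome)
  start <- suppressWarnings(as.integer(rows$Start))
  end <- suppressWarnings(as.integer(rows$End))
  keep <- !is.na(chrom) & !is.na(start) & !is.na(end) & start >= 1L & start <= end
  finish(chrom[keep], start[keep], end[keep], rep("*", sum(keep)),
         data.frame(num_probes = rows$Num_Probes[keep],
                    segment_mean = rows$Segment_Mean[keep],
                    stringsAsFactors = FALSE),
         schema, nrow(rows), sum(!keep), list())
}

convert_methylation <- function(rows, store) {
  schema <- bed_schema("dnamethylation")
  require_columns(rows, c("Composite Element REF", "Beta_value", "Gene_Symbol",
                          "Chromosome", "Genomic_Coordinate"))
  chrom <- normalize_chrom(rows$Chromosome)
  pos <- suppressWarnings(as.integer(rows$Genomic_Coordinate))
  keep <- !is.na(chrom) & !is.na(pos) & pos >= 1L
  misses <- list()
  symbols <- rows$Gene_Symbol
  strand <- rep("*", nrow(rows))
  for (i in which(keep)) {
    s <- strand_by_symbol(store, symbols[i])
    if (is_annotation_miss(s)) misses[[length(misses) + 1L]] <- s else strand[i] <- s
  }
  finish(chrom[keep], pos[keep], pos[keep], strand[keep],
         data.frame(composite_element_ref = rows$`Composite Element REF`[keep],
                    beta_value = rows$Beta_value[keep],
                    gene_symbol = symbols[keep],
                    stringsAsFactors = FALSE),
         schema, nrow(rows), sum(!keep), misses)
}

MAF_ATTR_COLS <- c(hugo_symbol = "Hugo_Symbol",
                   entrez_gene_id = "Entrez_Gene_Id",
                   variant_classification = "Variant_Classification",
                   variant_type = "Variant_Type",
                   reference_allele = "Reference_Allele",
                   tumor_seq_allele1 = "Tumor_Seq_Allele1",
                   tumor_seq_allele2 = "Tumor_Seq_Allele2",
                   dbsnp_rs = "dbSNP_RS",
                   tumor_sample_barcode = "Tumor_Sample_Barcode",
                   matched_norm_sample_barcode = "Matched_Norm_Sample_Barcode",
                   mutation_status = "Mutation_Status",
                   sequencer = "Sequencer",
                   validation_status = "Validation_Status")

convert_dnaseq <- function(rows, store) {
  schema <- bed_schema("dnaseq")
  require_columns(rows, c("Chromosome", "Start_position", "End_position",
                          "Strand", unname(MAF_ATTR_COLS)))
  chrom <- normalize_chrom(rows$Chromosome)
  start <- suppressWarnings(as.integer(rows$Start_position))
  end <- suppressWarnings(as.integer(rows$End_position))
  bad <- is.na(chrom) | is.na(start) | is.na(end)
  if (any(bad)) {
    i <- which(bad)[1L]
    fb_stop("freebed_malformed_input",
            sprintf("%s:%d: unparsable mutation coordinates",
                    attr(rows, "file") %||% "<rows>", row_line(rows, i)))
  }
  strand <- as.character(rows$Strand)
  strand[!strand %in% c("+", "-")] <- "*"
  attrs <- stats::setNames(
    lapply(MAF_ATTR_COLS, function(col) rows[[col]]),
    names(MAF_ATTR_COLS))
  finish(chrom, start, end, strand,
         as.data.frame(attrs, stringsAsFactors = FALSE, check.names = FALSE),
         schema, nrow(rows), 0L, list())
}

convert_mirnaseq <- function(rows, store) {
  schema <- bed_schema("mirnaseq")
  require_columns(rows, c("miRNA_ID", "read_count",
                          "reads_per_million_miRNA_mapped", "cross-mapped"))
  misses <- list()
  out <- list(chrom = character(0), start = integer(0), end = integer(0),
              strand = character(0))
  attrs <- list(mirna_id = character(0), read_count = character(0),
                reads_per_million_mirna_mapped = character(0),
                cross_mapped = character(0))
  dropped <- 0L
  for (i in seq_len(nrow(rows))) {
    loci <- coords_by_mirna(store, rows$miRNA_ID[i])
    if (is_annotation_miss(loci)) {
      misses[[length(misses) + 1L]] <- loci
      dropped <- dropped + 1L
      next
    }
    for (reg in loci) {
      out$chrom <- c(out$chrom, reg$chrom)
      out$start <- c(out$start, reg$start)
      out$end <- c(out$end, reg$end)
      out$strand <- c(out$strand, reg$strand)
      attrs$mirna_id <- c(attrs$mirna_id, rows$miRNA_ID[i])
      attrs$read_count <- c(attrs$read_count, rows$read_count[i])
      attrs$reads_per_million_mirna_mapped <-
        c(attrs$reads_per_million_mirna_mapped,
          rows$`reads_per_million_miRNA_mapped`[i])
      attrs$cross_mapped <- c(attrs$cross_mapped, rows$`cross-mapped`[i])
    }
  }
  finish(out$chrom, out$start, out$end, out$strand,
         as.data.frame(attrs, stringsAsFactors = FALSE),
         schema, nrow(rows), dropped, misses)
}

# Shared gene-quantification conversion: the composite key is
# "<symbol>|<entrez id>" ("?" symbol when unknown); coordinates come from
# the Entrez table.
convert_gene_quant <- function(rows, store, schema, key_col, value_cols) {
  require_columns(rows, c(key_col, unname(value_cols)))
  keys <- strsplit(as.character(rows[[key_col]]), "|", fixed = TRUE)
  misses <- list()
  keep <- logical(nrow(rows))
  chrom <- character(nrow(rows)); start <- integer(nrow(rows))
  end <- integer(nrow(rows)); strand <- character(nrow(rows))
  symbol <- character(nrow(rows)); entrez <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    k <- keys[[i]]
    if (length(k) != 2L) {
      fb_stop("freebed_malformed_input",
              sprintf("%s:%d: malformed gene key '%s'",
                      attr(rows, "file") %||% "<rows>", row_line(rows, i),
                      rows[[key_col]][i]))
    }
    symbol[i] <- if (k[1L] == "?") NA_character_ else k[1L]
    entrez[i] <- k[2L]
    reg <- coords_by_entrez(store, k[2L])
    if (is_annotation_miss(reg)) {
      misses[[length(misses) + 1L]] <- reg
      next
    }
    keep[i] <- TRUE
    chrom[i] <- reg$chrom; start[i] <- reg$start
    end[i] <- reg$end; strand[i] <- reg$strand
  }
  attrs <- c(list(entrez_gene_id = entrez[keep], gene_symbol = symbol[keep]),
             stats::setNames(lapply(value_cols, function(col) rows[[col]][keep]),
                             names(value_cols)))
  finish(chrom[keep], start[keep], end[keep], strand[keep],
         as.data.frame(attrs, stringsAsFactors = FALSE),
         schema, nrow(rows), sum(!keep), misses)
}

convert_rnaseq_gene <- function(rows, store) {
  convert_gene_quant(rows, store, bed_schema("rnaseq", "gene"), "gene",
                     c(raw_counts = "raw_counts",
                       median_length_normalized = "median_length_normalized",
                       rpkm = "RPKM"))
}

convert_rnaseqv2_gene <- function(rows, store) {
  convert_gene_quant(rows, store, bed_schema("rnaseqv2", "gene"), "gene_id",
                     c(raw_count = "raw_count",
                       scaled_estimate = "scaled_estimate",
                       normalized_count = "normalized_count"))
}

# Exon keys look like "chr1:1000-2000:+"; minus-strand keys may print
# start > end, which is normalized (the original key is preserved in the
# `exon` attribute).
parse_exon_key <- function(key, rows, i) {
  m <- regmatches(key, regexec("^([^:]+):([0-9]+)-([0-9]+):([+.-])$", key))[[1L]]
  chrom <- if (length(m) == 5L) normalize_chrom(m[2L]) else NA_character_
  if (length(m) != 5L || is.na(chrom)) {
    fb_stop("freebed_malformed_input",
            sprintf("%s:%d: malformed exon key '%s'",
                    attr(rows, "file") %||% "<rows>", row_line(rows, i), key))
  }
  a <- as.integer(m[3L]); b <- as.integer(m[4L])
  list(chrom = chrom, start = min(a, b), end = max(a, b),
       strand = if (m[5L] == ".") "*" else m[5L])
}

convert_exon_quant <- function(rows, store, schema) {
  require_columns(rows, c("exon", "raw_counts", "median_length_normalized", "RPKM"))
  parsed <- lapply(seq_len(nrow(rows)),
                   function(i) parse_exon_key(rows$exon[i], rows, i))
  finish(vapply(parsed, `[[`, "", "chrom"),
         vapply(parsed, `[[`, 0L, "start"),
         vapply(parsed, `[[`, 0L, "end"),
         vapply(parsed, `[[`, "", "strand"),
         data.frame(exon = rows$exon,
                    raw_counts = rows$raw_counts,
                    median_length_normalized = rows$median_length_normalized,
                    rpkm = rows$RPKM,
                    stringsAsFactors = FALSE),
         schema, nrow(rows), 0L, list())
}

# Junction keys are "chr1:12227:+,chr1:12595:+" (donor anchor, acceptor
# anchor). The record spans min..max anchor position; donor/acceptor
# orientation is preserved in the ad-hoc attribute columns. Junctions whose
# anchors sit on different chromosomes cannot form a single region and are
# dropped.
parse_jxn_anchor <- function(txt) {
  m <- regmatches(txt, regexec("^([^:]+):([0-9]+):([+.-])$", txt))[[1L]]
  if (length(m) != 4L) return(NULL)
  chrom <- normalize_chrom(m[2L])
  if (is.na(chrom)) return(NULL)
  list(chrom = chrom, pos = as.integer(m[3L]),
       strand = if (m[4L] == ".") "*" else m[4L])
}

convert_spljxn <- function(rows, store, schema) {
  require_columns(rows, c("junction", "raw_counts"))
  n <- nrow(rows)
  keep <- logical(n)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  strand <- character(n)
  donor_chrom <- character(n); donor_pos <- integer(n)
  acceptor_chrom <- character(n); acceptor_pos <- integer(n)
  for (i in seq_len(n)) {
    halves <- strsplit(rows$junction[i], ",", fixed = TRUE)[[1L]]
    if (length(halves) != 2L) {
      fb_stop("freebed_malformed_input",
              sprintf("%s:%d: malformed junction key '%s'",
                      attr(rows, "file") %||% "<rows>", row_line(rows, i),
                      rows$junction[i]))
    }
    donor <- parse_jxn_anchor(halves[1L])
    acceptor <- parse_jxn_anchor(halves[2L])
    if (is.null(donor) || is.null(acceptor)) {
      fb_stop("freebed_malformed_input",
              sprintf("%s:%d: malformed junction key '%s'",
                      attr(rows, "file") %||% "<rows>", row_line(rows, i),
                      rows$junction[i]))
    }
    if (donor$chrom != acceptor$chrom) next  # cross-chromosome: dropped
    keep[i] <- TRUE
    chrom[i] <- donor$chrom
    start[i] <- min(donor$pos, acceptor$pos)
    end[i] <- max(donor$pos, acceptor$pos)
    strand[i] <- if (donor$strand == acceptor$strand) donor$strand else "*"
    donor_chrom[i] <- donor$chrom; donor_pos[i] <- donor$pos
    acceptor_chrom[i] <- acceptor$chrom; acceptor_pos[i] <- acceptor$pos
  }
  finish(chrom[keep], start[keep], end[keep], strand[keep],
         data.frame(junction = rows$junction[keep],
                    donor_chrom = donor_chrom[keep],
                    donor_pos = donor_pos[keep],
                    acceptor_chrom = acceptor_chrom[keep],
                    acceptor_pos = acceptor_pos[keep],
                    raw_counts = rows$raw_counts[keep],
                    stringsAsFactors = FALSE),
         schema, n, sum(!keep), list())
}

convert_rnaseqv2_isoform <- function(rows, store) {
  schema <- bed_schema("rnaseqv2", "isoform")
  require_columns(rows, c("isoform_id", "raw_count", "scaled_estimate",
                          "normalized_count"))
  n <- nrow(rows)
  keep <- logical(n)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  strand <- character(n); entrez <- character(n)
  misses <- list()
  for (i in seq_len(n)) {
    reg <- coords_by_ucsc(store, rows$isoform_id[i])
    if (is_annotation_miss(reg)) {
      misses[[length(misses) + 1L]] <- reg
      next
    }
    keep[i] <- TRUE
    chrom[i] <- reg$chrom; start[i] <- reg$start; end[i] <- reg$end
    strand[i] <- reg$strand; entrez[i] <- reg$entrez_id
  }
  finish(chrom[keep], start[keep], end[keep], strand[keep],
         data.frame(isoform_id = rows$isoform_id[keep],
                    entrez_gene_id = entrez[keep],
                    raw_count = rows$raw_count[keep],
                    scaled_estimate = rows$scaled_estimate[keep],
                    normalized_count = rows$normalized_count[keep],
                    stringsAsFactors = FALSE),
         schema, n, sum(!keep), misses)
}

# Dispatch table, keyed by (type[, subtype]); adding a data type requires
# only a new schema and a registration here.
.converter_registry <- list(
  cnv = convert_cnv,
  dnamethylation = convert_methylation,
  dnaseq = convert_dnaseq,
  mirnaseq = convert_mirnaseq,
  rnaseq.gene = convert_rnaseq_gene,
  rnaseq.exon = function(rows, store) convert_exon_quant(rows, store, bed_schema("rnaseq", "exon")),
  rnaseq.spljxn = function(rows, store) convert_spljxn(rows, store, bed_schema("rnaseq", "spljxn")),
  rnaseqv2.gene = convert_rnaseqv2_gene,
  rnaseqv2.exon = function(rows, store) convert_exon_quant(rows, store, bed_schema("rnaseqv2", "exon")),
  rnaseqv2.spljxn = function(rows, store) convert_spljxn(rows, store, bed_schema("rnaseqv2", "spljxn")),
  rnaseqv2.isoform = convert_rnaseqv2_isoform
)
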