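#' Local annotation store for coordinate/strand enrichment
#'
#' The original TCGA files often carry only an identifier (an Entrez Gene
#' id, a gene symbol, a UCSC transcript id, or a miRNA id) without genomic
#' coordinates. Four lookup chains over local tables recover the missing
#' chromosome/start/end/strand, mirroring what live queries against NCBI
#' Entrez Gene, HGNC, UCSC and miRBase would return:
#'
#' * `coords_by_entrez()`: Entrez Gene id -> coordinates + strand.
#' * `strand_by_symbol()`: gene symbol -> Entrez id (HGNC) -> strand.
#' * `coords_by_ucsc()`: UCSC transcript id -> Entrez id -> coordinates.
#' * `coords_by_mirna()`: miRNA id -> one or more genomic loci (miRBase;
#'   a miRNA may map to multiple placements).
#'
#' Tables are loaded once from tab-delimited files and kept in memory;
#' lookups never mutate the store. A failed lookup is a value (an
#' `annotation_miss` recording which link of the chain failed), not an
#' error. Symbol lookups are case-preserving; miRNA ids are matched
#' case-insensitively (miRBase ids are lowercase `hsa-...`). Versioned UCSC
#' ids (`uc001aaa.3`) fall back to the unversioned id when no exact match
#' exists. The store is genome-assembly-agnostic: the provenance of the
#' tables must declare the build.
#'
#' @param entrez_coords data.frame with columns `entrez_id`, `chrom`,
#'   `start`, `end`, `strand` (one-based closed).
#' @param symbol_to_entrez data.frame with columns `symbol`, `entrez_id`.
#' @param ucsc_to_entrez data.frame with columns `ucsc_id`, `entrez_id`.
#' @param mirna_coords data.frame with columns `mirna_id`, `chrom`, `start`,
#'   `end`, `strand`; `mirna_id` may repeat (multiple loci).
#' @return An `annotation_store` object.
#' @export
annotation_store <- function(entrez_coords = NULL, symbol_to_entrez = NULL,
                             ucsc_to_entrez = NULL, mirna_coords = NULL) {
  empty_coords <- data.frame(id = character(0), chrom = character(0),
                             start = integer(0), end = integer(0),
                             strand = character(0), stringsAsFactors = FALSE)
  norm_coords <- function(tab, id_col, lower_id = FALSE, dedup = TRUE) {
    if (is.null(tab) || nrow(tab) == 0L) return(empty_coords)
    out <- data.frame(id = as.character(tab[[id_col]]),
                      chrom = normalize_chrom(tab$chrom),
                      start = as.integer(tab$start),
                      end = as.integer(tab$end),
                      strand = as.character(tab$strand),
                      stringsAsFactors = FALSE)
    if (lower_id) out$id <- tolower(out$id)
    bad <- is.na(out$chrom) | is.na(out$start) | is.na(out$end) |
      out$start < 1L | out$start > out$end | !out$strand %in% c("+", "-", "*")
    if (any(bad)) {
      fb_stop("freebed_table_format",
              sprintf("invalid region in annotation table for id '%s'",
                      out$id[bad][1L]))
    }
    if (dedup && anyDuplicated(out$id)) {
      fb_warn("freebed_duplicate_key",
              sprintf("duplicate ids in annotation table (%d); last occurrence wins",
                      sum(duplicated(out$id))))
      out <- out[!duplicated(out$id, fromLast = TRUE), , drop = FALSE]
    }
    out
  }
  norm_map <- function(tab, from, to) {
    if (is.null(tab) || nrow(tab) == 0L) {
      return(stats::setNames(character(0), character(0)))
    }
    keys <- as.character(tab[[from]])
    vals <- as.character(tab[[to]])
    if (anyDuplicated(keys)) {
      fb_warn("freebed_duplicate_key",
              sprintf("duplicate keys in annotation table (%d); last occurrence wins",
                      sum(duplicated(keys))))
      keep <- !duplicated(keys, fromLast = TRUE)
      keys <- keys[keep]; vals <- vals[keep]
    }
    stats::setNames(vals, keys)
  }
  structure(
    list(
      entrez_coords = norm_coords(entrez_coords, "entrez_id"),
      symbol_to_entrez = norm_map(symbol_to_entrez, "symbol", "entrez_id"),
      ucsc_to_entrez = norm_map(ucsc_to_entrez, "ucsc_id", "entrez_id"),
      mirna_coords = norm_coords(mirna_coords, "mirna_id",
                                 lower_id = TRUE, dedup = FALSE)
    ),
    class = "annotation_store"
  )
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf(paste0("<annotation_store> %d entrez coords, %d symbols, ",
                     "%d ucsc ids, %d mirna loci\n"),
              nrow(x$entrez_coords), length(x$symbol_to_entrez),
              length(x$ucsc_to_entrez), nrow(x$mirna_coords)))
  invisible(x)
}

map_get <- function(map, key) {
  i <- match(key, names(map))
  if (is.na(i)) NA_character_ else unname(map[i])
}

annotation_miss <- function(id_kind, id_value, stage) {
  structure(list(id_kind = id_kind, id_value = id_value, stage = stage),
            class = "annotation_miss")
}

#' @rdname annotation_store
#' @param x Object to test.
#' @export
is_annotation_miss <- function(x) inherits(x, "annotation_miss")

region_row <- function(tab, i) {
  list(chrom = tab$chrom[i], start = tab$start[i], end = tab$end[i],
       strand = tab$strand[i])
}

#' @rdname annotation_store
#' @param store An `annotation_store`.
#' @param gene_id Entrez Gene id (coerced to character).
#' @return `coords_by_entrez()` returns a region (list with `chrom`,
#'   `start`, `end`, `strand`) or an `annotation_miss`.
#' @export
coords_by_entrez <- function(store, gene_id) {
  i <- match(as.character(gene_id), store$entrez_coords$id)
  if (is.na(i)) return(annotation_miss("entrez", as.character(gene_id), "entrez_coords"))
  region_row(store$entrez_coords, i)
}

#' @rdname annotation_store
#' @param symbol HGNC gene symbol (case-preserving lookup).
#' @return `strand_by_symbol()` returns `"+"`/`"-"`/`"*"` or an
#'   `annotation_miss` whose `stage` names the failed link
#'   (`symbol_to_entrez` or `entrez_coords`).
#' @export
strand_by_symbol <- function(store, symbol) {
  eid <- map_get(store$symbol_to_entrez, as.character(symbol))
  if (is.na(eid)) return(annotation_miss("symbol", as.character(symbol), "symbol_to_entrez"))
  reg <- coords_by_entrez(store, eid)
  if (is_annotation_miss(reg)) {
    return(annotation_miss("symbol", as.character(symbol), "entrez_coords"))
  }
  reg$strand
}

#' @rdname annotation_store
#' @param transcript_id UCSC transcript id; a versioned id (`uc001aaa.3`)
#'   falls back to the unversioned form when the exact id is absent.
#' @export
coords_by_ucsc <- function(store, transcript_id) {
  tid <- as.character(transcript_id)
  eid <- map_get(store$ucsc_to_entrez, tid)
  if (is.na(eid)) {
    stripped <- sub("\\.[0-9]+$", "", tid)
    if (!identical(stripped, tid)) eid <- map_get(store$ucsc_to_entrez, stripped)
  }
  if (is.na(eid)) return(annotation_miss("ucsc", tid, "ucsc_to_entrez"))
  reg <- coords_by_entrez(store, eid)
  if (is_annotation_miss(reg)) return(annotation_miss("ucsc", tid, "entrez_coords"))
  reg$entrez_id <- eid
  reg
}

#' @rdname annotation_store
#' @param mirna_id miRNA id, matched case-insensitively.
#' @return `coords_by_mirna()` returns a list of one or more regions (in
#'   store order) or an `annotation_miss`.
#' @export
coords_by_mirna <- function(store, mirna_id) {
  key <- tolower(as.character(mirna_id))
  idx <- which(store$mirna_coords$id == key)
  if (length(idx) == 0L) return(annotation_miss("mirna", as.character(mirna_id), "mirna_coords"))
  lapply(idx, function(i) region_row(store$mirna_coords, i))
}

read_annotation_table <- function(path, columns) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) {
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(columns)),
                                         columns)))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, columns)) {
    fb_stop("freebed_table_format",
            sprintf("%s:1: expected header '%s', found '%s'",
                    path, paste(columns, collapse = "\t"),
                    paste(header, collapse = "\t")))
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(columns))) {
    bad <- which(nfield != length(columns))[1L]
    fb_stop("freebed_table_format",
            sprintf("%s:%d: expected %d tab-separated columns, found %d",
                    path, bad + 1L, length(columns), nfield[bad]))
  }
  mat <- matrix(unlist(parts), ncol = length(columns), byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- columns
  out
}

#' Load and persist annotation tables
#'
#' `load_annotation_store()` reads the four tab-delimited lookup tables.
#' `save_annotation_cache()` persists a store to a single tab-delimited
#' cache file (leading table-name column) that `load_annotation_cache()`
#' reloads bit-exactly, so repeated conversion runs skip the per-table
#' parsing — the local stand-in for periodically tracking remote database
#' content.
#'
#' @param entrez_coords,symbol_to_entrez,ucsc_to_entrez,mirna_coords Paths
#'   to the four tables (headers required; see [annotation_store()] for
#'   columns). `NULL` loads an empty table.
#' @return An `annotation_store`.
#' @export
load_annotation_store <- function(entrez_coords = NULL, symbol_to_entrez = NULL,
                                  ucsc_to_entrez = NULL, mirna_coords = NULL) {
  rd <- function(path, cols) {
    if (is.null(path)) NULL else read_annotation_table(path, cols)
  }
  annotation_store(
    entrez_coords = rd(entrez_coords, c("entrez_id", "chrom", "start", "end", "strand")),
    symbol_to_entrez = rd(symbol_to_entrez, c("symbol", "entrez_id")),
    ucsc_to_entrez = rd(ucsc_to_entrez, c("ucsc_id", "entrez_id")),
    mirna_coords = rd(mirna_coords, c("mirna_id", "chrom", "start", "end", "strand"))
  )
}

#' @rdname load_annotation_store
#' @param dir A directory holding `entrez_coords.tsv`, `symbol_to_entrez.tsv`,
#'   `ucsc_to_entrez.tsv`, `mirna_coords.tsv` (missing files load empty).
#' @export
load_annotation_dir <- function(dir) {
  p <- function(name) {
    f <- file.path(dir, paste0(name, ".tsv"))
    if (file.exists(f)) f else NULL
  }
  load_annotation_store(entrez_coords = p("entrez_coords"),
                        symbol_to_entrez = p("symbol_to_entrez"),
                        ucsc_to_entrez = p("ucsc_to_entrez"),
                        mirna_coords = p("mirna_coords"))
}

#' @rdname load_annotation_store
#' @param store An `annotation_store`.
#' @param path Cache file path.
#' @export
save_annotation_cache <- function(store, path) {
  stopifnot(inherits(store, "annotation_store"))
  rows <- character(0)
  ec <- store$entrez_coords
  if (nrow(ec)) {
    rows <- c(rows, sprintf("entrez_coords\t%s\t%s\t%d\t%d\t%s",
                            ec$id, ec$chrom, ec$start, ec$end, ec$strand))
  }
  if (length(store$symbol_to_entrez)) {
    rows <- c(rows, sprintf("symbol_to_entrez\t%s\t%s",
                            names(store$symbol_to_entrez),
                            unname(store$symbol_to_entrez)))
  }
  if (length(store$ucsc_to_entrez)) {
    rows <- c(rows, sprintf("ucsc_to_entrez\t%s\t%s",
                            names(store$ucsc_to_entrez),
                            unname(store$ucsc_to_entrez)))
  }
  mc <- store$mirna_coords
  if (nrow(mc)) {
    rows <- c(rows, sprintf("mirna_coords\t%s\t%s\t%d\t%d\t%s",
                            mc$id, mc$chrom, mc$start, mc$end, mc$strand))
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname load_annotation_store
#' @export
load_annotation_cache <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab_of <- vapply(parts, `[[`, "", 1L)
  get_coords <- function(name, id_col) {
    sel <- parts[tab_of == name]
    if (length(sel) == 0L) return(NULL)
    if (any(lengths(sel) != 6L)) {
      bad <- which(tab_of == name)[which(lengths(sel) != 6L)[1L]]
      fb_stop("freebed_table_format",
              sprintf("%s:%d: malformed cache row", path, bad))
    }
    mat <- matrix(unlist(sel), ncol = 6L, byrow = TRUE)
    stats::setNames(
      data.frame(mat[, 2L], mat[, 3L], as.integer(mat[, 4L]),
                 as.integer(mat[, 5L]), mat[, 6L], stringsAsFactors = FALSE),
      c(id_col, "chrom", "start", "end", "strand"))
  }
  get_map <- function(name, from, to) {
    sel <- parts[tab_of == name]
    if (length(sel) == 0L) return(NULL)
    if (any(lengths(sel) != 3L)) {
      bad <- which(tab_of == name)[which(lengths(sel) != 3L)[1L]]
      fb_stop("freebed_table_format",
              sprintf("%s:%d: malformed cache row", path, bad))
    }
    mat <- matrix(unlist(sel), ncol = 3L, byrow = TRUE)
    stats::setNames(data.frame(mat[, 2L], mat[, 3L], stringsAsFactors = FALSE),
                    c(from, to))
  }
  annotation_store(
    entrez_coords = get_coords("entrez_coords", "entrez_id"),
    symbol_to_entrez = get_map("symbol_to_entrez", "symbol", "entrez_id"),
    ucsc_to_entrez = get_map("ucsc_to_entrez", "ucsc_id", "entrez_id"),
    mirna_coords = get_coords("mirna_coords", "mirna_id")
  )
}
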