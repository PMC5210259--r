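#' Flatten a clinical or biospecimen document to attribute-value pairs
#'
#' Clinical and biospecimen documents are hierarchical XML; each non-empty
#' leaf element becomes one `(key, value)` pair. The key is the path of
#' element names from the root (root excluded) joined by `"__"` and
#' lowercased; repeated sibling leaves with the same name are
#' disambiguated with a 1-based `"__k"` suffix. Attribute order within
#' elements is irrelevant (only element structure and text matter).
#'
#' @param doc An `xml_document`, or a path to an XML file.
#' @return A named character vector (names are keys).
#' @examples
#' doc <- xml2::read_xml(
#'   "<patient><gender>FEMALE</gender><race>WHITE</race><race>ASIAN</race></patient>")
#' flatten_metadata_doc(doc)
#' @export
flatten_metadata_doc <- function(doc) {
  if (is.character(doc)) {
    doc <- tryCatch(xml2::read_xml(doc), error = function(e) {
      fb_stop("freebed_document_parse",
              sprintf("cannot parse metadata document: %s", conditionMessage(e)))
    })
  }
  root <- if (inherits(doc, "xml_document")) xml2::xml_root(doc) else doc
  pairs <- list()
  walk <- function(node, prefix) {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0L) {
      value <- trimws(xml2::xml_text(node))
      if (nzchar(value)) {
        key <- tolower(paste(prefix, collapse = "__"))
        pairs[[length(pairs) + 1L]] <<- c(key, value)
      }
      return(invisible())
    }
    names_k <- xml2::xml_name(kids)
    dup <- names_k %in% names_k[duplicated(names_k)]
    counter <- stats::setNames(integer(length(unique(names_k))), unique(names_k))
    for (i in seq_along(kids)) {
      nm <- names_k[i]
      seg <- nm
      if (dup[i]) {
        counter[nm] <- counter[nm] + 1L
        seg <- paste0(nm, "__", counter[nm])
      }
      walk(kids[[i]], c(prefix, seg))
    }
  }
  walk(root, character(0))
  if (length(pairs) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(vapply(pairs, `[[`, "", 2L), vapply(pairs, `[[`, "", 1L))
}

#' Assemble the per-aliquot .meta record
#'
#' Clinical data are per patient and biospecimen data per sample/aliquot;
#' the aliquot-oriented organization denormalizes both into one flat
#' record per aliquot. Clinical keys get the `clinical__` prefix,
#' biospecimen keys `biospecimen__` (preventing collisions between fields
#' with identical names in both sources), and three provenance keys are
#' always present: `manually_curated__tumor_tag`,
#' `manually_curated__exp_data_type`,
#' `manually_curated__tcga_aliquot_barcode`. Keys are unique and sorted.
#'
#' A linkage error is raised when the clinical document's patient barcode
#' does not match the aliquot's patient id, or a biospecimen barcode does
#' not belong to the aliquot.
#'
#' @param aliquot A `tcga_barcode` or barcode string.
#' @param clinical_pairs,biospecimen_pairs Named character vectors from
#'   [flatten_metadata_doc()].
#' @param tumor_tag,exp_data_type Provenance values.
#' @return A `meta_record`: named character vector of pairs, sorted by
#'   key, with the aliquot kept in `attr(, "aliquot")`.
#' @export
assemble_meta <- function(aliquot, clinical_pairs, biospecimen_pairs,
                          tumor_tag, exp_data_type) {
  b <- as_tcga_barcode(aliquot)
  full <- format(b)
  pid <- tcga_patient_id(b)
  doc_pid <- map_get(clinical_pairs, "bcr_patient_barcode")
  if (!is.na(doc_pid) && !identical(unname(doc_pid), pid)) {
    fb_stop("freebed_linkage",
            sprintf("clinical document for patient '%s' attached to aliquot '%s'",
                    doc_pid, full))
  }
  doc_aid <- map_get(biospecimen_pairs, "bcr_aliquot_barcode")
  if (!is.na(doc_aid) && !identical(unname(doc_aid), full)) {
    fb_stop("freebed_linkage",
            sprintf("biospecimen entry for aliquot '%s' attached to aliquot '%s'",
                    doc_aid, full))
  }
  pairs <- c(
    if (length(clinical_pairs)) {
      stats::setNames(unname(clinical_pairs),
                      paste0("clinical__", names(clinical_pairs)))
    },
    if (length(biospecimen_pairs)) {
      stats::setNames(unname(biospecimen_pairs),
                      paste0("biospecimen__", names(biospecimen_pairs)))
    },
    stats::setNames(
      c(tumor_tag, exp_data_type, full),
      c("manually_curated__tumor_tag", "manually_curated__exp_data_type",
        "manually_curated__tcga_aliquot_barcode"))
  )
  if (anyDuplicated(names(pairs))) {
    fb_stop("freebed_linkage", "duplicate metadata keys after prefixing")
  }
  pairs <- pairs[order(names(pairs), method = "radix")]
  structure(pairs, class = "meta_record", aliquot = full)
}

#' Write and read .meta files
#'
#' Line format is `key<TAB>value`, UTF-8, sorted by key — a bit-exact
#' contract so identical inputs always produce identical files.
#'
#' @param meta A `meta_record` (or any named character vector).
#' @param path File path.
#' @export
write_meta <- function(meta, path) {
  keys <- names(meta)
  o <- order(keys, method = "radix")
  writeLines(paste(keys[o], unname(meta)[o], sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- which(lengths(parts) != 2L)[1L]
    fb_stop("freebed_malformed_input",
            sprintf("%s:%d: expected key<TAB>value", path, bad))
  }
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' Build the per-data-type metadata dictionary
#'
#' The dictionary maps every metadata attribute observed across a set of
#' meta records to the exact set of distinct values it assumes — no more,
#' no fewer.
#'
#' @param records List of `meta_record`s (or named character vectors).
#' @return Named list: attribute key -> sorted character vector of
#'   distinct values.
#' @export
build_metadata_dictionary <- function(records) {
  keys <- unlist(lapply(records, names), use.names = FALSE)
  vals <- unlist(lapply(records, unname), use.names = FALSE)
  if (length(keys) == 0L) return(stats::setNames(list(), character(0)))
  dict <- lapply(split(vals, keys), function(v) sort(unique(v), method = "radix"))
  dict[order(names(dict), method = "radix")]
}

#' @rdname build_metadata_dictionary
#' @param dict A dictionary from `build_metadata_dictionary()`.
#' @param path Output path; each line is `key<TAB>v1<TAB>v2...` with values
#'   sorted lexicographically.
#' @export
write_metadata_dictionary <- function(dict, path) {
  lines <- vapply(names(dict), function(k) {
    paste(c(k, dict[[k]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname build_metadata_dictionary
#' @export
read_metadata_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-1L]),
                  vapply(parts, `[[`, "", 1L))
}
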