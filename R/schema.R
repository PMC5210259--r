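#' Per-data-type column schemas
#'
#' Every (experiment type, subtype) pair has a fixed, ordered column schema.
#' The first four columns are always the mandatory free-BED fields `chrom`,
#' `chromStart`, `chromEnd`, `strand`; the remaining N columns are the
#' type-specific attribute tail carried over from the original TCGA layout
#' (plus, for splice junctions, ad-hoc donor/acceptor columns added to ease
#' downstream processing). The schema is the source of the `header.schema`
#' descriptor written next to each output directory.
#'
#' @param type One of `"cnv"`, `"dnamethylation"`, `"dnaseq"`, `"mirnaseq"`,
#'   `"rnaseq"`, `"rnaseqv2"`.
#' @param subtype For `rnaseq`: `"gene"`, `"exon"` or `"spljxn"`; for
#'   `rnaseqv2` additionally `"isoform"`. `NULL` for the other types.
#' @return A `bed_schema` object: list with `experiment_type`, `subtype`
#'   (`NA` when none) and `columns` (data.frame of `name`, `kind`).
#' @examples
#' s <- bed_schema("rnaseqv2", "gene")
#' s$columns$name
#' @export
bed_schema <- function(type, subtype = NULL) {
  key <- schema_key_parts(type, subtype)
  sch <- .schema_registry[[key]]
  if (is.null(sch)) {
    fb_stop("freebed_config_error",
            sprintf("no schema registered for type '%s' subtype '%s'",
                    type, if (is.null(subtype)) "<none>" else subtype))
  }
  sch
}

EXPERIMENT_TYPES <- c("cnv", "dnamethylation", "dnaseq", "mirnaseq",
                      "rnaseq", "rnaseqv2")

MANDATORY_FIELDS <- c("chrom", "chromStart", "chromEnd", "strand")

schema_key_parts <- function(type, subtype) {
  if (is.null(subtype) || is.na(subtype)) type else paste(type, subtype, sep = ".")
}

schema_key <- function(schema) {
  schema_key_parts(schema$experiment_type, schema$subtype)
}

#' @rdname bed_schema
#' @return `bed_subtypes()` returns the character vector of subtypes for a
#'   type (`NA` for subtype-less types); `bed_schema_keys()` all registered
#'   keys.
#' @export
bed_subtypes <- function(type) {
  if (!type %in% EXPERIMENT_TYPES) {
    fb_stop("freebed_config_error", sprintf("unknown experiment type '%s'", type))
  }
  switch(type,
    rnaseq = c("gene", "exon", "spljxn"),
    rnaseqv2 = c("gene", "exon", "spljxn", "isoform"),
    NA_character_
  )
}

#' @rdname bed_schema
#' @export
bed_schema_keys <- function() names(.schema_registry)

new_schema <- function(type, subtype, attrs) {
  cols <- rbind(
    data.frame(name = MANDATORY_FIELDS,
               kind = c("string", "integer", "integer", "char"),
               stringsAsFactors = FALSE),
    attrs
  )
  if (anyDuplicated(cols$name)) {
    fb_stop("freebed_schema_error", "duplicate column names in schema")
  }
  structure(
    list(experiment_type = type,
         subtype = if (is.null(subtype)) NA_character_ else subtype,
         columns = cols),
    class = "bed_schema"
  )
}

attr_cols <- function(names, kinds) {
  data.frame(name = names, kind = kinds, stringsAsFactors = FALSE)
}

attribute_names <- function(schema) {
  setdiff(schema$columns$name, MANDATORY_FIELDS)
}

attribute_kind <- function(schema, name) {
  schema$columns$kind[match(name, schema$columns$name)]
}

#' @export
print.bed_schema <- function(x, ...) {
  cat(sprintf("<bed_schema> %s: %d columns (%s)\n", schema_key(x),
              nrow(x$columns), paste(x$columns$name, collapse = ", ")))
  invisible(x)
}

# The registered schemas. Attribute tails mirror the original level-2/3
# column layouts; names are lowercased snake_case.
.schema_registry <- local({
  reg <- list()
  add <- function(type, subtype, names, kinds) {
    reg[[schema_key_parts(type, subtype)]] <<- new_schema(type, subtype,
                                                          attr_cols(names, kinds))
  }
  add("cnv", NULL,
      c("num_probes", "segment_mean"),
      c("integer", "float"))
  add("dnamethylation", NULL,
      c("composite_element_ref", "beta_value", "gene_symbol"),
      c("string", "float", "string"))
  add("dnaseq", NULL,
      c("hugo_symbol", "entrez_gene_id", "variant_classification",
        "variant_type", "reference_allele", "tumor_seq_allele1",
        "tumor_seq_allele2", "dbsnp_rs", "tumor_sample_barcode",
        "matched_norm_sample_barcode", "mutation_status", "sequencer",
        "validation_status"),
      c("string", "string", "string", "string", "string", "string",
        "string", "string", "string", "string", "string", "string",
        "string"))
  add("mirnaseq", NULL,
      c("mirna_id", "read_count", "reads_per_million_mirna_mapped",
        "cross_mapped"),
      c("string", "integer", "float", "char"))
  add("rnaseq", "gene",
      c("entrez_gene_id", "gene_symbol", "raw_counts",
        "median_length_normalized", "rpkm"),
      c("string", "string", "integer", "float", "float"))
  add("rnaseq", "exon",
      c("exon", "raw_counts", "median_length_normalized", "rpkm"),
      c("string", "integer", "float", "float"))
  add("rnaseq", "spljxn",
      c("junction", "donor_chrom", "donor_pos", "acceptor_chrom",
        "acceptor_pos", "raw_counts"),
      c("string", "string", "integer", "string", "integer", "integer"))
  add("rnaseqv2", "gene",
      c("entrez_gene_id", "gene_symbol", "raw_count", "scaled_estimate",
        "normalized_count"),
      c("string", "string", "integer", "float", "float"))
  add("rnaseqv2", "exon",
      c("exon", "raw_counts", "median_length_normalized", "rpkm"),
      c("string", "integer", "float", "float"))
  add("rnaseqv2", "spljxn",
      c("junction", "donor_chrom", "donor_pos", "acceptor_chrom",
        "acceptor_pos", "raw_counts"),
      c("string", "string", "integer", "string", "integer", "integer"))
  add("rnaseqv2", "isoform",
      c("isoform_id", "entrez_gene_id", "raw_count", "scaled_estimate",
        "normalized_count"),
      c("string", "string", "integer", "float", "float"))
  reg
})
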