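#' TCGA aliquot barcodes
#'
#' An aliquot barcode is the unit of analysis of TCGA genomic data: a
#' human-readable, tumor-sample-specific identifier of the form
#' `TCGA-<tss>-<participant>-<sample><vial>-<portion><analyte>-<plate>-<center>`,
#' e.g. `TCGA-02-0021-01A-01D-0002-04`. The first three dash-separated groups
#' identify the patient, the first four the sample. Validation is strict on
#' structure (group count, lengths, character classes) but permissive on the
#' actual tissue-source-site and center codes, for which no registry is
#' shipped.
#'
#' @param text A single barcode string.
#' @return `parse_tcga_barcode()` returns a `tcga_barcode` object: a named
#'   list with components `tss`, `participant`, `sample`, `vial`, `portion`,
#'   `analyte`, `plate`, `center`.
#' @examples
#' b <- parse_tcga_barcode("TCGA-02-0021-01A-01D-0002-04")
#' b$participant
#' format(b)
#' tcga_patient_id(b)
#' tcga_sample_id(b)
#' @export
parse_tcga_barcode <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    fb_stop("freebed_malformed_barcode", "barcode must be a single non-empty string")
  }
  parts <- strsplit(text, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 7L || parts[1L] != "TCGA") {
    fb_stop("freebed_malformed_barcode",
            sprintf("malformed barcode '%s': expected 7 dash-separated groups starting with TCGA", text))
  }
  ok <- grepl("^[0-9A-Z]{2}$", parts[2L]) &&
    grepl("^[0-9A-Z]{4}$", parts[3L]) &&
    grepl("^[0-9]{2}[A-Z]$", parts[4L]) &&
    grepl("^[0-9]{2}[A-Z]$", parts[5L]) &&
    grepl("^[0-9A-Z]{4}$", parts[6L]) &&
    grepl("^[0-9]{2}$", parts[7L])
  if (!ok) {
    fb_stop("freebed_malformed_barcode",
            sprintf("malformed barcode '%s': group lengths or character classes do not match", text))
  }
  structure(
    list(
      tss = parts[2L],
      participant = parts[3L],
      sample = substr(parts[4L], 1L, 2L),
      vial = substr(parts[4L], 3L, 3L),
      portion = substr(parts[5L], 1L, 2L),
      analyte = substr(parts[5L], 3L, 3L),
      plate = parts[6L],
      center = parts[7L]
    ),
    class = "tcga_barcode"
  )
}

#' @rdname parse_tcga_barcode
#' @param x A `tcga_barcode`.
#' @param ... Ignored.
#' @export
format.tcga_barcode <- function(x, ...) {
  sprintf("TCGA-%s-%s-%s%s-%s%s-%s-%s",
          x$tss, x$participant, x$sample, x$vial,
          x$portion, x$analyte, x$plate, x$center)
}

#' @export
print.tcga_barcode <- function(x, ...) {
  cat("<tcga_barcode> ", format(x), "\n", sep = "")
  invisible(x)
}

as_tcga_barcode <- function(x) {
  if (inherits(x, "tcga_barcode")) x else parse_tcga_barcode(x)
}

#' @rdname parse_tcga_barcode
#' @param barcode A `tcga_barcode` or barcode string.
#' @return `tcga_patient_id()` returns `"TCGA-<tss>-<participant>"`;
#'   `tcga_sample_id()` additionally appends `<sample><vial>`.
#' @export
tcga_patient_id <- function(barcode) {
  b <- as_tcga_barcode(barcode)
  sprintf("TCGA-%s-%s", b$tss, b$participant)
}

#' @rdname parse_tcga_barcode
#' @export
tcga_sample_id <- function(barcode) {
  b <- as_tcga_barcode(barcode)
  sprintf("TCGA-%s-%s-%s%s", b$tss, b$participant, b$sample, b$vial)
}
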