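#' Output file naming
#'
#' Every aliquot yields `<full-aliquot-barcode>.<ext>` data files; the
#' metadata companion is format-independent and attached to the canonical
#' BED name as `<barcode>.bed.meta`. Barcode alphabet guarantees
#' filesystem-safe names.
#'
#' @param barcode A `tcga_barcode` or barcode string.
#' @param format One of `"bed"`, `"csv"`, `"gtf"`, `"json"`, `"xml"`,
#'   `"meta"`.
#' @return The file name.
#' @examples
#' aliquot_file_name("TCGA-02-0021-01A-01D-0002-04", "bed")
#' aliquot_file_name("TCGA-02-0021-01A-01D-0002-04", "meta")
#' @export
aliquot_file_name <- function(barcode, format) {
  bc <- format(as_tcga_barcode(barcode))
  if (identical(format, "meta")) return(paste0(bc, ".bed.meta"))
  if (!format %in% OUTPUT_FORMATS) {
    fb_stop("freebed_config_error", sprintf("unknown output format '%s'", format))
  }
  paste0(bc, ".", format)
}

OUTPUT_FORMATS <- c("bed", "csv", "gtf", "json", "xml")

FORMAT_WRITERS <- list(bed = function(r, s, p) write_bed(r, s, p),
                       csv = function(r, s, p) write_bed_csv(r, s, p),
                       gtf = function(r, s, p) write_bed_gtf(r, s, p),
                       json = function(r, s, p) write_bed_json(r, s, p),
                       xml = function(r, s, p) write_bed_xml(r, s, p))

# Source-file suffix -> subtype, per experiment type. The shipped source
# adapter reads a local directory tree (tcga_original/<TAG>/<type>/
# <barcode>.<suffix>.txt); the retired portal-download path is out of
# scope by design.
SOURCE_SUFFIXES <- list(
  cnv = c(cnv = NA),
  dnamethylation = c(dnamethylation = NA),
  dnaseq = c(maf = NA),
  mirnaseq = c(mirnaseq = NA),
  rnaseq = c(gene = "gene", exon = "exon", spljxn = "spljxn"),
  rnaseqv2 = c(gene = "gene", exon = "exon", spljxn = "spljxn",
               isoform = "isoform")
)

#' Read an XML conversion-run configuration
#'
#' One `<job>` element per run item, with child elements `source`,
#' `tumor`, `type`, `formats` (comma-separated), `annotations`, `out`.
#'
#' @param path Config file path.
#' @return A list of job lists, as accepted by [run_convert()].
#' @export
read_convert_config <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    fb_stop("freebed_config_error",
            sprintf("cannot parse config '%s': %s", path, conditionMessage(e)))
  })
  jobs <- xml2::xml_find_all(doc, "job")
  if (length(jobs) == 0L) {
    fb_stop("freebed_config_error", sprintf("%s: no <job> elements", path))
  }
  lapply(jobs, function(j) {
    get <- function(name) {
      n <- xml2::xml_find_first(j, name)
      if (inherits(n, "xml_missing")) {
        fb_stop("freebed_config_error",
                sprintf("%s: <job> missing <%s>", path, name))
      }
      xml2::xml_text(n)
    }
    list(source = get("source"), tumor = get("tumor"), type = get("type"),
         formats = strsplit(get("formats"), ",", fixed = TRUE)[[1L]],
         annotations = get("annotations"), out = get("out"))
  })
}

validate_job <- function(job) {
  needed <- c("source", "tumor", "type", "formats", "annotations", "out")
  missing <- setdiff(needed, names(job))
  if (length(missing)) {
    fb_stop("freebed_config_error",
            sprintf("job missing field(s): %s", paste(missing, collapse = ", ")))
  }
  if (!job$type %in% EXPERIMENT_TYPES) {
    fb_stop("freebed_config_error",
            sprintf("unknown experiment type '%s'", job$type))
  }
  bad <- setdiff(job$formats, OUTPUT_FORMATS)
  if (length(bad)) {
    fb_stop("freebed_config_error",
            sprintf("unknown output format(s): %s", paste(bad, collapse = ", ")))
  }
  if (!dir.exists(file.path(job$source, job$type))) {
    fb_stop("freebed_config_error",
            sprintf("source directory '%s' has no '%s' subdirectory",
                    job$source, job$type))
  }
  invisible(job)
}

log_line <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

# Biospecimen pairs for one aliquot: sample-level leaves plus the leaves
# of the matching <aliquot> element (other aliquots are irrelevant to
# this record).
biospecimen_pairs_for_aliquot <- function(path, barcode) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//aliquot")
  hit <- NULL
  for (n in nodes) {
    bc <- xml2::xml_text(xml2::xml_find_first(n, "bcr_aliquot_barcode"))
    if (identical(bc, barcode)) { hit <- n; break }
  }
  if (is.null(hit)) {
    fb_stop("freebed_linkage",
            sprintf("%s: no biospecimen entry for aliquot '%s'", path, barcode))
  }
  sample_doc <- xml2::xml_new_root("sample")
  for (kid in xml2::xml_children(doc)) {
    if (xml2::xml_name(kid) != "aliquots") {
      xml2::xml_add_child(sample_doc, kid)
    }
  }
  c(flatten_metadata_doc(sample_doc), flatten_metadata_doc(hit))
}

#' Run source-to-repository conversion jobs
#'
#' The orchestration entry point: each job names a source tumor directory
#' (the `tcga_original/<TAG>` layout emitted by [generate_cohort()]), an
#' experiment type, the output formats, the annotation-table directory
#' and the output root. For every source experiment file the matching
#' converter runs, the records are written in each requested format, the
#' aliquot's `.meta` companion is assembled from the clinical and
#' biospecimen documents, and each output directory receives one
#' `header.schema` and one `metadata_dictionary.txt`. Layout:
#' `bed/<tumor-tag-lowercase>/<type>/` for subtype-less types and
#' `bed/<tag>/<type>/<subtype>/` for the RNA-seq families (each subtype
#' has its own schema, hence its own descriptor files).
#'
#' All jobs are validated before any output is written; an invalid type
#' or format aborts the whole run with a config error. Re-running an
#' unchanged config over unchanged inputs rewrites byte-identical
#' outputs.
#'
#' @param jobs A list of job lists (`source`, `tumor`, `type`, `formats`,
#'   `annotations`, `out`), or a single job list.
#' @param config Alternatively, path to an XML config file
#'   ([read_convert_config()]).
#' @param quiet Suppress progress logging.
#' @return A run report: per-job file reports plus aggregate totals
#'   (`rows_in`, `records_out`, `dropped`, `misses`, `files`, `ok`).
#' @export
run_convert <- function(jobs = NULL, config = NULL, quiet = FALSE) {
  if (is.null(jobs) && is.null(config)) {
    fb_stop("freebed_config_error", "either jobs or config is required")
  }
  if (!is.null(config)) jobs <- read_convert_config(config)
  if (!is.null(names(jobs)) && "type" %in% names(jobs)) jobs <- list(jobs)
  lapply(jobs, validate_job)  # fail before any work starts

  job_reports <- lapply(jobs, function(job) {
    tryCatch(run_one_job(job, quiet = quiet),
             freebed_error = function(e) {
               log_line("job failed (%s/%s): %s", job$tumor, job$type,
                        conditionMessage(e))
               list(tumor = job$tumor, type = job$type, ok = FALSE,
                    error = conditionMessage(e), files = list(),
                    totals = new_report(0L, 0L, 0L))
             })
  })
  totals <- list(
    rows_in = sum(vapply(job_reports, function(j) j$totals$rows_in, 0L)),
    records_out = sum(vapply(job_reports, function(j) j$totals$records_out, 0L)),
    dropped = sum(vapply(job_reports, function(j) j$totals$dropped, 0L)),
    misses = sum(vapply(job_reports, function(j) length(j$totals$misses), 0L)),
    files = sum(vapply(job_reports, function(j) length(j$files), 0L))
  )
  structure(list(jobs = job_reports, totals = totals,
                 ok = all(vapply(job_reports, `[[`, TRUE, "ok"))),
            class = "freebed_run_report")
}

#' @export
print.freebed_run_report <- function(x, ...) {
  cat(sprintf("<freebed_run_report> %d job(s), %s\n", length(x$jobs),
              if (x$ok) "ok" else "FAILED"))
  cat(sprintf("  files: %d  rows in: %d  records out: %d  dropped: %d  misses: %d\n",
              x$totals$files, x$totals$rows_in, x$totals$records_out,
              x$totals$dropped, x$totals$misses))
  invisible(x)
}

run_one_job <- function(job, quiet = FALSE) {
  store <- load_annotation_dir(job$annotations)
  type <- job$type
  src_type_dir <- file.path(job$source, type)
  meta_dir <- file.path(job$source, "meta")
  suffixes <- SOURCE_SUFFIXES[[type]]
  files <- sort(list.files(src_type_dir, pattern = "\\.txt$"), method = "radix")

  file_reports <- list()
  # meta records per output directory, for the per-directory dictionary
  dir_meta <- list()
  dir_schema <- list()

  for (f in files) {
    m <- regmatches(f, regexec("^(TCGA-[^.]+)\\.([^.]+)\\.txt$", f))[[1L]]
    if (length(m) != 3L || !m[3L] %in% names(suffixes)) {
      fb_stop("freebed_malformed_input",
              sprintf("unrecognized source file name '%s' for type '%s'", f, type))
    }
    barcode <- m[2L]
    subtype <- suffixes[[m[3L]]]
    if (is.na(subtype)) subtype <- NULL
    schema <- bed_schema(type, subtype)

    rows <- read_tcga_table(file.path(src_type_dir, f))
    res <- convert_records(rows, type, subtype, store)
    if (!quiet) {
      log_line("%s/%s: %s: %d rows -> %d records (%d dropped, %d misses)",
               job$tumor, schema_key(schema), barcode, res$report$rows_in,
               res$report$records_out, res$report$dropped,
               length(res$report$misses))
    }

    out_dir <- file.path(job$out, "bed", tolower(job$tumor), type)
    if (!is.null(subtype)) out_dir <- file.path(out_dir, subtype)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

    for (fmt in job$formats) {
      FORMAT_WRITERS[[fmt]](res$records, schema,
                            file.path(out_dir, aliquot_file_name(barcode, fmt)))
    }

    meta <- assemble_aliquot_meta(meta_dir, barcode, job$tumor, type)
    write_meta(meta, file.path(out_dir, aliquot_file_name(barcode, "meta")))

    dir_meta[[out_dir]] <- c(dir_meta[[out_dir]], list(meta))
    dir_schema[[out_dir]] <- schema
    file_reports[[f]] <- res$report
  }

  for (d in names(dir_meta)) {
    write_header_schema(dir_schema[[d]], file.path(d, "header.schema"))
    write_metadata_dictionary(build_metadata_dictionary(dir_meta[[d]]),
                              file.path(d, "metadata_dictionary.txt"))
  }

  totals <- new_report(
    sum(vapply(file_reports, `[[`, 0L, "rows_in")),
    sum(vapply(file_reports, `[[`, 0L, "records_out")),
    sum(vapply(file_reports, `[[`, 0L, "dropped")),
    misses = do.call(c, c(list(), lapply(file_reports, `[[`, "misses")))
  )
  list(tumor = job$tumor, type = type, ok = TRUE, files = file_reports,
       totals = totals)
}

assemble_aliquot_meta <- function(meta_dir, barcode, tumor_tag, type) {
  b <- as_tcga_barcode(barcode)
  clin_path <- file.path(meta_dir, paste0(tcga_patient_id(b), ".clinical.xml"))
  bio_path <- file.path(meta_dir, paste0(tcga_sample_id(b), ".biospecimen.xml"))
  clinical <- if (file.exists(clin_path)) {
    flatten_metadata_doc(clin_path)
  } else stats::setNames(character(0), character(0))
  biospecimen <- if (file.exists(bio_path)) {
    biospecimen_pairs_for_aliquot(bio_path, format(b))
  } else stats::setNames(character(0), character(0))
  assemble_meta(b, clinical, biospecimen, tumor_tag, type)
}
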