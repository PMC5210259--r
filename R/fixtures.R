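#' Specify a deterministic synthetic cohort
#'
#' The generator emulates the source-side directory tree a conversion run
#' reads: per-tumor directories holding the six experiment-type file
#' layouts, a `meta` directory with clinical and biospecimen XML
#' documents, and the four annotation lookup tables — all internally
#' consistent, so the full pipeline runs with no download. The same spec
#' always produces a byte-identical tree.
#'
#' Defaults are desk-scale: 4 patients, one tumor tag, all six experiment
#' types, a synthetic genome of three chromosomes (chr1, chr2, chrX) of
#' 10 Mb. Value models are plausibility-only (the conversion copies
#' values, never models them): methylation beta ~ Beta(0.5, 0.5), read
#' counts ~ NegBin(mean 500, dispersion 0.5), segment means ~ N(0, 0.5),
#' coordinates uniform over the synthetic chromosomes. Floats are rounded
#' to 6 significant digits, the serializers' own rendering precision.
#'
#' `miss_fraction` removes exactly `round(miss_fraction * n)` of the gene,
#' transcript and miRNA ids from their annotation tables (the ids still
#' appear in the experiment files), to exercise the annotation-miss paths.
#'
#' @param seed Integer RNG seed.
#' @param n_patients Total number of distinct patients across all tags.
#' @param tumor_tags Character vector of tumor abbreviations (e.g. "BRCA",
#'   "OV"); patients are assigned round-robin.
#' @param types Subset of the six experiment types.
#' @param n_genes,n_mirnas,n_transcripts Synthetic feature counts.
#' @param miss_fraction Fraction of feature ids omitted from the
#'   annotation tables.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(seed = 1L, n_patients = 4L, tumor_tags = "BRCA",
                        types = EXPERIMENT_TYPES, n_genes = 50L,
                        n_mirnas = 20L, n_transcripts = 80L,
                        miss_fraction = 0) {
  stopifnot(n_patients >= 1L, length(tumor_tags) >= 1L,
            all(types %in% EXPERIMENT_TYPES),
            miss_fraction >= 0, miss_fraction <= 1)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 tumor_tags = toupper(tumor_tags), types = types,
                 n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
                 n_transcripts = as.integer(n_transcripts),
                 miss_fraction = miss_fraction),
            class = "cohort_spec")
}

# Synthetic genome: three chromosomes of 10 Mb.
FIXTURE_CHROMS <- c(chr1 = 1e7, chr2 = 1e7, chrX = 1e7)

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @return `cohort_value_models()` returns the per-type samplers (named
#'   list of functions of `n`) used by the generator.
#' @export
cohort_value_models <- function(spec) {
  list(
    beta_value = function(n) pmin(1, pmax(0, stats::rbeta(n, 0.5, 0.5))),
    read_count = function(n) stats::rnbinom(n, mu = 500, size = 2),
    segment_mean = function(n) stats::rnorm(n, 0, 0.5),
    position = function(n, len) sample.int(len, n, replace = TRUE)
  )
}

sig6 <- function(x) signif(x, 6)

write_src_table <- function(df, path, comments = character(0)) {
  cols <- lapply(df, as.character)
  header <- paste(names(df), collapse = "\t")
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  writeLines(c(comments, header, body), path, useBytes = TRUE)
}

xml_leaf <- function(parent, name, value) {
  xml2::xml_add_child(parent, name, as.character(value))
}

#' Generate the synthetic source tree
#'
#' Writes `tcga_original/<TAG>/<type>/...` experiment files, per-patient
#' clinical and per-sample biospecimen documents under
#' `tcga_original/<TAG>/meta/`, the four annotation tables under
#' `annotations/`, and a `manifest.tsv` of relative path + MD5 checksum
#' for every emitted file.
#'
#' @param spec A [cohort_spec()].
#' @param root Output directory (created if needed).
#' @return Invisibly, a list with `root`, the `manifest` data.frame and
#'   the per-patient aliquot map.
#' @export
generate_cohort <- function(spec, root) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  models <- cohort_value_models(spec)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)

  chrom_names <- names(FIXTURE_CHROMS)
  strip_chr <- function(x) sub("^chr", "", x)

  # --- features ------------------------------------------------------------
  genes <- data.frame(
    entrez_id = as.character(1000L + seq_len(spec$n_genes)),
    symbol = sprintf("GENE%04d", seq_len(spec$n_genes)),
    chrom = sample(chrom_names, spec$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  genes$start <- models$position(spec$n_genes, 9.9e6)
  genes$end <- genes$start + sample(1000:50000, spec$n_genes, replace = TRUE)
  genes$strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)

  transcripts <- data.frame(
    ucsc_id = sprintf("uc%06d.%d", seq_len(spec$n_transcripts),
                      sample(1:3, spec$n_transcripts, replace = TRUE)),
    gene = sample.int(spec$n_genes, spec$n_transcripts, replace = TRUE),
    stringsAsFactors = FALSE)

  n_mir <- spec$n_mirnas
  mir_ids <- sprintf("hsa-mir-%d", 100L + seq_len(n_mir))
  extra_locus <- seq_len(n_mir) %% 10L == 0L  # every 10th miRNA has 2 loci
  mk_locus <- function(k) {
    chrom <- sample(chrom_names, k, replace = TRUE)
    start <- models$position(k, 9.9e6)
    data.frame(mirna_id = character(k), chrom = chrom, start = start,
               end = start + 71L,
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  mirnas <- mk_locus(n_mir); mirnas$mirna_id <- mir_ids
  extra <- mk_locus(sum(extra_locus)); extra$mirna_id <- mir_ids[extra_locus]
  mirna_loci <- rbind(mirnas, extra)

  # --- annotation tables (minus the configured miss fraction) --------------
  drop_n <- function(n) round(spec$miss_fraction * n)
  gene_missing <- sort(sample.int(spec$n_genes, drop_n(spec$n_genes)))
  tx_missing <- sort(sample.int(spec$n_transcripts, drop_n(spec$n_transcripts)))
  mir_missing <- sort(sample.int(n_mir, drop_n(n_mir)))

  ann_dir <- file.path(root, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  gkeep <- setdiff(seq_len(spec$n_genes), gene_missing)
  write_src_table(
    data.frame(entrez_id = genes$entrez_id[gkeep], chrom = genes$chrom[gkeep],
               start = genes$start[gkeep], end = genes$end[gkeep],
               strand = genes$strand[gkeep], stringsAsFactors = FALSE),
    file.path(ann_dir, "entrez_coords.tsv"))
  write_src_table(
    data.frame(symbol = genes$symbol, entrez_id = genes$entrez_id,
               stringsAsFactors = FALSE),
    file.path(ann_dir, "symbol_to_entrez.tsv"))
  txkeep <- setdiff(seq_len(spec$n_transcripts), tx_missing)
  write_src_table(
    data.frame(ucsc_id = transcripts$ucsc_id[txkeep],
               entrez_id = genes$entrez_id[transcripts$gene[txkeep]],
               stringsAsFactors = FALSE),
    file.path(ann_dir, "ucsc_to_entrez.tsv"))
  mirkeep <- !mirna_loci$mirna_id %in% mir_ids[mir_missing]
  write_src_table(mirna_loci[mirkeep, , drop = FALSE],
                  file.path(ann_dir, "mirna_coords.tsv"))

  # Shared methylation probe set: probe -> gene, position inside the gene.
  n_probes <- 30L
  probe_gene <- sample.int(spec$n_genes, n_probes, replace = TRUE)
  probes <- data.frame(
    id = sprintf("cg%08d", sample.int(1e7, n_probes)),
    gene = probe_gene,
    pos = genes$start[probe_gene] +
      vapply(probe_gene, function(g) {
        sample.int(genes$end[g] - genes$start[g], 1L)
      }, 0L),
    stringsAsFactors = FALSE)

  # --- patients and aliquots ----------------------------------------------
  tags <- spec$tumor_tags
  patient_tag <- tags[(seq_len(spec$n_patients) - 1L) %% length(tags) + 1L]
  tss_of <- stats::setNames(sprintf("%02d", seq_along(tags)), tags)
  analyte_of <- c(cnv = "D", dnamethylation = "D", dnaseq = "D",
                  mirnaseq = "R", rnaseq = "R", rnaseqv2 = "R")
  aliquot_of <- function(p, type) {
    sprintf("TCGA-%s-%04d-01A-01%s-%04d-01",
            tss_of[[patient_tag[p]]], p, analyte_of[[type]],
            match(type, EXPERIMENT_TYPES))
  }

  for (tag in tags) {
    for (d in c(spec$types, "meta")) {
      dir.create(file.path(root, "tcga_original", tag, d),
                 recursive = TRUE, showWarnings = FALSE)
    }
  }

  genders <- c("FEMALE", "MALE")
  races <- c("WHITE", "BLACK OR AFRICAN AMERICAN", "ASIAN")

  for (p in seq_len(spec$n_patients)) {
    tag <- patient_tag[p]
    src <- file.path(root, "tcga_original", tag)
    pid <- sprintf("TCGA-%s-%04d", tss_of[[tag]], p)
    sid <- paste0(pid, "-01A")

    # clinical document (per patient)
    doc <- xml2::xml_new_root("patient")
    xml_leaf(doc, "bcr_patient_barcode", pid)
    xml_leaf(doc, "gender", sample(genders, 1L))
    xml_leaf(doc, "race", sample(races, 1L))
    xml_leaf(doc, "age_at_initial_pathologic_diagnosis", sample(30:85, 1L))
    xml_leaf(doc, "vital_status", sample(c("Alive", "Dead"), 1L))
    xml_leaf(doc, "tumor_tissue_site", tag)
    xml2::write_xml(doc, file.path(src, "meta", paste0(pid, ".clinical.xml")))

    # biospecimen document (per sample, listing every aliquot)
    bdoc <- xml2::xml_new_root("sample")
    xml_leaf(bdoc, "bcr_sample_barcode", sid)
    xml_leaf(bdoc, "sample_type_id", "01")
    xml_leaf(bdoc, "is_ffpe", "NO")
    aliq_el <- xml2::xml_add_child(bdoc, "aliquots")
    for (type in spec$types) {
      a <- xml2::xml_add_child(aliq_el, "aliquot")
      xml_leaf(a, "bcr_aliquot_barcode", aliquot_of(p, type))
      xml_leaf(a, "plate_id", sprintf("%04d", match(type, EXPERIMENT_TYPES)))
      xml_leaf(a, "center_id", "01")
    }
    xml2::write_xml(bdoc, file.path(src, "meta", paste0(sid, ".biospecimen.xml")))

    for (type in spec$types) {
      bc <- aliquot_of(p, type)
      tdir <- file.path(src, type)
      switch(type,
        cnv = {
          segs <- do.call(rbind, lapply(chrom_names, function(ch) {
            k <- sample(2:4, 1L)
            bounds <- sort(models$position(2L * k, FIXTURE_CHROMS[[ch]]))
            data.frame(Sample = bc, Chromosome = strip_chr(ch),
                       Start = bounds[seq(1L, 2L * k, 2L)],
                       End = bounds[seq(2L, 2L * k, 2L)],
                       Num_Probes = stats::rnbinom(k, mu = 50, size = 5) + 2L,
                       Segment_Mean = sig6(models$segment_mean(k)),
                       stringsAsFactors = FALSE)
          }))
          write_src_table(segs, file.path(tdir, paste0(bc, ".cnv.txt")))
        },
        dnamethylation = {
          beta <- sig6(models$beta_value(n_probes))
          beta[sample.int(n_probes, 2L)] <- "NA"  # platform NA rows
          tab <- data.frame(
            `Composite Element REF` = probes$id,
            Beta_value = beta,
            Gene_Symbol = genes$symbol[probes$gene],
            Chromosome = strip_chr(genes$chrom[probes$gene]),
            Genomic_Coordinate = probes$pos,
            check.names = FALSE, stringsAsFactors = FALSE)
          write_src_table(tab, file.path(tdir, paste0(bc, ".dnamethylation.txt")))
        },
        dnaseq = {
          k <- 15L
          g <- sample.int(spec$n_genes, k, replace = TRUE)
          pos <- genes$start[g] +
            vapply(g, function(i) sample.int(genes$end[i] - genes$start[i], 1L), 0L)
          alleles <- c("A", "C", "G", "T")
          ref <- sample(alleles, k, replace = TRUE)
          alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
          tab <- data.frame(
            Hugo_Symbol = genes$symbol[g],
            Entrez_Gene_Id = genes$entrez_id[g],
            Chromosome = strip_chr(genes$chrom[g]),
            Start_position = pos, End_position = pos,
            Strand = genes$strand[g],
            Variant_Classification = sample(c("Missense_Mutation", "Silent",
                                              "Nonsense_Mutation"), k, TRUE),
            Variant_Type = "SNP",
            Reference_Allele = ref, Tumor_Seq_Allele1 = ref,
            Tumor_Seq_Allele2 = alt,
            dbSNP_RS = ifelse(stats::runif(k) < 0.3,
                              sprintf("rs%07d", sample.int(1e7, k)), "novel"),
            Tumor_Sample_Barcode = bc,
            Matched_Norm_Sample_Barcode = sub("-01A-", "-10A-", bc),
            Mutation_Status = "Somatic",
            Sequencer = "Illumina HiSeq",
            Validation_Status = sample(c("Valid", "Untested"), k, TRUE),
            stringsAsFactors = FALSE)
          write_src_table(tab, file.path(tdir, paste0(bc, ".maf.txt")),
                          comments = "#version 2.4")
        },
        mirnaseq = {
          counts <- models$read_count(n_mir)
          tab <- data.frame(
            miRNA_ID = mir_ids,
            read_count = counts,
            `reads_per_million_miRNA_mapped` =
              sig6(counts / max(1, sum(counts)) * 1e6),
            `cross-mapped` = ifelse(extra_locus, "Y", "N"),
            check.names = FALSE, stringsAsFactors = FALSE)
          write_src_table(tab, file.path(tdir, paste0(bc, ".mirnaseq.txt")))
        },
        rnaseq = {
          counts <- models$read_count(spec$n_genes)
          sym <- genes$symbol
          sym[1L] <- "?"  # unknown-symbol convention in the source files
          write_src_table(data.frame(
            gene = paste(sym, genes$entrez_id, sep = "|"),
            raw_counts = counts,
            median_length_normalized = sig6(stats::runif(spec$n_genes)),
            RPKM = sig6(counts / 40),
            stringsAsFactors = FALSE),
            file.path(tdir, paste0(bc, ".gene.txt")))
          write_exon_file(genes, models, file.path(tdir, paste0(bc, ".exon.txt")))
          write_spljxn_file(genes, models, file.path(tdir, paste0(bc, ".spljxn.txt")))
        },
        rnaseqv2 = {
          counts <- models$read_count(spec$n_genes)
          sym <- genes$symbol
          sym[1L] <- "?"
          write_src_table(data.frame(
            gene_id = paste(sym, genes$entrez_id, sep = "|"),
            raw_count = counts,
            scaled_estimate = sig6(counts / sum(pmax(counts, 1)) * 1e-2),
            normalized_count = sig6(counts * stats::runif(spec$n_genes, 0.5, 2)),
            stringsAsFactors = FALSE),
            file.path(tdir, paste0(bc, ".gene.txt")))
          write_exon_file(genes, models, file.path(tdir, paste0(bc, ".exon.txt")))
          write_spljxn_file(genes, models, file.path(tdir, paste0(bc, ".spljxn.txt")))
          counts_t <- models$read_count(spec$n_transcripts)
          write_src_table(data.frame(
            isoform_id = transcripts$ucsc_id,
            raw_count = counts_t,
            scaled_estimate = sig6(counts_t / sum(pmax(counts_t, 1)) * 1e-2),
            normalized_count = sig6(counts_t * stats::runif(spec$n_transcripts, 0.5, 2)),
            stringsAsFactors = FALSE),
            file.path(tdir, paste0(bc, ".isoform.txt")))
        }
      )
    }
  }

  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  files <- sort(setdiff(files, "manifest.tsv"), method = "radix")
  manifest <- data.frame(
    path = files,
    md5 = unname(tools::md5sum(file.path(root, files))),
    stringsAsFactors = FALSE)
  writeLines(paste(manifest$path, manifest$md5, sep = "\t"),
             file.path(root, "manifest.tsv"), useBytes = TRUE)
  invisible(list(root = root, manifest = manifest,
                 aliquots = expand_aliquots(spec, patient_tag, aliquot_of)))
}

expand_aliquots <- function(spec, patient_tag, aliquot_of) {
  do.call(rbind, lapply(seq_len(spec$n_patients), function(p) {
    data.frame(patient = p, tumor_tag = patient_tag[p], type = spec$types,
               barcode = vapply(spec$types, function(t) aliquot_of(p, t), ""),
               stringsAsFactors = FALSE)
  }))
}

# Two exons per gene; minus-strand exon keys are printed end-first, the
# convention the converter has to normalize.
write_exon_file <- function(genes, models, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    width <- g$end - g$start
    b <- sort(g$start + sample.int(width, 4L))
    key <- function(s, e) {
      if (g$strand == "-") sprintf("%s:%d-%d:%s", g$chrom, e, s, g$strand)
      else sprintf("%s:%d-%d:%s", g$chrom, s, e, g$strand)
    }
    counts <- models$read_count(2L)
    data.frame(exon = c(key(b[1L], b[2L]), key(b[3L], b[4L])),
               raw_counts = counts,
               median_length_normalized = sig6(stats::runif(2L)),
               RPKM = sig6(counts / 40),
               stringsAsFactors = FALSE)
  }))
  write_src_table(rows, path)
}

# One junction per gene: donor/acceptor anchors inside the gene, printed
# donor-first (so minus-strand junctions have donor pos > acceptor pos).
write_spljxn_file <- function(genes, models, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    b <- sort(g$start + sample.int(g$end - g$start, 2L))
    anchors <- if (g$strand == "-") c(b[2L], b[1L]) else c(b[1L], b[2L])
    data.frame(
      junction = sprintf("%s:%d:%s,%s:%d:%s", g$chrom, anchors[1L], g$strand,
                         g$chrom, anchors[2L], g$strand),
      raw_counts = models$read_count(1L),
      stringsAsFactors = FALSE)
  }))
  write_src_table(rows, path)
}
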