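---
title: "Methods: free-BED conversion of TCGA-style cancer genomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-BED conversion of TCGA-style cancer genomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freebed)
```

## The conversion model

The unit of analysis is the **aliquot**: a physical portion of a tumor or
control sample, identified by a structured barcode
(`TCGA-<tss>-<participant>-<sample><vial>-<portion><analyte>-<plate>-<center>`)
whose dash-separated prefixes identify the patient (3 groups) and the sample
(4 groups). One genomic experiment corresponds to one aliquot, so the output
repository is aliquot-oriented: for every experiment one `.bed` data file and
one `.bed.meta` metadata file, named after the full barcode.

Every record, regardless of experiment type, is a genomic region plus a typed
attribute tail. The four mandatory fields — `chrom`, `chromStart`,
`chromEnd`, `strand` — use one-based closed coordinates (the 3rd through 7th
bases are `[3, 7]`), the convention of the source data. Internally a record
set is a `GenomicRanges::GRanges`, which is natively one-based closed with
strand levels `+/-/*`; the serializers write it out verbatim rather than
shifting to UCSC's 0-based half-open convention. This is a deliberate,
documented deviation from standard BED, which is why the format is called
"free" BED: unlimited schema-defined columns, one-based closed coordinates,
structure declared in a side file rather than in the data file.

Assumptions worth stating explicitly:

* **Values are copied, never recomputed.** Expression counts, beta values and
  segment means pass through unchanged (up to the numeric rendering below);
  no normalization or re-quantification happens.
* **One genome build per run.** The annotation store is assembly-agnostic;
  the provenance of its tables must declare the build, and mixing builds
  between source data and tables is the caller's error, undetectable here.
* **Region first.** A row that cannot be placed on the genome is not a
  region record. Hence the asymmetric miss policy: rows whose *region* is
  unrecoverable (gene/isoform/miRNA id absent from the tables) are dropped
  and counted; rows missing only *strand* (methylation probes whose gene
  symbol does not resolve) keep their position and get the `*` placeholder.

## Per-type converters

Each (experiment type, subtype) pair has a registered schema and converter;
dispatch is a table keyed by `type[.subtype]`, so adding a data type is one
schema plus one registration.

| type.subtype | region source | attribute tail |
|---|---|---|
| `cnv` | segment columns | `num_probes`, `segment_mean` |
| `dnamethylation` | probe position (single base) | probe id, beta, symbol |
| `dnaseq` | MAF coordinates | 13 MAF columns |
| `mirnaseq` | miRBase lookup (1..k loci) | id, counts, cross-mapped |
| `rnaseq[v2].gene` | Entrez lookup via `symbol\|id` key | ids + quantifications |
| `rnaseq[v2].exon` | composite key `chr:a-b:strand` | original key + quantifications |
| `rnaseq[v2].spljxn` | span of the two anchors | key, donor/acceptor, counts |
| `rnaseqv2.isoform` | UCSC → Entrez chain | isoform id, Entrez id, quantifications |

Details that were genuinely open and are fixed here:

* **Splice junctions** get ad-hoc attributes easing downstream use:
  `donor_chrom`, `donor_pos`, `acceptor_chrom`, `acceptor_pos`, preserving
  the original orientation even though the region itself is normalized to
  `start <= end`. A junction whose anchors sit on different chromosomes
  cannot form one region and is dropped (counted, reported). The exact
  ad-hoc column set of historical converters is not documented anywhere
  usable; this decomposition is this package's own reconstruction.
* **Exon keys** printed end-first on the minus strand are normalized, and
  the verbatim original key is kept as the leading `exon` attribute in
  *every* record — a fixed schema cannot make a column conditional on
  whether normalization fired.
* **Methylation records are single-base regions** (`start == end`), legal
  under the closed-interval convention.
* Every record of a given (type, subtype) serializes to exactly
  `4 + N` fields; the intersection of all schemas' columns is exactly the
  four mandatory fields.

## Annotation chains

Four lookup chains replace live queries against NCBI Entrez Gene, HGNC, UCSC
and miRBase with local tab-delimited tables (plus a single-file cache that
reloads bit-exactly):

1. Entrez Gene id → (chrom, start, end, strand);
2. gene symbol → Entrez id → strand (symbols case-preserving);
3. UCSC transcript id → Entrez id → coordinates, with a version fallback:
   `uc001aaa.3` retries as `uc001aaa` when the exact id is absent, because
   source files and transcript tables routinely disagree on versions;
4. miRNA id → one or more loci (case-insensitive ids, since miRBase ids are
   lowercase `hsa-...`); a k-locus miRNA emits k records per source row.

A failed lookup is a value, not an error: an `annotation_miss` recording the
id kind and which link of the chain failed, carried in the conversion report
and never silently discarded. Lookups never mutate the store. Duplicate keys
in a table keep the last occurrence with a warning — the pragmatic choice for
periodically re-exported tables, where later rows are newer. One region per
Entrez id is stored; multi-placement handling is reserved to miRNAs, where
the data visibly require it.

## Metadata flattening

Clinical documents are per patient, biospecimen documents per sample; the
aliquot-oriented layout denormalizes both into one flat `.meta` record per
aliquot. Flattening maps each non-empty XML leaf to a pair whose key is the
lowercased path from (but excluding) the root, joined with `__`; repeated
sibling leaves get a 1-based `__k` suffix. Clinical keys are prefixed
`clinical__`, biospecimen keys `biospecimen__` (the two sources share field
names, so unprefixed keys would collide), and three provenance keys are
always present (`manually_curated__tumor_tag`, `__exp_data_type`,
`__tcga_aliquot_barcode`). Barcode linkage is checked: a clinical document
for patient A cannot attach to an aliquot of patient B. The `.meta` line
format is `key<TAB>value`, keys sorted; the per-directory
`metadata_dictionary.txt` lists each attribute with its exact set of
observed distinct values, sorted. The key-naming scheme (prefixes, `__`
separator) is this package's own convention; no authoritative scheme
survives for the historical repositories.

## Repository layout

Outputs land under `bed/<tumor-tag-lowercase>/<type>/` with type directories
`cnv`, `dnamethylation`, `dnaseq`, `mirnaseq`, `rnaseq`, `rnaseqv2`. The
RNA-seq families have per-subtype schemas, and the schema descriptor is a
per-directory file — so those types fan out one further level
(`rnaseq/gene/`, `rnaseq/exon/`, ...), each leaf directory holding its
`.bed`/`.bed.meta` pairs plus exactly one `header.schema` and one
`metadata_dictionary.txt`. `header.schema` is XML, one `<field>` per column
with name and value kind, validated against an XSD shipped in
`inst/extdata/` (the historical element vocabulary being unavailable, the
package ships and validates its own). Conversion runs are driven by a job
list or an XML config (`<job>` per item); all jobs are validated before any
output is written, and re-running an unchanged job rewrites byte-identical
files.

## Numerical and formatting choices

* Floats render with up to 6 significant digits, plain notation at
  magnitudes ≥ 1e-4 and exponent notation below; integers bare; decimal
  point locale-independent. Fixed rendering is what makes determinism and
  cross-format equality byte-exact.
* The missing-value token is `null` in BED/CSV/GTF/XML and JSON `null` in
  JSON; `NA`, empty and `.` fields in source files are read as missing.
* Strand placeholder is `*` (the `GRanges` convention), chosen over `.` to
  avoid colliding with GTF's empty-field dot; GTF output maps `*` to `.`.
* Chromosomes normalize to `chr`-prefixed names, mitochondrion `chrM`;
  `17`, `chr17` and `MT` are all accepted, since source platforms mix
  conventions. Unrecognizable names are a per-row drop (CNV) or input error
  (MAF) depending on whether the type tolerates malformed rows.
* Output ordering is total and deterministic: karyotype chromosome order
  (`chr1` … `chr22`, `chrX`, `chrY`, `chrM` — not lexicographic), then
  start, end, strand, then every attribute as text. Shuffled input
  serializes identically. Lexicographic sorts of keys/values use C-locale
  radix order.
* The GTF `source` column carries the package name; feature tokens are
  per-type (`cnv_segment`, `methylation_site`, `mutation`, `mirna`, `gene`,
  `exon`, `splice_junction`, `isoform`).

## The synthetic cohort generator

`generate_cohort()` emulates the *source* side: a `tcga_original/<TAG>/`
tree with per-type experiment files, a `meta/` directory of clinical and
biospecimen XML, the four annotation tables, and an MD5 manifest. The same
spec always yields a byte-identical tree. Defaults are desk-scale and fixed
once: 4 patients, one tumor tag, all six types, 50 genes, 20 miRNAs (every
10th with two loci), 80 transcripts, a 3 × 10 Mb synthetic genome
(`chr1`, `chr2`, `chrX`), `miss_fraction = 0`. Value models are
plausibility-only, chosen to look like the real marginals a converter must
format correctly: beta values ~ Beta(0.5, 0.5) (the characteristic bimodal
methylation shape), read counts ~ negative binomial with mean 500 and
dispersion 0.5, segment means ~ Normal(0, 0.5), coordinates uniform with
`start <= end` enforced. Floats are rounded to 6 significant digits at
generation time — the serializers' own precision — so that pipeline round
trips are exact.

What the generator does **not** emulate: linkage disequilibrium, co-methylation
structure, mutation signatures, batch effects, missing-file patterns, or the
scale of real archives. Passing tests therefore demonstrate structural and
accounting correctness of the conversion — formats, coordinates, chains,
pairing, determinism — not statistical fidelity of any downstream analysis
on real tumor data. `miss_fraction` removes an exact count
(`round(f * n)`) of gene/transcript/miRNA ids from the annotation tables
while keeping them in the experiment files, exercising the miss paths with
predictable accounting.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
cohorts of 1–4 patients (tens of files, a few thousand rows), 1000-case
property loops for barcodes, coordinate bijection, chain-vs-oracle
equivalence and cache round trips, and 50-record dictionary oracles. These
sizes are the package's chosen regression scale: large enough to exercise
every code path (multi-locus miRNAs, version fallback, `?` symbols, NA
betas, minus-strand key normalization), small enough to run comfortably on
a laptop.

## Known limitations

* Only the six experiment types listed are supported; protected/controlled
  data types, level-1 raw data and UUID-based identifiers are out of scope.
* The shipped source adapter reads a local directory tree; there is no
  live-download path (the portals the historical layouts came from have
  been retired or superseded).
* No genome-build liftover and no symbol-synonym resolution beyond the
  shipped symbol table.
* Barcode support is aliquot-granularity only (no slide/analyte-only
  variants).
* The free-BED output is one-based closed; feeding it to tools that assume
  UCSC BED semantics without adjustment will shift regions by one base.
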