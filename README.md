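# freebed

Cancer-genomics results in TCGA-style distributions arrive as six loosely
related tab-delimited layouts — copy-number segment tables, DNA-methylation
probe files, somatic-mutation MAF tables, and miRNA-seq / RNA-seq V1 / RNA-seq
V2 quantifications — several of which carry only a feature identifier and no
genomic coordinates. That heterogeneity blocks the region-based integration
(overlap, join, cover) that genomic query tools expect. `freebed` is an ETL
toolkit for analysts who want all of these data as uniform, region-addressed
files: it converts each experiment type into a **"free" BED** format and lays
the results out as an aliquot-oriented repository, one data file plus one
metadata file per genomic experiment.

## The free-BED format

A free-BED file is a headerless, tab-delimited, one-line-per-feature table
whose first four columns are fixed across every experiment type:

| column | meaning |
|---|---|
| `chrom` | chromosome (`chr1` … `chr22`, `chrX`, `chrY`, `chrM`) |
| `chromStart` | start position, **one-based**, inclusive |
| `chromEnd` | end position, inclusive (closed interval) |
| `strand` | `+`, `-`, or `*` when unknown / not applicable |

followed by an unlimited, schema-defined attribute tail (columns 5 … 4+N)
specific to the (experiment type, subtype) pair. Coordinates use the
one-based base-counted convention of the source data — the 3rd through 7th
bases of a sequence are the closed interval `[3, 7]` — and are deliberately
*not* shifted to the 0-based half-open convention of UCSC BED. The column
structure of every output directory is declared in an XML `header.schema`
side file; per-aliquot clinical + biospecimen metadata are flattened to
sorted `key<TAB>value` `.meta` files, and each directory also gets a
`metadata_dictionary.txt` listing every attribute with all distinct values it
assumes. Records can additionally be written as CSV, GTF, JSON and XML.

Where the source files lack coordinates or strand, four local ID-mapping
chains recover them: Entrez Gene id → coordinates; gene symbol → Entrez id →
strand (HGNC); UCSC transcript id → Entrez id → coordinates; miRNA id →
miRBase loci (possibly several per miRNA, each yielding its own record).
A row whose missing datum is the region itself is dropped and counted; a row
missing only strand is kept with `*`.

## Worked example

No download is needed: the package ships a deterministic synthetic-cohort
generator that emulates the source directory tree, including internally
consistent annotation tables and clinical/biospecimen documents.

```r
library(freebed)

spec <- cohort_spec(seed = 42, n_patients = 2)
root <- tempfile("demo")
generate_cohort(spec, root)

job <- list(source = file.path(root, "tcga_original", "BRCA"), tumor = "BRCA",
            type = "rnaseqv2", formats = c("bed", "gtf"),
            annotations = file.path(root, "annotations"),
            out = file.path(root, "out"))
report <- run_convert(list(job), quiet = TRUE)
print(report)
#> <freebed_run_report> 1 job(s), ok
#>   files: 8  rows in: 560  records out: 560  dropped: 0  misses: 0
```

560 source rows (gene, exon, splice-junction and isoform quantifications for
two aliquots) became 560 records with nothing dropped: every feature id
resolved through the annotation chains. The gene-quantification output for
the first aliquot starts:

```
chr1	74743	76893	-	1002	GENE0002	380	0.000135361	268.765
chr1	2035611	2039303	-	1043	GENE0043	186	6.62558e-05	229.488
chr1	2181546	2208712	-	1037	GENE0037	868	0.000309194	1102.46
```

i.e. `chrom`, `chromStart`, `chromEnd`, `strand` — the coordinates and strand
recovered from the Entrez Gene table, since the source row carried only
`GENE0002|1002` — followed by the schema's attribute tail (`entrez_gene_id`,
`gene_symbol`, `raw_count`, `scaled_estimate`, `normalized_count`). Its
`.bed.meta` companion begins:

```
biospecimen__bcr_aliquot_barcode	TCGA-01-0001-01A-01R-0006-01
biospecimen__bcr_sample_barcode	TCGA-01-0001-01A
biospecimen__center_id	01
biospecimen__is_ffpe	NO
```

A thin command-line front end is installed at
`system.file("cli", "freebed.R", package = "freebed")`
(`convert --config <xml> | --source ... --type ...`, and `fixtures`).

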