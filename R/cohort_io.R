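## Domain containers and file IO for every format the pipeline touches.
## All tabular files are tab-delimited UTF-8 with a mandatory header
## (clinical and group tables are CSV); missing numeric fields fail fast
## because every downstream statistic assumes complete vectors.

HPV_GENES <- c("E1", "E2", "E4", "E5", "E6", "E7", "L1", "L2")

APC_CELL_TYPES <- c("B cells", "Macrophage M1", "Macrophage M2",
                    "Myeloid dendritic cell")

# ---------------------------------------------------------------------------
# Constructors / validators
# ---------------------------------------------------------------------------

#' Construct a ligandome
#'
#' A ligandome is a collection of HLA-eluted peptide records, either at the
#' per-sample level (each record tied to a sample) or at the cohort-union
#' level (distinct peptides over all samples of a cohort).
#'
#' @param records data.frame with columns `sample_id`, `hla_class` ("I" or
#'   "II"), `peptide`, and optionally `allele` (may be empty strings).
#' @param level `"sample"` or `"cohort-union"`.
#' @return object of class `"ligandome"` (a validated data.frame with a
#'   `level` attribute).
#' @export
ligandome <- function(records, level = c("sample", "cohort-union")) {
  level <- match.arg(level)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"allele" %in% names(records)) records$allele <- ""
  check_columns(records, c("sample_id", "hla_class", "peptide"), "<records>")
  records$peptide <- normalize_peptides(records$peptide)
  if (nrow(records)) validate_sequences(records$peptide)
  records$hla_class <- as_hla_class(records$hla_class)
  key <- if (level == "sample") {
    paste(records$sample_id, records$hla_class, records$peptide)
  } else {
    paste(records$hla_class, records$peptide)
  }
  if (anyDuplicated(key))
    stop(sprintf("duplicate ligandome record at %s level: %s",
                 level, key[which(duplicated(key))[1]]), call. = FALSE)
  records <- records[, c("sample_id", "hla_class", "peptide", "allele")]
  rownames(records) <- NULL
  structure(records, level = level, class = c("ligandome", "data.frame"))
}

#' Collapse a sample-level ligandome to cohort-union level
#'
#' @param lig a [ligandome()].
#' @return cohort-union ligandome with one record per distinct
#'   (hla_class, peptide) pair; `sample_id` is set to `"cohort"`.
#' @export
as_cohort_union <- function(lig) {
  stopifnot(inherits(lig, "ligandome"))
  if (attr(lig, "level") == "cohort-union") return(lig)
  u <- unique(as.data.frame(lig)[, c("hla_class", "peptide")])
  ligandome(data.frame(sample_id = "cohort", hla_class = u$hla_class,
                       peptide = u$peptide, allele = "",
                       stringsAsFactors = FALSE),
            level = "cohort-union")
}

#' Construct a benign-tissue ligand atlas
#'
#' @param entries data.frame with columns `tissue`, `hla_class`, `peptide`.
#' @return object of class `"benign_atlas"`.
#' @export
benign_atlas <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  check_columns(entries, c("tissue", "hla_class", "peptide"), "<entries>")
  if (nrow(entries) == 0 || length(unique(entries$tissue)) < 1)
    stop("benign atlas must contain at least one tissue", call. = FALSE)
  entries$peptide <- normalize_peptides(entries$peptide)
  validate_sequences(entries$peptide)
  entries$hla_class <- as_hla_class(entries$hla_class)
  entries <- unique(entries[, c("tissue", "hla_class", "peptide")])
  rownames(entries) <- NULL
  structure(entries, class = c("benign_atlas", "data.frame"))
}

#' Construct an expression matrix container
#'
#' Holds raw gene-level counts, gene lengths, the tumor/healthy-mucosa group
#' assignment, and (once computed) TPM.
#'
#' @param counts gene x sample matrix of non-negative integers.
#' @param gene_lengths named positive numeric vector (nucleotides), names
#'   matching the count rows.
#' @param group named character vector mapping sample to `"tumor"` or
#'   `"healthy_mucosa"`.
#' @param tpm optional precomputed TPM matrix.
#' @return object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(counts, gene_lengths, group, tpm = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!setequal(rownames(counts), names(gene_lengths)))
    stop("count rows and gene_lengths names must cover the same genes",
         call. = FALSE)
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  group <- group[colnames(counts)]
  if (anyNA(group) || !all(group %in% c("tumor", "healthy_mucosa")))
    stop("every sample needs a group of 'tumor' or 'healthy_mucosa'",
         call. = FALSE)
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 group = group, tpm = tpm),
            class = "expression_matrix")
}

#' Construct an antibody intensity matrix
#'
#' @param intensities antigen x patient matrix of positive intensities.
#' @param positive_controls character vector of control antigen row ids.
#' @param normalized optional normalized matrix (see [normalize_antibody()]).
#' @return object of class `"antibody_matrix"`.
#' @export
antibody_matrix <- function(intensities, positive_controls, normalized = NULL) {
  intensities <- as.matrix(intensities)
  missing_ctl <- setdiff(positive_controls, rownames(intensities))
  if (length(missing_ctl))
    stop(sprintf("positive control(s) not among antigen rows: %s",
                 paste(missing_ctl, collapse = ", ")), call. = FALSE)
  structure(list(intensities = intensities,
                 positive_controls = positive_controls,
                 normalized = normalized),
            class = "antibody_matrix")
}

#' Construct a binding-affinity prediction table
#'
#' @param rows data.frame with columns `peptide`, `allele`, `affinity_nM`,
#'   and optionally `percent_rank`.
#' @return object of class `"binding_table"`.
#' @export
binding_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  check_columns(rows, c("peptide", "allele", "affinity_nM"), "<rows>")
  if (!"percent_rank" %in% names(rows)) rows$percent_rank <- NA_real_
  rows$peptide <- normalize_peptides(rows$peptide)
  validate_sequences(rows$peptide)
  rows$affinity_nM <- as.numeric(rows$affinity_nM)
  if (anyNA(rows$affinity_nM) || any(rows$affinity_nM <= 0))
    stop("affinity_nM must be positive numbers", call. = FALSE)
  key <- paste(rows$peptide, rows$allele)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (peptide, allele) pair: %s",
                 key[which(duplicated(key))[1]]), call. = FALSE)
  rows <- rows[, c("peptide", "allele", "affinity_nM", "percent_rank")]
  rownames(rows) <- NULL
  structure(rows, class = c("binding_table", "data.frame"))
}

#' Construct a protein-level somatic variant table
#'
#' @param rows data.frame with columns `patient_id`, `gene`, `protein_pos`
#'   (1-based), `ref_aa`, `alt_aa`.
#' @return object of class `"variant_table"`.
#' @export
variant_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  check_columns(rows, c("patient_id", "gene", "protein_pos", "ref_aa", "alt_aa"),
                "<rows>")
  rows$protein_pos <- as.integer(rows$protein_pos)
  rows$ref_aa <- toupper(rows$ref_aa)
  rows$alt_aa <- toupper(rows$alt_aa)
  ok_aa <- rows$ref_aa %in% AA_ALPHABET & rows$alt_aa %in% AA_ALPHABET
  if (!all(ok_aa))
    stop("ref_aa/alt_aa must be single letters of the amino-acid alphabet",
         call. = FALSE)
  if (any(rows$ref_aa == rows$alt_aa))
    stop("ref_aa must differ from alt_aa", call. = FALSE)
  if (anyNA(rows$protein_pos) || any(rows$protein_pos < 1))
    stop("protein_pos must be a 1-based positive integer", call. = FALSE)
  rows <- rows[, c("patient_id", "gene", "protein_pos", "ref_aa", "alt_aa")]
  rownames(rows) <- NULL
  structure(rows, class = c("variant_table", "data.frame"))
}

#' Construct a clinical table
#'
#' `stage_group` is derived: `"low"` for UICC I-II, `"high"` for III-IV.
#'
#' @param rows data.frame with columns `patient_id`, `hpv_status`
#'   ("positive"/"negative"), `uicc_stage` ("I".."IV"), `recurrence`,
#'   `dfs_time` (months), `dfs_event`, `has_serum` (logical or 0/1).
#' @return object of class `"clinical_table"`.
#' @export
clinical_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  check_columns(rows, c("patient_id", "hpv_status", "uicc_stage", "recurrence",
                        "dfs_time", "dfs_event", "has_serum"), "<rows>")
  if (anyDuplicated(rows$patient_id))
    stop("duplicate patient_id in clinical table", call. = FALSE)
  if (!all(rows$hpv_status %in% c("positive", "negative")))
    stop("hpv_status must be 'positive' or 'negative'", call. = FALSE)
  if (!all(rows$uicc_stage %in% c("I", "II", "III", "IV")))
    stop("uicc_stage must be one of I, II, III, IV", call. = FALSE)
  for (cn in c("recurrence", "dfs_event", "has_serum")) {
    v <- rows[[cn]]
    if (is.character(v)) v <- trimws(v)
    lv <- if (is.logical(v)) v
          else if (is.numeric(v)) v != 0
          else toupper(v) %in% c("TRUE", "T", "1", "YES")
    if (is.character(v) &&
        !all(toupper(v) %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO")))
      stop(sprintf("column %s must be boolean-coded", cn), call. = FALSE)
    rows[[cn]] <- lv
  }
  rows$dfs_time <- as.numeric(rows$dfs_time)
  if (anyNA(rows$dfs_time) || any(rows$dfs_time < 0))
    stop("dfs_time must be non-negative", call. = FALSE)
  rows$stage_group <- ifelse(rows$uicc_stage %in% c("I", "II"), "low", "high")
  rows <- rows[, c("patient_id", "hpv_status", "uicc_stage", "stage_group",
                   "recurrence", "dfs_time", "dfs_event", "has_serum")]
  rownames(rows) <- NULL
  structure(rows, class = c("clinical_table", "data.frame"))
}

#' Construct an HPV oncogene read-count table
#'
#' @param rows data.frame with columns `patient_id` and the eight HPV genes
#'   `E1 E2 E4 E5 E6 E7 L1 L2` (absent genes recorded as 0).
#' @return object of class `"hpv_read_counts"`.
#' @export
hpv_read_counts <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  check_columns(rows, c("patient_id", HPV_GENES), "<rows>")
  for (g in HPV_GENES) {
    rows[[g]] <- as.integer(rows[[g]])
    if (anyNA(rows[[g]]) || any(rows[[g]] < 0))
      stop(sprintf("HPV read counts for %s must be non-negative integers", g),
           call. = FALSE)
  }
  rows <- rows[, c("patient_id", HPV_GENES)]
  rownames(rows) <- NULL
  structure(rows, class = c("hpv_read_counts", "data.frame"))
}

#' Construct an antigen-presenting-cell fraction matrix
#'
#' @param fractions cell_type x patient matrix of fractions in \[0, 1\];
#'   rows must include B cells, M1/M2 macrophages and myeloid dendritic cells.
#' @return object of class `"apc_fractions"`.
#' @export
apc_fractions <- function(fractions) {
  fractions <- as.matrix(fractions)
  missing_ct <- setdiff(APC_CELL_TYPES, rownames(fractions))
  if (length(missing_ct))
    stop(sprintf("APC matrix missing cell type(s): %s",
                 paste(missing_ct, collapse = ", ")), call. = FALSE)
  if (any(fractions < 0) || any(fractions > 1))
    stop("APC fractions must lie in [0, 1]", call. = FALSE)
  structure(fractions, class = c("apc_fractions", "matrix", "array"))
}

# ---------------------------------------------------------------------------
# Readers
# ---------------------------------------------------------------------------

#' Read any pipeline input file into its typed container
#'
#' Dispatcher over the per-format readers. Column schemas are strict; a
#' missing column raises an error naming it, an invalid amino-acid character
#' raises a record-level error with its line number, and duplicate keys fail
#' validation.
#'
#' @param kind one of `"ligandome"`, `"benign_atlas"`, `"expression"`,
#'   `"antibody"`, `"binding"`, `"variants"`, `"clinical"`, `"hpv_counts"`,
#'   `"apc_fractions"`, `"panel_fasta"`.
#' @param path path to the main file.
#' @param ... extra paths for multi-file kinds: `expression` needs
#'   `lengths` (TSV `gene  length_nt`) and `groups` (CSV `sample,group`);
#'   `antibody` needs `controls` (one control antigen id per line);
#'   `ligandome` accepts `level`.
#' @return validated object of the kind's container type.
#' @export
read_inputs <- function(kind, path, ...) {
  switch(match.arg(kind, c("ligandome", "benign_atlas", "expression",
                           "antibody", "binding", "variants", "clinical",
                           "hpv_counts", "apc_fractions", "panel_fasta")),
    ligandome     = read_ligandome(path, ...),
    benign_atlas  = read_benign_atlas(path),
    expression    = read_expression(path, ...),
    antibody      = read_antibody(path, ...),
    binding       = read_binding(path),
    variants      = read_variants(path),
    clinical      = read_clinical(path),
    hpv_counts    = read_hpv_counts(path),
    apc_fractions = read_apc_fractions(path),
    panel_fasta   = read_panel_fasta(path))
}

#' @rdname read_inputs
#' @param level ligandome level, `"sample"` or `"cohort-union"`.
#' @export
read_ligandome <- function(path, level = "sample") {
  df <- read_tsv_checked(path, c("sample_id", "hla_class", "peptide"))
  seqs <- normalize_peptides(df$peptide)
  validate_sequences(seqs, line_offset = 1L)  # header is line 1
  df$peptide <- seqs
  ligandome(df, level = level)
}

#' @rdname read_inputs
#' @export
read_benign_atlas <- function(path) {
  df <- read_tsv_checked(path, c("tissue", "hla_class", "peptide"))
  df$peptide <- normalize_peptides(df$peptide)
  validate_sequences(df$peptide, line_offset = 1L)
  benign_atlas(df)
}

#' @rdname read_inputs
#' @param lengths path to the gene-length TSV (`gene  length_nt`).
#' @param groups path to the sample-group CSV (`sample,group`).
#' @export
read_expression <- function(path, lengths, groups) {
  cdf <- read_tsv_checked(path, "gene")
  counts <- as.matrix(cdf[, setdiff(names(cdf), "gene"), drop = FALSE])
  rownames(counts) <- cdf$gene
  ldf <- read_tsv_checked(lengths, c("gene", "length_nt"))
  len <- stats::setNames(as.numeric(ldf$length_nt), ldf$gene)
  gdf <- read_csv_checked(groups, c("sample", "group"))
  grp <- stats::setNames(gdf$group, gdf$sample)
  expression_matrix(counts, len, grp)
}

#' @rdname read_inputs
#' @param controls path to the positive-control list (one antigen per line).
#' @export
read_antibody <- function(path, controls) {
  adf <- read_tsv_checked(path, "antigen")
  m <- as.matrix(adf[, setdiff(names(adf), "antigen"), drop = FALSE])
  rownames(m) <- adf$antigen
  ctl <- readLines(controls)
  ctl <- ctl[nzchar(trimws(ctl))]
  antibody_matrix(m, trimws(ctl))
}

#' @rdname read_inputs
#' @export
read_binding <- function(path) {
  df <- read_tsv_checked(path, c("peptide", "allele", "affinity_nM"))
  binding_table(df)
}

#' @rdname read_inputs
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) return(read_variants_vcf(path))
  df <- read_tsv_checked(path, c("patient_id", "gene", "protein_pos",
                                 "ref_aa", "alt_aa"))
  variant_table(df)
}

## Minimal VCF 4.2 subset: protein-level consequence carried in an
## ANN=gene|pPOS|REF|ALT INFO token; patient taken from the single sample
## column. Genomic-to-protein mapping is upstream of this pipeline.
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (!length(header)) stop("VCF lacks a #CHROM header line", call. = FALSE)
  cols <- strsplit(sub("^#", "", header[1]), "\t")[[1]]
  if (length(cols) < 10)
    stop("minimal VCF requires a single sample column", call. = FALSE)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  rows <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    info <- f[8]
    ann <- regmatches(info, regexpr("ANN=[^;]+", info))
    if (!length(ann))
      stop(sprintf("VCF record without ANN token: %s", ln), call. = FALSE)
    parts <- strsplit(sub("^ANN=", "", ann), "\\|")[[1]]
    if (length(parts) != 4)
      stop(sprintf("malformed ANN token (need gene|pPOS|REF|ALT): %s", ann),
           call. = FALSE)
    data.frame(patient_id = cols[10], gene = parts[1],
               protein_pos = as.integer(sub("^p", "", parts[2])),
               ref_aa = parts[3], alt_aa = parts[4],
               stringsAsFactors = FALSE)
  })
  variant_table(do.call(rbind, rows))
}

#' @rdname read_inputs
#' @export
read_clinical <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "hpv_status", "uicc_stage",
                                 "recurrence", "dfs_time", "dfs_event",
                                 "has_serum"))
  clinical_table(df)
}

#' @rdname read_inputs
#' @export
read_hpv_counts <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", HPV_GENES))
  hpv_read_counts(df)
}

#' @rdname read_inputs
#' @export
read_apc_fractions <- function(path) {
  df <- read_tsv_checked(path, "cell_type")
  m <- as.matrix(df[, setdiff(names(df), "cell_type"), drop = FALSE])
  rownames(m) <- df$cell_type
  apc_fractions(m)
}

#' @rdname read_inputs
#' @export
read_panel_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  prot <- stats::setNames(as.character(aa), names(aa))
  names(prot) <- sub("\\s.*$", "", names(prot))  # header is the gene symbol
  if (anyDuplicated(names(prot)))
    stop("duplicate gene symbol in panel FASTA", call. = FALSE)
  prot <- toupper(prot)
  structure(prot, class = "panel_proteome")
}

# ---------------------------------------------------------------------------
# Writers
# ---------------------------------------------------------------------------

#' Write a pipeline object back to its on-disk format
#'
#' Output is deterministic: fixed column order and rows sorted by primary
#' key, so re-reading yields an equal object and repeated writes are
#' byte-identical.
#'
#' @param object a validated pipeline container.
#' @param path output path (main file).
#' @param ... extra paths for multi-file kinds (`lengths`, `groups`,
#'   `controls`), mirroring [read_inputs()].
#' @return invisibly, the main path written.
#' @export
write_outputs <- function(object, path, ...) UseMethod("write_outputs")

#' @export
write_outputs.ligandome <- function(object, path, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$sample_id, df$hla_class, df$peptide), ]
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
write_outputs.benign_atlas <- function(object, path, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$tissue, df$hla_class, df$peptide), ]
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
write_outputs.expression_matrix <- function(object, path, lengths, groups, ...) {
  ord <- order(rownames(object$counts))
  cdf <- data.frame(gene = rownames(object$counts)[ord],
                    object$counts[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(cdf, path)
  ldf <- data.frame(gene = rownames(object$counts)[ord],
                    length_nt = unname(object$gene_lengths[ord]))
  write_tsv_plain(ldf, lengths)
  gdf <- data.frame(sample = names(object$group), group = unname(object$group))
  utils::write.csv(gdf, groups, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_outputs.antibody_matrix <- function(object, path, controls, ...) {
  ord <- order(rownames(object$intensities))
  adf <- data.frame(antigen = rownames(object$intensities)[ord],
                    object$intensities[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(adf, path)
  writeLines(sort(object$positive_controls), controls)
  invisible(path)
}

#' @export
write_outputs.binding_table <- function(object, path, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$peptide, df$allele), ]
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
write_outputs.variant_table <- function(object, path, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$patient_id, df$gene, df$protein_pos), ]
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
write_outputs.clinical_table <- function(object, path, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$patient_id),
           c("patient_id", "hpv_status", "uicc_stage", "recurrence",
             "dfs_time", "dfs_event", "has_serum")]
  for (cn in c("recurrence", "dfs_event", "has_serum"))
    df[[cn]] <- as.integer(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_outputs.hpv_read_counts <- function(object, path, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$patient_id), ]
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
write_outputs.apc_fractions <- function(object, path, ...) {
  m <- unclass(object)
  ord <- order(rownames(m))
  df <- data.frame(cell_type = rownames(m)[ord], m[ord, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
write_outputs.panel_proteome <- function(object, path, ...) {
  prot <- unclass(object)
  prot <- prot[order(names(prot))]
  aa <- Biostrings::AAStringSet(prot)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' @export
write_outputs.tap_set <- function(object, path, ...) {
  n <- length(object$peptides)
  df <- data.frame(peptide = object$peptides,
                   hla_class = rep_len(object$hla_class, n),
                   stage = rep_len(object$stage, n),
                   genes = vapply(object$genes, paste, character(1),
                                  collapse = ";"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$peptide), ]
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
print.ligandome <- function(x, ...) {
  cat(sprintf("Ligandome (%s level): %d records, %d class I / %d class II peptides\n",
              attr(x, "level"), nrow(x),
              length(unique(x$peptide[x$hla_class == "I"])),
              length(unique(x$peptide[x$hla_class == "II"]))))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tumor, %d healthy mucosa); TPM %s\n",
              nrow(x$counts), ncol(x$counts), sum(x$group == "tumor"),
              sum(x$group == "healthy_mucosa"),
              if (is.null(x$tpm)) "not computed" else "computed"))
  invisible(x)
}
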