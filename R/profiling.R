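## Comparative ligandome profiling: TAP calling against the healthy-tonsil
## reference, benign-atlas filtering to tumor-unique peptides (TAP-U),
## binary presentation matrices, per-stratum presentation ratios, and
## allele-restriction counts from binding predictions.

new_tap_set <- function(hla_class, peptides, genes, stage,
                        overlap_count = NA_integer_) {
  stopifnot(stage %in% c("TAP", "TAP_U"))
  ord <- order(peptides)
  structure(list(hla_class = hla_class,
                 peptides = peptides[ord],
                 genes = genes[ord],
                 stage = stage,
                 overlap_count = overlap_count),
            class = "tap_set")
}

#' @export
print.tap_set <- function(x, ...) {
  cat(sprintf("%s set (HLA class %s): %d peptides from %d source genes\n",
              x$stage, x$hla_class, length(x$peptides),
              length(unique(unlist(x$genes)))))
  if (!is.na(x$overlap_count))
    cat(sprintf("  reference overlap: %d peptides\n", x$overlap_count))
  invisible(x)
}

#' Call tumor-associated peptides (TAP) by comparative profiling
#'
#' A tumor peptide of the requested HLA class is a TAP when its sequence
#' does not occur in the reference (healthy-tonsil) ligandome on *either*
#' HLA class -- the cross-class union rule. The count of tumor peptides of
#' the class that do occur in the reference is reported as the overlap.
#'
#' @param tumor cohort-union, panel-filtered tumor [ligandome()].
#' @param reference cohort-union reference ligandome (healthy tonsils).
#' @param hla_class `"I"` or `"II"`.
#' @param mapping optional [map_peptides()] result used to attach source
#'   genes to the returned set.
#' @return object of class `"tap_set"` with `stage = "TAP"` and the overlap
#'   count in `$overlap_count`.
#' @export
call_tap <- function(tumor, reference, hla_class, mapping = NULL) {
  stopifnot(inherits(tumor, "ligandome"), inherits(reference, "ligandome"))
  hla_class <- as_hla_class(hla_class)
  if (attr(tumor, "level") != "cohort-union")
    tumor <- as_cohort_union(tumor)
  if (attr(reference, "level") != "cohort-union")
    reference <- as_cohort_union(reference)
  tum <- unique(tumor$peptide[tumor$hla_class == hla_class])
  ref_union <- unique(reference$peptide)  # both classes
  if (!length(tum))
    warning(sprintf("empty tumor ligandome for HLA class %s", hla_class))
  overlap <- sum(tum %in% ref_union)
  keep <- tum[!tum %in% ref_union]
  genes <- peptide_gene_list(keep, mapping)
  new_tap_set(hla_class, keep, genes, "TAP", overlap_count = overlap)
}

peptide_gene_list <- function(peptides, mapping) {
  if (is.null(mapping)) return(rep(list(character(0)), length(peptides)))
  idx <- match(peptides, mapping$peptide)
  if (anyNA(idx))
    stop("mapping does not cover all TAP peptides", call. = FALSE)
  mapping$genes[idx]
}

#' Filter TAP against a benign-tissue ligand atlas (TAP-U calling)
#'
#' Retains TAP whose sequence occurs in no atlas entry of any tissue or HLA
#' class. An optional reference ligandome (healthy tonsils) is filtered
#' against as well, so the tonsil ligandome can join the atlas stage; since
#' TAP already exclude reference sequences this never changes counts.
#'
#' @param tap a `"tap_set"` with `stage == "TAP"`.
#' @param atlas a [benign_atlas()].
#' @param reference optional [ligandome()] additionally treated as benign.
#' @return `"tap_set"` with `stage = "TAP_U"`.
#' @export
call_tap_u <- function(tap, atlas, reference = NULL) {
  stopifnot(inherits(tap, "tap_set"))
  if (tap$stage != "TAP") stop("call_tap_u expects a TAP-stage set", call. = FALSE)
  benign <- character(0)
  if (is.null(atlas) || nrow(atlas) == 0) {
    warning("empty benign atlas: TAP returned unchanged")
  } else {
    stopifnot(inherits(atlas, "benign_atlas"))
    benign <- unique(atlas$peptide)
  }
  if (!is.null(reference)) benign <- union(benign, unique(reference$peptide))
  keep <- !tap$peptides %in% benign
  new_tap_set(tap$hla_class, tap$peptides[keep], tap$genes[keep], "TAP_U")
}

#' Distinct source-gene count of a TAP/TAP-U set
#'
#' @param tap a `"tap_set"` whose genes were attached via `mapping`.
#' @return integer count of distinct gene symbols.
#' @export
tap_gene_count <- function(tap) length(unique(unlist(tap$genes)))

#' Binary presentation matrix of a TAP set across patients
#'
#' Cell `(x, patient)` is 1 iff the patient's sample-level ligandome
#' contains peptide `x` (peptide level) or any peptide of gene `x` (gene
#' level) on the TAP set's HLA class. Gene rows are therefore the OR over
#' that gene's peptide rows.
#'
#' @param tap a `"tap_set"` (genes required for `level = "gene"`).
#' @param sample_ligandome sample-level [ligandome()] of the tumor cohort.
#' @param clinical a [clinical_table()] defining the patient columns.
#' @param level `"peptide"` or `"gene"`.
#' @return object of class `"presentation_matrix"`: binary matrix with an
#'   attached feature table (`attr(, "features")`: id and source genes) and
#'   metadata attributes `hla_class`, `level`.
#' @export
presentation_matrix <- function(tap, sample_ligandome, clinical,
                                level = c("peptide", "gene")) {
  level <- match.arg(level)
  stopifnot(inherits(tap, "tap_set"), inherits(sample_ligandome, "ligandome"),
            inherits(clinical, "clinical_table"))
  if (attr(sample_ligandome, "level") != "sample")
    stop("presentation_matrix needs a sample-level ligandome", call. = FALSE)
  lig <- as.data.frame(sample_ligandome)
  lig <- lig[lig$hla_class == tap$hla_class, , drop = FALSE]
  extra <- setdiff(unique(lig$sample_id), clinical$patient_id)
  if (length(extra))
    stop(sprintf("ligandome sample(s) absent from clinical table: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  patients <- clinical$patient_id
  if (level == "peptide") {
    ids <- tap$peptides
    gene_of <- tap$genes
    m <- vapply(patients, function(p) {
      as.integer(ids %in% lig$peptide[lig$sample_id == p])
    }, integer(length(ids)))
  } else {
    all_genes <- sort(unique(unlist(tap$genes)))
    if (!length(all_genes))
      stop("gene-level matrix requires gene annotations on the TAP set",
           call. = FALSE)
    ids <- all_genes
    gene_of <- as.list(all_genes)
    pep_of_gene <- lapply(all_genes, function(g) {
      tap$peptides[vapply(tap$genes, function(gs) g %in% gs, logical(1))]
    })
    m <- vapply(patients, function(p) {
      pres <- lig$peptide[lig$sample_id == p]
      vapply(pep_of_gene, function(peps) as.integer(any(peps %in% pres)),
             integer(1))
    }, integer(length(ids)))
  }
  m <- matrix(m, nrow = length(ids), ncol = length(patients),
              dimnames = list(ids, patients))
  structure(m,
            features = data.frame(id = ids, stringsAsFactors = FALSE,
                                  genes = I(gene_of)),
            hla_class = tap$hla_class, level = level,
            class = c("presentation_matrix", "matrix", "array"))
}

#' Presentation ratios per clinical stratum
#'
#' For each matrix row, the fraction of patients presenting it within each
#' stratum: all patients, HPV+, HPV-, low stage (UICC I-II) and high stage
#' (III-IV). Rows are ranked by all-cohort ratio, descending, ties broken
#' alphabetically. An empty stratum yields `NA`, not zero.
#'
#' @param pm a [presentation_matrix()].
#' @param clinical a [clinical_table()].
#' @return data.frame with columns `id`, `all`, `hpv_pos`, `hpv_neg`,
#'   `low_stage`, `high_stage`.
#' @export
presentation_ratios <- function(pm, clinical) {
  stopifnot(inherits(pm, "presentation_matrix"),
            inherits(clinical, "clinical_table"))
  pats <- colnames(pm)
  cl <- clinical[match(pats, clinical$patient_id), ]
  strata <- list(all = rep(TRUE, length(pats)),
                 hpv_pos = cl$hpv_status == "positive",
                 hpv_neg = cl$hpv_status == "negative",
                 low_stage = cl$stage_group == "low",
                 high_stage = cl$stage_group == "high")
  ratios <- lapply(strata, function(sel) {
    if (!any(sel)) return(rep(NA_real_, nrow(pm)))
    rowMeans(pm[, sel, drop = FALSE])
  })
  out <- data.frame(id = rownames(pm), stringsAsFactors = FALSE)
  for (nm in names(ratios)) out[[nm]] <- ratios[[nm]]
  out <- out[order(-out$all, out$id), ]
  rownames(out) <- NULL
  out
}

#' Count allele-restricted TAP-U peptides from binding predictions
#'
#' For each HLA allele, the number of distinct TAP-U sequences predicted to
#' bind it with affinity at or below the threshold (500 nM by convention;
#' the threshold is inclusive). One peptide may count toward several
#' alleles. TAP-U peptides absent from the binding table are excluded and
#' counted in the `n_unscored` attribute, with a warning.
#'
#' @param tap_u a `"tap_set"` with `stage == "TAP_U"`.
#' @param binding a [binding_table()].
#' @param threshold_nm inclusive affinity cutoff in nM.
#' @return data.frame `allele`, `n_peptides`, ranked descending (ties
#'   alphabetical), with attribute `n_unscored`.
#' @export
count_allele_restricted <- function(tap_u, binding, threshold_nm = 500) {
  stopifnot(inherits(tap_u, "tap_set"), inherits(binding, "binding_table"))
  scored <- unique(binding$peptide)
  unscored <- setdiff(tap_u$peptides, scored)
  if (length(unscored))
    warning(sprintf("%d TAP-U peptide(s) absent from binding table; excluded",
                    length(unscored)))
  b <- as.data.frame(binding)
  b <- b[b$peptide %in% tap_u$peptides & b$affinity_nM <= threshold_nm, ,
         drop = FALSE]
  if (nrow(b)) {
    tab <- stats::aggregate(peptide ~ allele, data = b,
                            FUN = function(x) length(unique(x)))
    names(tab) <- c("allele", "n_peptides")
  } else {
    tab <- data.frame(allele = character(0), n_peptides = integer(0))
  }
  tab <- tab[order(-tab$n_peptides, tab$allele), ]
  rownames(tab) <- NULL
  attr(tab, "n_unscored") <- length(unscored)
  tab
}
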