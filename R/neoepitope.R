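## Mutation-motif search: apply missense variants to panel proteins,
## enumerate candidate peptide windows spanning the variant position, and
## search the ligandome for exact matches.

#' Apply a single missense substitution to a protein sequence
#'
#' @param protein_seq amino-acid string.
#' @param pos 1-based protein position.
#' @param ref_aa expected reference residue at `pos`.
#' @param alt_aa alternate residue.
#' @param gene optional gene symbol for error messages.
#' @return mutated sequence, same length.
#' @export
apply_variant <- function(protein_seq, pos, ref_aa, alt_aa, gene = "<gene>") {
  L <- nchar(protein_seq)
  if (pos < 1 || pos > L)
    stop(sprintf("%s: position %d outside protein of length %d", gene, pos, L),
         call. = FALSE)
  found <- substr(protein_seq, pos, pos)
  if (found != ref_aa)
    stop(sprintf("%s: reference mismatch at position %d (expected %s, found %s)",
                 gene, pos, ref_aa, found), call. = FALSE)
  paste0(substr(protein_seq, 1, pos - 1), alt_aa,
         substr(protein_seq, pos + 1, L))
}

#' Enumerate mutant peptide windows covering a variant position
#'
#' All contiguous substrings of the mutated protein whose length is in the
#' configured ranges and which include the variant position, deduplicated
#' by sequence. Default lengths follow immunopeptidomics convention:
#' 8-12 residues for HLA class I and 12-25 for class II.
#'
#' @param mut_seq mutated protein sequence.
#' @param pos 1-based variant position within `mut_seq`.
#' @param class_i_lengths,class_ii_lengths integer vectors of window lengths.
#' @return data.frame `sequence`, `start`, `length`, `hla_class`
#'   (a window length in both ranges is emitted once per class).
#' @export
generate_mutant_windows <- function(mut_seq, pos,
                                    class_i_lengths = 8:12,
                                    class_ii_lengths = 12:25) {
  L <- nchar(mut_seq)
  if (pos < 1 || pos > L)
    stop("variant position outside the sequence", call. = FALSE)
  one_class <- function(lens, cls) {
    rows <- lapply(lens, function(w) {
      starts <- max(1L, pos - w + 1L):min(pos, L - w + 1L)
      starts <- starts[starts >= 1 & starts + w - 1L <= L]
      if (!length(starts)) return(NULL)
      data.frame(sequence = substring(mut_seq, starts, starts + w - 1L),
                 start = starts, length = w, hla_class = cls,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)
    out[!duplicated(out$sequence), , drop = FALSE]
  }
  out <- rbind(one_class(class_i_lengths, "I"), one_class(class_ii_lengths, "II"))
  rownames(out) <- NULL
  out
}

#' Build mutant candidates for every variant in a table
#'
#' @param variants a [variant_table()].
#' @param panel a `panel_proteome`.
#' @param ... window length ranges passed to [generate_mutant_windows()].
#' @return data.frame of candidates: `patient_id`, `gene`, `protein_pos`,
#'   `sequence`, `length`, `hla_class`.
#' @export
mutant_candidates <- function(variants, panel, ...) {
  stopifnot(inherits(variants, "variant_table"))
  prot <- unclass(panel)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!v$gene %in% names(prot)) return(NULL)  # off-panel gene
    mut <- apply_variant(prot[[v$gene]], v$protein_pos, v$ref_aa, v$alt_aa,
                         gene = v$gene)
    w <- generate_mutant_windows(mut, v$protein_pos, ...)
    if (is.null(w)) return(NULL)
    data.frame(patient_id = v$patient_id, gene = v$gene,
               protein_pos = v$protein_pos, sequence = w$sequence,
               length = w$length, hla_class = w$hla_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), gene = character(0),
                      protein_pos = integer(0), sequence = character(0),
                      length = integer(0), hla_class = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Search the ligandome for mutation-bearing candidate peptides
#'
#' Exact sequence matches between the candidate set and the ligandome
#' (both HLA classes). A hit is attributed to the variant's patient when it
#' occurs in that patient's own sample; otherwise it is flagged as a
#' cohort-wide match only.
#'
#' @param candidates a [mutant_candidates()] data.frame (columns
#'   `patient_id`, `gene`, `sequence` at minimum).
#' @param lig a [ligandome()] (sample level for patient attribution).
#' @return data.frame of hits: `sequence`, `gene`, `variant_patient`,
#'   `same_patient` (logical), `cohort_wide` (logical).
#' @export
search_ligandome <- function(candidates, lig) {
  stopifnot(inherits(lig, "ligandome"))
  hits <- candidates[candidates$sequence %in% lig$peptide, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(sequence = character(0), gene = character(0),
                      variant_patient = character(0),
                      same_patient = logical(0), cohort_wide = logical(0),
                      stringsAsFactors = FALSE))
  }
  same <- vapply(seq_len(nrow(hits)), function(i) {
    any(lig$peptide == hits$sequence[i] &
          lig$sample_id == hits$patient_id[i])
  }, logical(1))
  out <- data.frame(sequence = hits$sequence, gene = hits$gene,
                    variant_patient = hits$patient_id,
                    same_patient = same, cohort_wide = !same,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Rank genes by number of patients carrying at least one variant
#'
#' @param variants a [variant_table()].
#' @param gene_subset optional character vector restricting the tally (for
#'   example the TAP source genes); also used as the denominator set for
#'   the zero-variant patient fraction.
#' @param all_patients optional character vector of cohort patient ids for
#'   the zero-variant fraction; defaults to the patients in `variants`.
#' @return list `ranking` (data.frame `gene`, `n_patients`, descending,
#'   ties alphabetical) and `zero_variant_fraction`.
#' @export
summarize_mutated_genes <- function(variants, gene_subset = NULL,
                                    all_patients = NULL) {
  stopifnot(inherits(variants, "variant_table"))
  v <- as.data.frame(variants)
  if (!is.null(gene_subset)) v <- v[v$gene %in% gene_subset, , drop = FALSE]
  if (is.null(all_patients)) all_patients <- unique(variants$patient_id)
  if (nrow(v)) {
    u <- unique(v[, c("patient_id", "gene")])
    tab <- stats::aggregate(patient_id ~ gene, data = u, FUN = length)
    names(tab) <- c("gene", "n_patients")
    tab <- tab[order(-tab$n_patients, tab$gene), ]
  } else {
    tab <- data.frame(gene = character(0), n_patients = integer(0))
  }
  rownames(tab) <- NULL
  carriers <- unique(v$patient_id)
  zero_frac <- if (length(all_patients))
    1 - length(intersect(all_patients, carriers)) / length(all_patients)
  else 1
  list(ranking = tab, zero_variant_fraction = zero_frac)
}
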