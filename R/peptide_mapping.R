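## Peptide-to-protein mapping against the curated gene panel, panel
## filtering of ligandomes, and collapsing of nested length variants.

#' Build an exact-substring index over the panel proteome
#'
#' @param panel a `panel_proteome` (named character vector of protein
#'   sequences, names are unique gene symbols) or a named character vector.
#' @param il_equivalent fold isoleucine and leucine to a common token at
#'   build and query time (they are isobaric in MS). Default `FALSE`: exact
#'   matching is the single deterministic convention used for all counts.
#' @return object of class `"proteome_index"`.
#' @export
build_proteome_index <- function(panel, il_equivalent = FALSE) {
  prot <- unclass(panel)
  if (is.null(names(prot)) || !length(prot))
    stop("panel must be a non-empty named vector of protein sequences",
         call. = FALSE)
  if (anyDuplicated(names(prot)))
    stop(sprintf("duplicate gene symbol in panel: %s",
                 names(prot)[which(duplicated(names(prot)))[1]]),
         call. = FALSE)
  prot <- toupper(prot)
  folded <- if (il_equivalent) gsub("I", "L", prot, fixed = TRUE) else prot
  structure(list(proteins = prot, folded = folded,
                 il_equivalent = il_equivalent),
            class = "proteome_index")
}

#' Map peptide sequences to panel genes
#'
#' Every peptide is assigned all panel genes whose protein contains it as a
#' contiguous substring. Peptides matching more than one gene are retained
#' and flagged ambiguous; peptides matching none are flagged unmapped.
#'
#' @param peptides character vector of validated peptide sequences.
#' @param index a [build_proteome_index()] result.
#' @param il_equivalent fold I/L at query time; must be requested at index
#'   build time too (the index carries the folded proteins either way when
#'   built with `il_equivalent = TRUE`).
#' @return object of class `"peptide_mapping"`: data.frame with columns
#'   `peptide`, `genes` (list column), `n_genes`, `ambiguous`, `unmapped`.
#' @export
map_peptides <- function(peptides, index, il_equivalent = index$il_equivalent) {
  stopifnot(inherits(index, "proteome_index"))
  peptides <- normalize_peptides(peptides)
  peptides <- unique(peptides)
  targets <- if (il_equivalent) index$folded else index$proteins
  queries <- if (il_equivalent) gsub("I", "L", peptides, fixed = TRUE) else peptides
  genes <- lapply(queries, function(q) {
    names(targets)[grepl(q, targets, fixed = TRUE)]
  })
  n <- lengths(genes)
  out <- data.frame(peptide = peptides, n_genes = n,
                    ambiguous = n > 1, unmapped = n == 0,
                    stringsAsFactors = FALSE)
  out$genes <- genes
  structure(out[, c("peptide", "genes", "n_genes", "ambiguous", "unmapped")],
            class = c("peptide_mapping", "data.frame"))
}

#' Restrict a ligandome to panel-mapped peptides
#'
#' Drops every record whose peptide does not map to the panel proteome.
#' Idempotent; the panel-mapped cohort-union counts per HLA class are what
#' comparative profiling operates on.
#'
#' @param lig a [ligandome()].
#' @param mapping a [map_peptides()] result covering all sequences in `lig`.
#' @return filtered ligandome (same level), with the mapping attached as
#'   attribute `"mapping"`.
#' @export
filter_to_panel <- function(lig, mapping) {
  stopifnot(inherits(lig, "ligandome"), inherits(mapping, "peptide_mapping"))
  not_covered <- setdiff(lig$peptide, mapping$peptide)
  if (length(not_covered))
    stop(sprintf("mapping does not cover %d ligandome peptide(s), e.g. %s",
                 length(not_covered), not_covered[1]), call. = FALSE)
  mapped <- mapping$peptide[!mapping$unmapped]
  keep <- as.data.frame(lig)[lig$peptide %in% mapped, , drop = FALSE]
  out <- ligandome(keep, level = attr(lig, "level"))
  attr(out, "mapping") <- mapping
  out
}

#' Gene symbols behind a set of peptides
#'
#' Ambiguous (multi-gene) peptides count toward every matched gene.
#'
#' @param peptides character vector of peptide sequences.
#' @param mapping a [map_peptides()] result.
#' @return sorted character vector of distinct gene symbols.
#' @export
genes_of_peptides <- function(peptides, mapping) {
  idx <- match(peptides, mapping$peptide)
  if (anyNA(idx))
    stop("mapping does not cover all requested peptides", call. = FALSE)
  sort(unique(unlist(mapping$genes[idx])))
}

#' Collapse peptides into nested length-variant families
#'
#' Greedy grouping used for reporting: sequences are sorted by decreasing
#' length (ties broken alphabetically); each sequence joins the first
#' existing family whose representative contains it as a substring,
#' otherwise it founds a new family. All TAP/TAP-U counts elsewhere stay at
#' the distinct-sequence level; this is a display aid for Sankey-style
#' summaries of shorter length variants.
#'
#' @param sequences unique character vector of peptide sequences.
#' @return list of families, each `list(representative=, members=)`.
#' @export
collapse_variant_families <- function(sequences) {
  if (anyDuplicated(sequences)) stop("sequences must be unique", call. = FALSE)
  sequences <- sequences[order(-nchar(sequences), sequences)]
  reps <- character(0)
  members <- list()
  for (s in sequences) {
    hit <- which(vapply(reps, function(r) grepl(s, r, fixed = TRUE), logical(1)))
    if (length(hit)) {
      members[[hit[1]]] <- c(members[[hit[1]]], s)
    } else {
      reps <- c(reps, s)
      members[[length(reps)]] <- s
    }
  }
  mapply(function(r, m) list(representative = r, members = m),
         reps, members, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
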