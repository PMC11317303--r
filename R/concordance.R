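## Point-biserial correlation engine and the integration analyses across
## omics layers (presentation x TPM, presentation x antibody response,
## presentation x APC fractions), antibody normalization, the serum
## variance filter, and hypergeometric over-representation.

#' Point-biserial correlation between a binary and a continuous variable
#'
#' Computed from the point-biserial formula
#' `r = (M1 - M0)/s_n * sqrt(n1*n0)/n` with the population (divide-by-n)
#' standard deviation, which is algebraically the Pearson correlation of
#' the 0/1 coding with the continuous vector. The p-value uses
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom, two-sided.
#'
#' @param binary 0/1 vector (logical accepted).
#' @param continuous numeric vector of the same length (n >= 3).
#' @return list `r`, `p`, `n`, `computable`. Degenerate input (binary all
#'   0 or all 1, or constant continuous) is flagged `computable = FALSE`
#'   with `r` and `p` set to `NA` -- no number is emitted.
#' @export
point_biserial <- function(binary, continuous) {
  binary <- as.numeric(binary)
  if (length(binary) != length(continuous))
    stop("binary and continuous must have equal length", call. = FALSE)
  n <- length(binary)
  if (n < 3) stop("point-biserial needs n >= 3", call. = FALSE)
  if (!all(binary %in% c(0, 1)))
    stop("binary vector must contain only 0/1", call. = FALSE)
  n1 <- sum(binary == 1)
  n0 <- n - n1
  s_n <- sqrt(sum((continuous - mean(continuous))^2) / n)
  if (n1 == 0 || n0 == 0 || s_n == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, computable = FALSE))
  m1 <- mean(continuous[binary == 1])
  m0 <- mean(continuous[binary == 0])
  r <- (m1 - m0) / s_n * sqrt(n1 * n0) / n
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, computable = TRUE)
}

#' Stratified point-biserial correlation matrix across omics layers
#'
#' Pairs each presentation-matrix row with its matching row of a continuous
#' feature matrix and computes the point-biserial correlation within each
#' requested clinical stratum. At gene level each gene's presentation row is
#' paired with that gene's continuous row; at peptide level each peptide is
#' paired with its source gene's row (ambiguous peptides with every matched
#' gene). With `pairing = "all"` every (row, feature) combination is
#' correlated, as in an APC-infiltration matrix.
#'
#' @param pm a [presentation_matrix()].
#' @param continuous feature x patient numeric matrix (e.g. TPM, normalized
#'   antibody intensities, APC fractions); rownames are gene symbols for
#'   matched pairing.
#' @param clinical a [clinical_table()].
#' @param strata subset of `c("all","hpv_pos","hpv_neg","low_stage","high_stage")`.
#' @param pairing `"matched"` (by source gene) or `"all"` (full cross).
#' @return object of class `"correlation_result"`: data.frame with columns
#'   `feature_x`, `feature_y`, `stratum`, `n`, `r`, `p`, `significant`
#'   (p < 0.05; degenerate pairs carry `NA` and are never significant).
#' @export
correlation_matrix <- function(pm, continuous, clinical,
                               strata = c("all", "hpv_pos", "hpv_neg",
                                          "low_stage", "high_stage"),
                               pairing = c("matched", "all")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(pm, "presentation_matrix"),
            inherits(clinical, "clinical_table"))
  strata <- match.arg(strata, several.ok = TRUE)
  continuous <- as.matrix(continuous)
  shared <- intersect(colnames(pm), colnames(continuous))
  if (length(shared) < 3)
    stop("fewer than 3 shared patients between the two layers", call. = FALSE)
  cl <- clinical[match(shared, clinical$patient_id), ]
  sel_of <- list(all = rep(TRUE, length(shared)),
                 hpv_pos = cl$hpv_status == "positive",
                 hpv_neg = cl$hpv_status == "negative",
                 low_stage = cl$stage_group == "low",
                 high_stage = cl$stage_group == "high")
  feats <- attr(pm, "features")
  pairs <- if (pairing == "all") {
    expand.grid(x = rownames(pm), y = rownames(continuous),
                stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
      g <- intersect(unlist(feats$genes[feats$id == rownames(pm)[i]]),
                     rownames(continuous))
      if (attr(pm, "level") == "gene")
        g <- intersect(rownames(pm)[i], rownames(continuous))
      if (!length(g)) return(NULL)
      data.frame(x = rownames(pm)[i], y = g, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(pairs) || nrow(pairs) == 0)
    return(empty_correlation_result())
  res <- do.call(rbind, lapply(strata, function(st) {
    sel <- sel_of[[st]]
    ns <- sum(sel)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      if (ns < 3) {
        return(data.frame(feature_x = pairs$x[k], feature_y = pairs$y[k],
                          stratum = st, n = ns, r = NA_real_, p = NA_real_,
                          significant = FALSE, stringsAsFactors = FALSE))
      }
      pb <- point_biserial(pm[pairs$x[k], shared][sel],
                           continuous[pairs$y[k], shared][sel])
      data.frame(feature_x = pairs$x[k], feature_y = pairs$y[k],
                 stratum = st, n = pb$n, r = pb$r, p = pb$p,
                 significant = isTRUE(pb$p < 0.05),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL
  structure(res, class = c("correlation_result", "data.frame"))
}

empty_correlation_result <- function() {
  structure(data.frame(feature_x = character(0), feature_y = character(0),
                       stratum = character(0), n = integer(0), r = numeric(0),
                       p = numeric(0), significant = logical(0),
                       stringsAsFactors = FALSE),
            class = c("correlation_result", "data.frame"))
}

#' Normalize antibody array intensities against positive controls
#'
#' `normalized[a, p] = log2(intensity[a, p]) - median_c log2(intensity[c, p])`
#' over the array's positive-control proteins c, making columns comparable
#' across arrays; control rows are excluded from the analyte output.
#'
#' @param am an [antibody_matrix()].
#' @return the `antibody_matrix` with `$normalized` filled (analyte rows
#'   only).
#' @export
normalize_antibody <- function(am) {
  stopifnot(inherits(am, "antibody_matrix"))
  if (any(am$intensities <= 0))
    stop("antibody intensities must be positive for log normalization",
         call. = FALSE)
  li <- log2(am$intensities)
  ctl_med <- apply(li[am$positive_controls, , drop = FALSE], 2, stats::median)
  analyte <- setdiff(rownames(li), am$positive_controls)
  am$normalized <- sweep(li[analyte, , drop = FALSE], 2, ctl_med, "-")
  am
}

#' Variance-plus-array filter for class II TAP-U peptides
#'
#' Retains peptides whose presence vector over the serum patients contains
#' both a 0 and a 1 (variance across the cohort) and whose source gene is
#' among the antibody-array antigens.
#'
#' @param pm peptide-level [presentation_matrix()] over class II TAP-U.
#' @param serum_patients character vector of serum-sampled patient ids
#'   (subset of the matrix columns).
#' @param array_genes character vector of array antigen gene symbols.
#' @return list `peptides` (sorted), `genes` (distinct source genes of the
#'   retained peptides, sorted), `n_peptides`, `n_genes`.
#' @export
variance_filter_tap_u <- function(pm, serum_patients, array_genes) {
  stopifnot(inherits(pm, "presentation_matrix"))
  if (attr(pm, "level") != "peptide")
    stop("variance filter operates on a peptide-level matrix", call. = FALSE)
  serum_patients <- intersect(serum_patients, colnames(pm))
  if (!length(serum_patients)) stop("empty serum patient subset", call. = FALSE)
  sub <- pm[, serum_patients, drop = FALSE]
  has_var <- apply(sub, 1, function(v) any(v == 1) && any(v == 0))
  feats <- attr(pm, "features")
  on_array <- vapply(feats$genes[match(rownames(pm), feats$id)],
                     function(g) any(g %in% array_genes), logical(1))
  keep <- rownames(pm)[has_var & on_array]
  genes <- sort(unique(unlist(feats$genes[match(keep, feats$id)])))
  list(peptides = sort(keep), genes = genes,
       n_peptides = length(keep), n_genes = length(genes))
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, the upper-tail probability of observing at least the
#' seen overlap between the selected genes and the pathway within the
#' universe (`P(X >= k)` under the hypergeometric), BH-adjusted across
#' pathways. A pathway is significant at p < 0.05 AND q < 0.1.
#'
#' @param selected_genes character vector (subset of the universe).
#' @param pathway_sets named list of gene vectors; each pathway is
#'   intersected with the universe before testing.
#' @param universe_genes character vector of background genes.
#' @return data.frame `pathway`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, ordered by p.
#' @export
ora_hypergeometric <- function(selected_genes, pathway_sets, universe_genes) {
  universe <- unique(universe_genes)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  selected <- unique(selected_genes)
  if (length(setdiff(selected, universe)))
    stop("selected genes must be a subset of the universe", call. = FALSE)
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(pathway_sets), function(pw) {
    K <- length(intersect(pathway_sets[[pw]], universe))
    k <- length(intersect(pathway_sets[[pw]], selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < 0.05 & out$q < 0.1
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Fraction of significant correlations in a correlation result
#'
#' Convenience summary used for calibration checks: the share of computable
#' rows with p < 0.05.
#'
#' @param cr a `"correlation_result"`.
#' @return numeric scalar (NA when nothing is computable).
#' @export
significant_fraction <- function(cr) {
  ok <- !is.na(cr$p)
  if (!any(ok)) return(NA_real_)
  mean(cr$p[ok] < 0.05)
}
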