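## TPM computation and a two-group negative-binomial Wald differential
## expression stage (median-of-ratios normalization, method-of-moments
## dispersion, unshrunk log fold changes), plus DEG calling at the
## |LFC| > 1, FDR < 0.05 thresholds and the DEG/TAP gene intersection.

#' Compute transcripts per million
#'
#' `tpm[g,s] = (counts[g,s] / length_kb[g]) / sum_j (counts[j,s] / length_kb[j]) * 1e6`.
#' An all-zero sample yields an all-zero column with a warning.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths named positive vector of lengths in nucleotides.
#' @return TPM matrix; columns sum to 1e6 (up to all-zero samples).
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("every gene needs a positive length", call. = FALSE)
  rate <- counts / (gene_lengths / 1e3)
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf("all-zero sample(s): %s",
                    paste(colnames(counts)[zero], collapse = ", ")))
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of its
#' count to the gene's geometric mean across samples (the DESeq-style
#' normalization reference).
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero))
    stop(paste("no gene has nonzero counts in every sample;",
               "a pseudo-reference would be required"), call. = FALSE)
  lc <- log(counts[all_nonzero, , drop = FALSE])
  geo <- exp(rowMeans(lc))
  apply(counts[all_nonzero, , drop = FALSE], 2,
        function(col) stats::median(col / geo))
}

#' Negative-binomial Wald differential expression (tumor vs healthy mucosa)
#'
#' Counts are normalized by median-of-ratios size factors; the per-gene
#' dispersion is a pooled within-group method-of-moments estimate on the
#' normalized counts, floored at 1e-8; the group-difference coefficient is
#' the log ratio of pseudo-counted (+0.5) group means; its Wald z uses the
#' delta-method standard error `sqrt((1/mu + alpha)/n)` summed over groups,
#' with a two-sided normal p-value. Fold changes are reported unshrunk in
#' log2. All-zero genes get `lfc = 0, p = 1`.
#'
#' @param counts gene x sample count matrix.
#' @param groups named character vector over samples, values `"tumor"` or
#'   `"healthy_mucosa"`; at least two samples per group.
#' @param pseudo_count stabilizer added to normalized group means.
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @return object of class `"de_result"`: data.frame with columns `gene`,
#'   `lfc` (log2, tumor over healthy), `se` (of the natural-log
#'   coefficient), `p`, `q` (BH), `direction` (`up`/`down`/`ns`).
#' @export
nb_wald_de <- function(counts, groups, pseudo_count = 0.5,
                       dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- groups[colnames(counts)]
  if (anyNA(groups) || !all(groups %in% c("tumor", "healthy_mucosa")))
    stop("groups must label every sample as tumor or healthy_mucosa",
         call. = FALSE)
  i1 <- which(groups == "tumor")
  i2 <- which(groups == "healthy_mucosa")
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  sf <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, stats::var)
  ## pooled within-group method-of-moments dispersion:
  ## var = mu + alpha mu^2  =>  alpha = (var - mu) / mu^2
  num <- (n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  alpha <- ifelse(den > 0, num / den, dispersion_floor)
  alpha <- pmax(alpha, dispersion_floor)
  mu1 <- m1 + pseudo_count
  mu2 <- m2 + pseudo_count
  coef <- log(mu1) - log(mu2)
  se <- sqrt((1 / mu1 + alpha) / n1 + (1 / mu2 + alpha) / n2)
  z <- coef / se
  p <- 2 * stats::pnorm(-abs(z))
  degenerate <- m1 == 0 & m2 == 0
  coef[degenerate] <- 0
  p[degenerate] <- 1
  q <- bh_adjust(p)
  lfc <- coef / log(2)
  direction <- ifelse(lfc > 1 & q < 0.05, "up",
                      ifelse(lfc < -1 & q < 0.05, "down", "ns"))
  out <- data.frame(gene = rownames(counts), lfc = lfc, se = se,
                    p = p, q = q, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement, in the input
#' order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds, read literally: up means `lfc > lfc_thresh` and
#' `q < fdr`; down means `lfc < -lfc_thresh` and `q < fdr`. A gene at
#' exactly the fold-change threshold is not called.
#'
#' @param de a `"de_result"` (or data.frame with `gene`, `lfc`, `q`).
#' @param lfc_thresh log2 fold-change threshold.
#' @param fdr FDR threshold.
#' @return list with character vectors `up` and `down`.
#' @export
call_deg <- function(de, lfc_thresh = 1, fdr = 0.05) {
  list(up = de$gene[de$lfc > lfc_thresh & de$q < fdr],
       down = de$gene[de$lfc < -lfc_thresh & de$q < fdr])
}

#' Partition up-regulated DEG by TAP class membership
#'
#' Splits the up-regulated genes that source any TAP into those presented
#' only on HLA class I, only on class II, or on both classes.
#'
#' @param up_genes character vector of up-regulated DEG symbols.
#' @param tap_I_genes,tap_II_genes source-gene sets of the class I and II
#'   TAP sets.
#' @return list with `class_I_only`, `class_II_only`, `both` (sorted gene
#'   vectors), `n_class_I_only`, `n_class_II_only`, `n_both`, `total`.
#' @export
intersect_deg_tap <- function(up_genes, tap_I_genes, tap_II_genes) {
  up <- unique(up_genes)
  in1 <- up %in% tap_I_genes
  in2 <- up %in% tap_II_genes
  out <- list(class_I_only = sort(up[in1 & !in2]),
              class_II_only = sort(up[!in1 & in2]),
              both = sort(up[in1 & in2]))
  out$n_class_I_only <- length(out$class_I_only)
  out$n_class_II_only <- length(out$class_II_only)
  out$n_both <- length(out$both)
  out$total <- out$n_class_I_only + out$n_class_II_only + out$n_both
  out
}
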