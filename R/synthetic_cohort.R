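## Parameterized synthetic cohorts with the statistical structure the
## analysis assumes: NB counts with designed DEG, TPM-coupled Bernoulli
## peptide presentation, antibody log-intensities shifted by class II
## presentation, Dirichlet APC fractions, exponential DFS with an optional
## presentation-linked hazard, and HPV read counts around the 500-read rule.

#' Synthetic cohort parameters
#'
#' Defaults mirror the emulated study cohort: 40 patients, 22 HPV-positive,
#' 27 with serum, a 312-gene panel and 6 healthy mucosa RNA samples.
#'
#' @param n_patients number of tumor patients.
#' @param n_hpv_pos number of HPV-positive patients (exactly enforced by
#'   construction of the read counts).
#' @param n_serum number of serum-sampled patients.
#' @param n_genes_panel panel size.
#' @param n_healthy_mucosa healthy mucosa RNA samples.
#' @param nb_mean_range range of baseline negative-binomial means.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_deg_up,n_deg_down designed numbers of up/down-regulated genes.
#' @param deg_lfc designed absolute log2 fold change of the DEG.
#' @param presentation_coupling strength (>= 0) linking a gene's
#'   standardized log-TPM to the per-patient presentation log-odds of its
#'   peptides.
#' @param antibody_coupling additive log2-intensity shift of a gene's
#'   antibody signal in patients presenting it on HLA class II.
#' @param survival_hr hazard ratio on DFS for patients presenting the
#'   designated survival-linked peptide (1 = no effect).
#' @param seed RNG seed.
#' @return object of class `"cohort_params"` (a validated list).
#' @export
cohort_params <- function(n_patients = 40, n_hpv_pos = 22, n_serum = 27,
                          n_genes_panel = 312, n_healthy_mucosa = 6,
                          nb_mean_range = c(50, 2000), nb_dispersion = 0.1,
                          n_deg_up = 40, n_deg_down = 6, deg_lfc = 2,
                          presentation_coupling = 1, antibody_coupling = 1,
                          survival_hr = 1, seed = 1L) {
  p <- as.list(environment())
  if (p$n_hpv_pos > p$n_patients)
    stop("n_hpv_pos cannot exceed n_patients", call. = FALSE)
  if (p$n_serum > p$n_patients)
    stop("n_serum cannot exceed n_patients", call. = FALSE)
  if (p$deg_lfc <= 0) stop("deg_lfc must be positive", call. = FALSE)
  if (p$presentation_coupling < 0)
    stop("presentation_coupling must be >= 0", call. = FALSE)
  if (p$n_deg_up + p$n_deg_down > p$n_genes_panel)
    stop("more designed DEG than panel genes", call. = FALSE)
  structure(p, class = "cohort_params")
}

#' Generate a random panel proteome
#'
#' Stand-in for the curated antigen panel: `n_genes` records with unique
#' symbols `GENE0001...`, sequences i.i.d. uniform over the 20 amino acids.
#' Deterministic for a fixed seed.
#'
#' @param n_genes number of proteins.
#' @param min_len,max_len protein length bounds (residues), `min_len >= 50`.
#' @param seed RNG seed.
#' @return a `"panel_proteome"` (named character vector).
#' @export
generate_panel_proteome <- function(n_genes, min_len = 150, max_len = 400,
                                    seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (min_len < 50 || min_len > max_len)
    stop("need 50 <= min_len <= max_len", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  lens <- if (min_len == max_len) rep(min_len, n_genes)
          else sample(min_len:max_len, n_genes, replace = TRUE)
  prot <- random_aa(n_genes, lens)
  names(prot) <- sprintf("GENE%04d", seq_len(n_genes))
  structure(prot, class = "panel_proteome")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Draw exactly n reads over the HPV genes so that the >= 500 calling rule
## comes out as designed for each patient.
simulate_hpv_counts <- function(patient_ids, positive) {
  rows <- lapply(seq_along(patient_ids), function(i) {
    x <- stats::setNames(rep(0L, 8), HPV_GENES)
    if (positive[i]) {
      which_gene <- sample(c("E6", "E7"), 1)
      x[which_gene] <- 500L + stats::rpois(1, 400)
      others <- setdiff(HPV_GENES, which_gene)
      x[others] <- stats::rpois(length(others), 80)
    } else {
      repeat {
        x[HPV_GENES] <- stats::rpois(8, 30)
        if (all(x < 500) && sum(x) < 500) break
      }
    }
    data.frame(patient_id = patient_ids[i], as.list(x),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  hpv_read_counts(do.call(rbind, rows))
}

#' Simulate a full synthetic cohort
#'
#' Draws every layer the pipeline consumes with a designed ground truth:
#' counts are NB with the designed DEG multiplied by `2^deg_lfc` in tumor;
#' each panel gene gets one class I and one class II peptide (substrings of
#' its protein) whose per-patient presentation is
#' `Bernoulli(plogis(a0 + presentation_coupling * z(log TPM)))`; antibody
#' log2-intensities are Normal with an `antibody_coupling` shift when the
#' gene is presented on class II; APC fractions are Dirichlet; DFS times
#' are exponential with an optional hazard ratio for presenting the first
#' gene's class I peptide; HPV read counts are constructed so exactly
#' `n_hpv_pos` patients satisfy the calling rule.
#'
#' @param params a [cohort_params()].
#' @return object of class `"cohort_bundle"`: a list with the panel, the
#'   sample-level and union tumor ligandomes, expression matrix, antibody
#'   matrix, APC fractions, clinical table, HPV read counts and a `truth`
#'   record (designed DEG, peptide table, presence matrices).
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(params$seed)

  patients <- sprintf("Pat%02d", seq_len(params$n_patients))
  healthy <- sprintf("HM%02d", seq_len(params$n_healthy_mucosa))
  panel <- generate_panel_proteome(params$n_genes_panel,
                                   seed = params$seed + 1L)
  genes <- names(panel)
  gene_lengths <- stats::setNames(3 * nchar(panel), genes)

  deg_up <- genes[seq_len(params$n_deg_up)]
  deg_down <- genes[params$n_deg_up + seq_len(params$n_deg_down)]

  base_mu <- exp(stats::runif(length(genes), log(params$nb_mean_range[1]),
                              log(params$nb_mean_range[2])))
  names(base_mu) <- genes
  mu_tumor <- base_mu
  mu_tumor[deg_up] <- mu_tumor[deg_up] * 2^params$deg_lfc
  mu_tumor[deg_down] <- mu_tumor[deg_down] / 2^params$deg_lfc
  size <- 1 / params$nb_dispersion
  draw_counts <- function(mu, n) {
    matrix(stats::rnbinom(length(mu) * n, mu = rep(mu, n), size = size),
           nrow = length(mu))
  }
  counts <- cbind(draw_counts(mu_tumor, params$n_patients),
                  draw_counts(base_mu, params$n_healthy_mucosa))
  dimnames(counts) <- list(genes, c(patients, healthy))
  group <- stats::setNames(rep(c("tumor", "healthy_mucosa"),
                               c(params$n_patients, params$n_healthy_mucosa)),
                           c(patients, healthy))
  expr <- expression_matrix(counts, gene_lengths, group)
  expr$tpm <- compute_tpm(counts, gene_lengths)

  ## per-gene peptides: one class I 9-mer and one class II 15-mer
  pick_pep <- function(g, w) {
    L <- nchar(panel[[g]])
    s <- sample.int(L - w + 1L, 1)
    substr(panel[[g]], s, s + w - 1L)
  }
  pep_I <- vapply(genes, pick_pep, character(1), w = 9L)
  pep_II <- vapply(genes, pick_pep, character(1), w = 15L)

  tumor_tpm <- expr$tpm[, patients, drop = FALSE]
  lt <- log1p(tumor_tpm)
  z <- t(apply(lt, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  a0 <- stats::qlogis(0.3)
  draw_presence <- function() {
    pr <- stats::plogis(a0 + params$presentation_coupling * z)
    m <- matrix(stats::rbinom(length(pr), 1, pr), nrow = nrow(pr),
                dimnames = list(genes, patients))
    m
  }
  presence_I <- draw_presence()
  presence_II <- draw_presence()

  lig_rows <- function(presence, peps, cls) {
    idx <- which(presence == 1, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(sample_id = patients[idx[, 2]], hla_class = cls,
               peptide = peps[idx[, 1]], allele = "",
               stringsAsFactors = FALSE)
  }
  recs <- rbind(lig_rows(presence_I, pep_I, "I"),
                lig_rows(presence_II, pep_II, "II"))
  recs <- unique(recs)
  sample_lig <- ligandome(recs, level = "sample")

  ## antibody: one antigen per gene over the serum patients
  serum <- patients[seq_len(params$n_serum)]
  ab_log <- matrix(stats::rnorm(length(genes) * length(serum), 10, 1),
                   nrow = length(genes), dimnames = list(genes, serum))
  ab_log <- ab_log + params$antibody_coupling *
    presence_II[, serum, drop = FALSE]
  controls <- sprintf("POS_CTRL_%02d", 1:4)
  ctl <- matrix(stats::rnorm(length(controls) * length(serum), 14, 0.1),
                nrow = length(controls), dimnames = list(controls, serum))
  ab <- antibody_matrix(rbind(2^ab_log, 2^ctl), controls)

  apc <- {
    shape <- c(2, 1.5, 1.5, 1, 12)
    raw <- matrix(stats::rgamma(5 * params$n_patients, shape = shape),
                  nrow = 5)
    frac <- sweep(raw, 2, colSums(raw), "/")
    dimnames(frac) <- list(c(APC_CELL_TYPES, "Other"), patients)
    apc_fractions(frac)
  }

  hpv_positive <- seq_len(params$n_patients) %in%
    sample.int(params$n_patients, params$n_hpv_pos)
  hpv <- simulate_hpv_counts(patients, hpv_positive)

  stage <- sample(rep(c("I", "II", "III", "IV"),
                      length.out = params$n_patients))
  surv_gene <- genes[1]
  presents_surv <- presence_I[surv_gene, ] == 1
  base_rate <- 1 / 36  # per month
  rate <- base_rate * ifelse(presents_surv, params$survival_hr, 1)
  t_event <- stats::rexp(params$n_patients, rate)
  censor <- stats::runif(params$n_patients, 24, 60)
  dfs_time <- pmin(t_event, censor)
  dfs_event <- t_event <= censor
  clinical <- clinical_table(data.frame(
    patient_id = patients,
    hpv_status = ifelse(hpv_positive, "positive", "negative"),
    uicc_stage = stage,
    recurrence = dfs_event,
    dfs_time = round(dfs_time, 2),
    dfs_event = dfs_event,
    has_serum = patients %in% serum,
    stringsAsFactors = FALSE))

  truth <- list(deg_up = deg_up, deg_down = deg_down,
                peptides = data.frame(gene = rep(genes, 2),
                                      hla_class = rep(c("I", "II"),
                                                      each = length(genes)),
                                      peptide = c(pep_I, pep_II),
                                      stringsAsFactors = FALSE),
                presence_I = presence_I, presence_II = presence_II,
                survival_gene = surv_gene,
                survival_peptide = unname(pep_I[surv_gene]),
                hpv_positive = stats::setNames(hpv_positive, patients))

  structure(list(panel = panel,
                 tumor_ligandome_sample = sample_lig,
                 tumor_ligandome_union = as_cohort_union(sample_lig),
                 expression = expr,
                 antibody = ab,
                 apc = apc,
                 clinical = clinical,
                 hpv_counts = hpv,
                 params = params,
                 truth = truth),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort bundle: %d patients, %d panel genes\n",
              nrow(x$clinical), length(x$panel)))
  invisible(x)
}
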