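## Deterministic "paper-mirror" fixture: a synthetic cohort bundle whose
## set sizes reproduce, by explicit construction, the printed counts of the
## emulated study -- 223/102 panel-mapped tumor peptides, 40 and 5+3
## healthy-tonsil overlaps (hence 183/94 TAP), 110/32 benign-atlas hits
## (hence 73/62 TAP-U from exactly 46/44 source genes), a 40-up/6-down
## designed DEG list partitioning the TAP genes 16/4/6, a 262-antigen
## antibody array covering exactly 33 variance-passing class II TAP-U
## peptides from 23 genes over 27 serum patients, and the survival-linked
## peptides KTIQEVAGY (EGFR, class I) and VIAAVKIFPRFFMVAKQCSAG (LY6K,
## class II). Counts are engineered by choosing peptides as substrings of
## chosen panel proteins, never by rejection on set sizes.

EGFR_PEPTIDE <- "KTIQEVAGY"
LY6K_PEPTIDE <- "VIAAVKIFPRFFMVAKQCSAG"

BENIGN_TISSUES <- c(
  "adipose tissue", "adrenal gland", "bladder", "bone marrow", "brain",
  "cerebellum", "colon", "duodenum", "esophagus", "gallbladder", "heart",
  "kidney", "liver", "lung", "lymph node", "mammary gland", "muscle",
  "myelon", "ovary", "pancreas", "prostate", "rectum", "skin",
  "small intestine", "spleen", "stomach", "testis", "thymus", "thyroid",
  "trachea")

## Sample `n` substrings of `protein` (lengths drawn from `lens`) that are
## globally unique across the fixture and map to exactly one panel protein.
## The retry loop repairs the astronomically rare collision; set sizes are
## fixed up front, never by rejection.
draw_gene_peptides <- function(gene, n, lens, panel, registry) {
  prot <- panel[[gene]]
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      w <- if (length(lens) == 1) lens else sample(lens, 1)
      s <- sample.int(nchar(prot) - w + 1L, 1)
      pep <- substr(prot, s, s + w - 1L)
      n_hits <- sum(vapply(panel, function(pr) grepl(pep, pr, fixed = TRUE),
                           logical(1)))
      if (!pep %in% registry$seqs && n_hits == 1L) break
      pep <- NA_character_
    }
    if (is.na(pep))
      stop(sprintf("could not draw a unique peptide from %s", gene),
           call. = FALSE)
    registry$seqs <- c(registry$seqs, pep)
    out[i] <- pep
  }
  out
}

draw_decoys <- function(n, len, panel, registry) {
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      pep <- random_aa(1, len)
      hit <- any(vapply(panel, function(pr) grepl(pep, pr, fixed = TRUE),
                        logical(1)))
      if (!hit && !pep %in% registry$seqs) break
      pep <- NA_character_
    }
    if (is.na(pep)) stop("could not draw a decoy peptide", call. = FALSE)
    registry$seqs <- c(registry$seqs, pep)
    out[i] <- pep
  }
  out
}

## Embed a literal peptide into a protein at a fixed offset.
embed_peptide <- function(protein, peptide, at = 50L) {
  stopifnot(nchar(protein) >= at + nchar(peptide))
  paste0(substr(protein, 1, at - 1L), peptide,
         substr(protein, at + nchar(peptide), nchar(protein)))
}

#' Build the deterministic paper-mirror fixture
#'
#' Constructs a [simulate_cohort()]-style bundle whose cohort-union set
#' sizes after panel mapping equal the emulated study's printed counts (see
#' the file header of this module). The construction is fully deterministic
#' for a fixed seed; running it twice yields identical bundles.
#'
#' @param seed RNG seed for the construction.
#' @return a `"cohort_bundle"` with the additional elements
#'   `ht_ligandome` (sample-level healthy-tonsil ligandome), `atlas`,
#'   `binding`, `variants`, and a designed-truth record in `$truth`.
#' @export
build_paper_mirror_fixture <- function(seed = 20240729L) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)

  n_patients <- 40L
  patients <- sprintf("Pat%02d", seq_len(n_patients))
  serum <- patients[1:27]
  ht_samples <- sprintf("HT%02d", 1:5)
  healthy <- sprintf("HM%02d", 1:6)

  ## ---- panel -------------------------------------------------------------
  named_genes <- c("EGFR", "LY6K", "TP53", "KNL1", "TEX15", "SPAG17",
                   "ITGB1", "CTNNB1", "IMP3", "KDM5B", "H4C1", "COL6A1",
                   "PRSS50", "BUB1", "BUB1B", "FES", "MAGEA4", "CCNA1",
                   "CDK4", "CDK2", "FJX1", "KIF2C", "MAGED4", "PRAME",
                   "IGF2BP1", "IGF2BP3", "MYBL2", "DMRTB1", "TDRD1",
                   "MORC1", "PRM1", "ODF1", "CTAGE1")
  n_panel <- 312L
  lens <- sample(150:400, n_panel, replace = TRUE)
  prot <- random_aa(n_panel, lens)
  names(prot) <- c(named_genes,
                   sprintf("GENE%04d", seq_len(n_panel - length(named_genes))))
  prot[["EGFR"]] <- embed_peptide(prot[["EGFR"]], EGFR_PEPTIDE, at = 50L)
  prot[["LY6K"]] <- embed_peptide(prot[["LY6K"]], LY6K_PEPTIDE, at = 40L)
  panel <- structure(prot, class = "panel_proteome")
  genes <- names(panel)

  ## ---- gene pools (disjoint by construction) ------------------------------
  pool <- local({
    used <- character(0)
    anon <- genes[!genes %in% named_genes]  # named genes never back-fill
    take <- function(preferred, n) {
      picked <- preferred[!preferred %in% used]
      if (length(picked) < n) {
        fill <- setdiff(anon, c(used, picked))
        picked <- c(picked, fill[seq_len(n - length(picked))])
      }
      picked <- picked[seq_len(n)]
      used <<- c(used, picked)
      picked
    }
    A  <- take(c("PRAME", "IGF2BP1", "IGF2BP3", "BUB1B", "CCNA1", "CDK4",
                 "CDK2", "FJX1", "MAGEA4", "KIF2C", "MAGED4"), 16)  # up-DEG, TAP I only
    B  <- take(c("PRSS50", "FES", "MYBL2", "TDRD1"), 4)             # up-DEG, TAP II only
    C  <- take(c("BUB1", "DMRTB1", "MORC1", "PRM1", "ODF1", "CTAGE1"), 6) # up-DEG, both
    D  <- take(character(0), 14)                                    # up-DEG, no TAP
    E  <- take(character(0), 6)                                     # down-DEG
    GB <- take(c("EGFR", "ITGB1"), 2)        # non-DEG, TAP-U on both classes
    F1 <- take(character(0), 22)             # non-DEG, class I TAP-U
    F2 <- take(character(0), 32)             # non-DEG, class II TAP-U
    G1 <- take(c("CTNNB1", "IMP3", "KDM5B", "TP53"), 22)  # class I TAP, atlas-covered
    G2 <- take(c("H4C1", "COL6A1"), 16)      # class II TAP, atlas-covered
    H1 <- take(character(0), 20)             # tumor/HT class I overlap
    H2 <- take(character(0), 4)              # tumor/HT class II overlap
    HT <- take(character(0), 15)             # HT-only ligands
    AT <- take(character(0), 20)             # benign-atlas-only ligands
    list(A = A, B = B, C = C, D = D, E = E, GB = GB, F1 = F1, F2 = F2,
         G1 = G1, G2 = G2, H1 = H1, H2 = H2, HT = HT, AT = AT)
  })

  registry <- new.env(parent = emptyenv())
  registry$seqs <- c(EGFR_PEPTIDE, LY6K_PEPTIDE)

  len_I <- 8:12
  len_II <- 12:25

  draw_set <- function(genes_vec, per_gene, lens) {
    res <- lapply(seq_along(genes_vec), function(i) {
      data.frame(gene = genes_vec[i],
                 peptide = draw_gene_peptides(genes_vec[i], per_gene[i],
                                              lens, panel, registry),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }

  ## ---- class I tumor peptides (223 mapped = 73 TAP-U + 110 atlas + 40 HT) --
  ## TAP-U I: 73 peptides over the 46 genes A+C+GB+F1 (27 genes x2, 19 x1)
  tapu1_genes <- c(pool$A, pool$C, pool$GB, pool$F1)
  per1 <- stats::setNames(rep(1L, length(tapu1_genes)), tapu1_genes)
  per1[c(pool$F1, pool$GB, pool$A[1:3])] <- 2L  # 22 + 2 + 3 = 27 doubles
  tapu1 <- draw_set(tapu1_genes, per1[tapu1_genes], len_I)
  ## make KTIQEVAGY one of EGFR's two class I TAP-U peptides
  egfr_rows <- which(tapu1$gene == "EGFR")
  tapu1$peptide[egfr_rows[1]] <- EGFR_PEPTIDE
  stopifnot(nrow(tapu1) == 73)

  atlas_hit_I <- draw_set(pool$G1, rep(5L, 22), len_I)   # 110 peptides
  overlap_I <- draw_set(pool$H1, rep(2L, 20), len_I)     # 40 peptides

  ## ---- class II tumor peptides (102 mapped = 62 TAP-U + 32 atlas + 8 HT) --
  tapu2_genes <- c(pool$B, pool$C, pool$GB, pool$F2)
  per2 <- stats::setNames(rep(1L, length(tapu2_genes)), tapu2_genes)
  per2[c(pool$GB, pool$F2[1:16])] <- 2L  # 18 doubles, 26 singles = 62
  tapu2 <- draw_set(tapu2_genes, per2[tapu2_genes], len_II)
  ## make the LY6K survival peptide one of the class II TAP-U singles
  lysub <- which(tapu2$gene == pool$F2[17])[1]  # a designated single
  tapu2$gene[lysub] <- "LY6K"
  tapu2$peptide[lysub] <- LY6K_PEPTIDE
  ## swap LY6K into the gene set in place of that single's original gene
  pool$F2[17] <- "LY6K"
  stopifnot(nrow(tapu2) == 62,
            length(unique(tapu2$gene)) == 44)

  atlas_hit_II <- draw_set(pool$G2, rep(2L, 16), len_II)  # 32 peptides
  overlap_II <- draw_set(pool$H2, rep(2L, 4), len_II)     # 8: 5 to HT-II, 3 to HT-I

  ## ---- decoys (raw lists only; removed by panel mapping) ------------------
  decoys_I <- draw_decoys(30, 9L, panel, registry)
  decoys_II <- draw_decoys(10, 15L, panel, registry)

  ## ---- the 33-peptide / 23-gene array-variance subset ---------------------
  doubles2 <- c(pool$GB, pool$F2[1:16])            # 18 genes x2
  singles2 <- setdiff(unique(tapu2$gene), doubles2) # 26 genes x1
  array_doubles <- c("EGFR", doubles2[doubles2 != "EGFR"][1:9])  # 10 genes
  array_singles <- c("LY6K", "BUB1", "FES",
                     setdiff(singles2, c("LY6K", "BUB1", "FES"))[1:10]) # 13
  array23 <- c(array_doubles, array_singles)
  stopifnot(length(array23) == 23)
  filtered33 <- tapu2$peptide[tapu2$gene %in% array23]
  stopifnot(length(filtered33) == 33)
  off_array_genes <- setdiff(unique(tapu2$gene), array23)  # 21 genes, 29 peptides

  ## ---- healthy-tonsil ligandome ------------------------------------------
  ht_only_I <- draw_set(pool$HT, rep(3L, 15), len_I)    # 45 HT-only class I
  ht_only_II <- draw_set(pool$HT, rep(2L, 15), len_II)  # 30 HT-only class II
  ht_I_seqs <- c(overlap_I$peptide, overlap_II$peptide[6:8], ht_only_I$peptide)
  ht_II_seqs <- c(overlap_II$peptide[1:5], ht_only_II$peptide)

  distribute <- function(seqs, samples, cls, min_k = 1, max_k = length(samples)) {
    rows <- lapply(seqs, function(s) {
      k <- sample(min_k:max_k, 1)
      data.frame(sample_id = sample(samples, k), hla_class = cls, peptide = s,
                 allele = "", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  ht_lig <- ligandome(rbind(distribute(ht_I_seqs, ht_samples, "I", 1, 3),
                            distribute(ht_II_seqs, ht_samples, "II", 1, 3)),
                      level = "sample")

  ## ---- benign atlas (30 benign tissues + tonsil = 31 labels) --------------
  atlas_only <- draw_set(pool$AT, rep(4L, 20), len_I)  # 80 benign-only ligands
  atlas_assign <- function(seqs, cls) {
    rows <- lapply(seqs, function(s) {
      k <- sample(1:4, 1)
      data.frame(tissue = sample(BENIGN_TISSUES, k), hla_class = cls,
                 peptide = s, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  atlas_df <- rbind(
    atlas_assign(atlas_hit_I$peptide, "I"),
    ## cross-class filtering: some class I TAP recorded as class II benign
    data.frame(tissue = sample(BENIGN_TISSUES, 10), hla_class = "II",
               peptide = atlas_hit_I$peptide[1:10], stringsAsFactors = FALSE),
    atlas_assign(atlas_hit_II$peptide, "II"),
    atlas_assign(atlas_only$peptide, "I"))
  ## every benign tissue label must occur; pin one ligand to each
  atlas_df <- rbind(atlas_df,
                    data.frame(tissue = BENIGN_TISSUES, hla_class = "I",
                               peptide = rep_len(atlas_only$peptide, 30),
                               stringsAsFactors = FALSE))
  ## tonsil entries mirror the HT ligandome union (31st tissue label)
  atlas_df <- rbind(atlas_df,
                    data.frame(tissue = "tonsil",
                               hla_class = c(rep("I", length(ht_I_seqs)),
                                             rep("II", length(ht_II_seqs))),
                               peptide = c(ht_I_seqs, ht_II_seqs),
                               stringsAsFactors = FALSE))
  atlas <- benign_atlas(atlas_df)

  ## ---- clinical table -----------------------------------------------------
  stage <- sample(rep(c("I", "II", "III", "IV"), c(8, 13, 9, 10)))
  hpv_positive <- seq_len(n_patients) %in% sample.int(n_patients, 22)
  low_stage <- which(stage %in% c("I", "II"))
  egfr_presenters <- sort(sample.int(n_patients, 8))
  ## exclusively low-stage, within the serum subset so the peptide passes
  ## the serum variance filter without adjustment
  ly6k_presenters <- sort(sample(intersect(low_stage, 1:27), 5))
  other_recur <- sort(sample(setdiff(seq_len(n_patients), egfr_presenters), 7))
  recurrence <- seq_len(n_patients) %in% c(egfr_presenters, other_recur)
  dfs_time <- numeric(n_patients)
  dfs_event <- logical(n_patients)
  dfs_time[egfr_presenters] <- round(stats::runif(8, 2, 10), 1)
  dfs_event[egfr_presenters] <- TRUE
  dfs_time[other_recur] <- round(stats::runif(7, 12, 40), 1)
  dfs_event[other_recur] <- TRUE
  cens <- !recurrence
  dfs_time[cens] <- round(stats::runif(sum(cens), 30, 60), 1)
  dfs_event[cens] <- FALSE
  clinical <- clinical_table(data.frame(
    patient_id = patients, hpv_status = ifelse(hpv_positive, "positive",
                                               "negative"),
    uicc_stage = stage, recurrence = recurrence, dfs_time = dfs_time,
    dfs_event = dfs_event, has_serum = patients %in% serum,
    stringsAsFactors = FALSE))

  ## ---- per-patient presentation of the tumor union ------------------------
  union_I <- c(tapu1$peptide, atlas_hit_I$peptide, overlap_I$peptide, decoys_I)
  union_II <- c(tapu2$peptide, atlas_hit_II$peptide, overlap_II$peptide,
                decoys_II)
  presenters <- new.env(parent = emptyenv())
  for (s in c(union_I, union_II)) {
    k <- 1L + stats::rbinom(1, 11, 0.25)
    assign(s, sort(sample.int(n_patients, k)), envir = presenters)
  }
  assign(EGFR_PEPTIDE, egfr_presenters, envir = presenters)
  assign(LY6K_PEPTIDE, ly6k_presenters, envir = presenters)
  ## the 33 array peptides need a 0 and a 1 over the serum patients
  for (s in filtered33) {
    who <- get(s, envir = presenters)
    if (!any(who <= 27)) who <- sort(c(who, sample(1:27, 1)))
    if (all(seq_len(27) %in% who)) who <- setdiff(who, who[1])
    assign(s, who, envir = presenters)
  }
  lig_rows <- function(seqs, cls) {
    do.call(rbind, lapply(seqs, function(s) {
      data.frame(sample_id = patients[get(s, envir = presenters)],
                 hla_class = cls, peptide = s, allele = "",
                 stringsAsFactors = FALSE)
    }))
  }
  tumor_sample_lig <- ligandome(rbind(lig_rows(union_I, "I"),
                                      lig_rows(union_II, "II")),
                                level = "sample")
  tumor_union_lig <- as_cohort_union(tumor_sample_lig)

  ## ---- expression (40 tumor + 6 healthy mucosa) ---------------------------
  gene_lengths <- stats::setNames(3 * nchar(panel), genes)
  deg_up <- c(pool$A, pool$B, pool$C, pool$D)
  deg_down <- pool$E
  base_mu <- exp(stats::runif(n_panel, log(50), log(2000)))
  names(base_mu) <- genes
  mu_tumor <- base_mu
  mu_tumor[deg_up] <- mu_tumor[deg_up] * 4
  mu_tumor[deg_down] <- mu_tumor[deg_down] / 4
  counts <- cbind(
    matrix(stats::rnbinom(n_panel * n_patients, mu = rep(mu_tumor, n_patients),
                          size = 10), nrow = n_panel),
    matrix(stats::rnbinom(n_panel * 6, mu = rep(base_mu, 6), size = 10),
           nrow = n_panel))
  dimnames(counts) <- list(genes, c(patients, healthy))
  group <- stats::setNames(rep(c("tumor", "healthy_mucosa"), c(n_patients, 6)),
                           c(patients, healthy))
  expr <- expression_matrix(counts, gene_lengths, group)
  expr$tpm <- compute_tpm(counts, gene_lengths)

  ## designed-truth DE table (consumed where the study's shrunk fit is not
  ## re-estimated): designed DEG at |lfc| 2, q far below threshold
  truth_de <- data.frame(gene = genes,
                         lfc = ifelse(genes %in% deg_up, 2,
                                      ifelse(genes %in% deg_down, -2, 0)),
                         q = ifelse(genes %in% c(deg_up, deg_down), 1e-6, 0.6),
                         stringsAsFactors = FALSE)

  ## ---- antibody array: 262 antigens, 8 positive controls ------------------
  array_fill <- setdiff(genes, c(array23, off_array_genes))
  array_antigens <- c(array23, array_fill[seq_len(262 - 23)])
  controls <- sprintf("POS_CTRL_%02d", 1:8)
  ab_log <- matrix(stats::rnorm(262 * 27, 10, 1.2), nrow = 262,
                   dimnames = list(array_antigens, serum))
  ctl_log <- matrix(stats::rnorm(8 * 27, 14, 0.1), nrow = 8,
                    dimnames = list(controls, serum))
  antibody <- antibody_matrix(rbind(2^ab_log, 2^ctl_log), controls)

  ## ---- APC fractions ------------------------------------------------------
  apc <- {
    shape <- c(2, 1.5, 1.5, 1, 12)
    raw <- matrix(stats::rgamma(5 * n_patients, shape = shape), nrow = 5)
    frac <- sweep(raw, 2, colSums(raw), "/")
    dimnames(frac) <- list(c(APC_CELL_TYPES, "Other"), patients)
    apc_fractions(frac)
  }

  ## ---- binding predictions for class I TAP-U ------------------------------
  alleles <- c("HLA-B44:03", "HLA-B44:02", "HLA-B57:01", "HLA-B41:02",
               "HLA-C12:03", "HLA-A32:01", "HLA-A02:01", "HLA-A01:01",
               "HLA-B07:02", "HLA-C07:01")
  binding_rows <- do.call(rbind, lapply(tapu1$peptide, function(s) {
    al <- sample(alleles, sample(2:4, 1))
    data.frame(peptide = s, allele = al,
               affinity_nM = round(2^stats::runif(length(al), 3, 14), 1),
               percent_rank = round(stats::runif(length(al), 0.01, 30), 2),
               stringsAsFactors = FALSE)
  }))
  binding <- binding_table(binding_rows)

  ## ---- HPV read counts: exactly 22 positives, both rule boundaries --------
  pos_idx <- which(hpv_positive)
  neg_idx <- which(!hpv_positive)
  hpv_rows <- lapply(seq_len(n_patients), function(i) {
    x <- stats::setNames(rep(0L, 8), HPV_GENES)
    if (i %in% pos_idx) {
      r <- match(i, pos_idx)
      if (r == 1) {
        x["E6"] <- 500L                       # inclusive-threshold boundary
      } else if (r == 2) {
        x[HPV_GENES] <- 63L                   # combined-rule positive: sum 504
      } else if (r %% 2 == 0) {
        x["E6"] <- 500L + stats::rpois(1, 700)
        x[setdiff(HPV_GENES, "E6")] <- stats::rpois(7, 60)
      } else {
        x["E7"] <- 500L + stats::rpois(1, 700)
        x[setdiff(HPV_GENES, "E7")] <- stats::rpois(7, 60)
      }
    } else {
      r <- match(i, neg_idx)
      if (r == 1) {
        x[HPV_GENES] <- c(100L, 100L, 100L, 100L, 50L, 29L, 10L, 10L)  # 499
      } else {
        repeat {
          x[HPV_GENES] <- stats::rpois(8, 25)
          if (all(x < 500) && sum(x) < 500) break
        }
      }
    }
    data.frame(patient_id = patients[i], as.list(x), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  hpv <- hpv_read_counts(do.call(rbind, hpv_rows))

  ## ---- somatic variants (top genes; windows never in the ligandome) -------
  var_design <- list(TP53 = 20, EGFR = 12, KNL1 = 10, TEX15 = 9, SPAG17 = 8,
                     CDK2 = 5, KDM5B = 4, CTNNB1 = 3)
  var_rows <- do.call(rbind, lapply(names(var_design), function(g) {
    who <- sample(patients, var_design[[g]])
    pos <- sample(30:(nchar(panel[[g]]) - 30), length(who), replace = TRUE)
    ref <- substring(panel[[g]], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA_ALPHABET, r), 1),
                  character(1))
    data.frame(patient_id = who, gene = g, protein_pos = pos, ref_aa = ref,
               alt_aa = alt, stringsAsFactors = FALSE)
  }))
  variants <- variant_table(var_rows)

  truth <- list(
    deg_up = sort(deg_up), deg_down = sort(deg_down),
    de_table = truth_de,
    tap_I = sort(c(tapu1$peptide, atlas_hit_I$peptide)),
    tap_II = sort(c(tapu2$peptide, atlas_hit_II$peptide)),
    tap_u_I = sort(tapu1$peptide), tap_u_II = sort(tapu2$peptide),
    tap_u_I_genes = sort(unique(tapu1$gene)),
    tap_u_II_genes = sort(unique(tapu2$gene)),
    tap_I_genes = sort(unique(c(tapu1$gene, atlas_hit_I$gene))),
    tap_II_genes = sort(unique(c(tapu2$gene, atlas_hit_II$gene))),
    overlap_I = sort(overlap_I$peptide),
    overlap_II_on_ht_II = sort(overlap_II$peptide[1:5]),
    overlap_II_on_ht_I = sort(overlap_II$peptide[6:8]),
    decoys_I = sort(decoys_I), decoys_II = sort(decoys_II),
    array_genes = sort(array_antigens),
    variance_filtered_peptides = sort(filtered33),
    variance_filtered_genes = sort(array23),
    survival_peptide_I = EGFR_PEPTIDE,
    survival_peptide_II = LY6K_PEPTIDE,
    egfr_presenters = patients[egfr_presenters],
    ly6k_presenters = patients[ly6k_presenters],
    hpv_positive = stats::setNames(hpv_positive, patients),
    presence = mget(ls(presenters), envir = presenters))

  structure(list(panel = panel,
                 tumor_ligandome_sample = tumor_sample_lig,
                 tumor_ligandome_union = tumor_union_lig,
                 ht_ligandome = ht_lig,
                 atlas = atlas,
                 expression = expr,
                 antibody = antibody,
                 apc = apc,
                 binding = binding,
                 variants = variants,
                 clinical = clinical,
                 hpv_counts = hpv,
                 seed = seed,
                 truth = truth),
            class = "cohort_bundle")
}
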