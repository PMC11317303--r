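# Comparative profiling: TAP/TAP-U calling, presentation matrices and
# ratios, and binder-restriction counts.

mini_union <- function(peps, cls = "I") {
  ligandome(data.frame(sample_id = "cohort", hla_class = cls, peptide = peps),
            level = "cohort-union")
}

test_that("self-comparison empties the TAP set and warns on empty tumor", {
  tum <- mini_union(c("ACDEFGHIK", "WYVTSRQPN"))
  expect_length(call_tap(tum, tum, "I")$peptides, 0L)
  empty <- mini_union("ACDEFGHIK")[0, ]
  empty <- ligandome(as.data.frame(empty), level = "cohort-union")
  expect_warning(call_tap(empty, tum, "I"), "empty")
})

test_that("cross-class union rule excludes matches on either reference class", {
  tum2 <- mini_union(c("ACDEFGHIKLMN", "CDEFGHIKLMNP"), cls = "II")
  ref <- ligandome(data.frame(sample_id = "cohort",
                              hla_class = c("I", "II"),
                              peptide = c("ACDEFGHIKLMN", "WYVTSRQPNMLK")),
                   level = "cohort-union")
  tap <- call_tap(tum2, ref, "II")
  # the class II tumor peptide seen on reference class I is excluded
  expect_equal(tap$peptides, "CDEFGHIKLMNP")
  expect_equal(tap$overlap_count, 1L)
})

test_that("growing the reference never grows the TAP set", {
  set.seed(7)
  peps <- unique(tapconcord:::random_aa(40, 9))
  tum <- mini_union(peps)
  ref_small <- mini_union(sample(peps, 5))
  for (extra in c(5, 15, 25)) {
    ref_big <- mini_union(unique(c(ref_small$peptide, sample(peps, extra))))
    tap_small <- call_tap(tum, ref_small, "I")$peptides
    tap_big <- call_tap(tum, ref_big, "I")$peptides
    expect_true(all(tap_big %in% tap_small))
  }
})

test_that("TAP/TAP-U invariants hold on the fixture pipeline", {
  prof <- fixture_profile()
  atlas_seqs <- unique(prof$bundle$atlas$peptide)
  ref_seqs <- unique(prof$ht$peptide)
  for (pair in list(list(prof$tap1, prof$tapu1), list(prof$tap2, prof$tapu2))) {
    tap <- pair[[1]]; tapu <- pair[[2]]
    expect_true(all(tap$peptides %in% prof$mapped_union$peptide))
    expect_false(any(tap$peptides %in% ref_seqs))
    expect_true(all(tapu$peptides %in% tap$peptides))
    expect_false(any(tapu$peptides %in% atlas_seqs))
  }
  # TAP-U peptide and gene memberships equal the designed truth
  expect_equal(sort(prof$tapu1$peptides), prof$bundle$truth$tap_u_I)
  expect_equal(sort(prof$tapu2$peptides), prof$bundle$truth$tap_u_II)
  expect_equal(sort(unique(unlist(prof$tapu1$genes))),
               prof$bundle$truth$tap_u_I_genes)
  # an atlas containing every TAP sequence empties the set
  all_atlas <- benign_atlas(data.frame(tissue = "everything", hla_class = "I",
                                       peptide = prof$tap1$peptides))
  expect_length(call_tap_u(prof$tap1, all_atlas)$peptides, 0L)
  expect_warning(call_tap_u(prof$tap1, NULL), "empty")
})

test_that("presentation matrix matches designed presence, gene rows OR peptides", {
  prof <- fixture_profile()
  b <- prof$bundle
  pm <- presentation_matrix(prof$tapu1, b$tumor_ligandome_sample, b$clinical,
                            level = "peptide")
  expect_true(all(pm %in% c(0, 1)))
  truth_counts <- vapply(rownames(pm),
                         function(s) length(b$truth$presence[[s]]), integer(1))
  expect_equal(unname(rowSums(pm)), unname(truth_counts))

  gm <- presentation_matrix(prof$tapu1, b$tumor_ligandome_sample, b$clinical,
                            level = "gene")
  feats <- attr(pm, "features")
  for (g in sample(rownames(gm), 10)) {
    peps <- feats$id[vapply(feats$genes, function(x) g %in% x, logical(1))]
    expect_equal(unname(gm[g, ]),
                 unname(as.integer(colSums(pm[peps, , drop = FALSE]) > 0)))
  }
  # unknown sample triggers an error
  bad <- ligandome(data.frame(sample_id = "Ghost", hla_class = "I",
                              peptide = prof$tapu1$peptides[1]),
                   level = "sample")
  expect_error(presentation_matrix(prof$tapu1, bad, b$clinical), "Ghost")
})

test_that("presentation ratios partition across HPV strata", {
  prof <- fixture_profile()
  b <- prof$bundle
  pm <- presentation_matrix(prof$tapu1, b$tumor_ligandome_sample, b$clinical,
                            level = "gene")
  pr <- presentation_ratios(pm, b$clinical)
  n_pos <- sum(b$clinical$hpv_status == "positive")
  n_neg <- sum(b$clinical$hpv_status == "negative")
  counts_all <- pr$all * nrow(b$clinical)
  counts_split <- pr$hpv_pos * n_pos + pr$hpv_neg * n_neg
  expect_equal(counts_all, counts_split)
  # ranked by all-cohort ratio descending
  expect_true(all(diff(pr$all) <= 0))

  # empty stratum reports NA, not zero
  cl_allpos <- b$clinical
  cl_allpos$hpv_status <- "positive"
  cl_allpos <- clinical_table(as.data.frame(cl_allpos)[
    , c("patient_id", "hpv_status", "uicc_stage", "recurrence", "dfs_time",
        "dfs_event", "has_serum")])
  pr2 <- presentation_ratios(pm, cl_allpos)
  expect_true(all(is.na(pr2$hpv_neg)))
})

test_that("binder restriction uses an inclusive 500 nM threshold", {
  tapu <- tapconcord:::new_tap_set("I", c("ACDEFGHIK", "WYVTSRQPN",
                                          "CDEFGHIKL"),
                                   rep(list(character(0)), 3), "TAP_U")
  bt <- binding_table(data.frame(
    peptide = c("ACDEFGHIK", "ACDEFGHIK", "WYVTSRQPN"),
    allele = c("HLA-A02:01", "HLA-B07:02", "HLA-A02:01"),
    affinity_nM = c(500, 500.01, 12)))
  expect_warning(res <- count_allele_restricted(tapu, bt), "absent")
  expect_equal(attr(res, "n_unscored"), 1L)
  # exactly-500 counted; 500.01 not; two peptides restricted on A02:01
  expect_equal(res$n_peptides[res$allele == "HLA-A02:01"], 2L)
  expect_false("HLA-B07:02" %in% res$allele)

  # one peptide binding two alleles contributes to each
  bt2 <- binding_table(data.frame(peptide = "ACDEFGHIK",
                                  allele = c("HLA-A02:01", "HLA-B07:02"),
                                  affinity_nM = c(100, 100)))
  tap1 <- tapconcord:::new_tap_set("I", "ACDEFGHIK", list(character(0)),
                                   "TAP_U")
  res2 <- count_allele_restricted(tap1, bt2)
  expect_equal(res2$n_peptides, c(1L, 1L))
})
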