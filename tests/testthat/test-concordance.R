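# Point-biserial engine, stratified correlation matrices, antibody
# normalization, the serum variance filter, and hypergeometric ORA.

test_that("point-biserial matches the hand calculation and is antisymmetric", {
  pb <- point_biserial(c(1, 1, 0, 0), c(10, 8, 2, 0))
  expect_equal(pb$r, 8 / sqrt(68), tolerance = 1e-12)

  swapped <- point_biserial(c(0, 0, 1, 1), c(10, 8, 2, 0))
  expect_equal(swapped$r, -pb$r, tolerance = 1e-12)
  expect_equal(swapped$p, pb$p, tolerance = 1e-12)

  # constant continuous or degenerate binary: flagged, no number emitted
  expect_false(point_biserial(c(1, 0, 1, 0), c(5, 5, 5, 5))$computable)
  expect_false(point_biserial(c(1, 1, 1, 1), c(1, 2, 3, 4))$computable)
  expect_error(point_biserial(c(1, 0, 2), c(1, 2, 3)), "0/1")
})

test_that("point-biserial equals Pearson on 0/1 coding over random vectors", {
  set.seed(33)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    b <- rbinom(n, 1, 0.5)
    y <- rnorm(n)
    if (all(b == 0) || all(b == 1)) next
    pb <- point_biserial(b, y)
    expect_equal(pb$r, cor(b, y), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(b, y))
    expect_equal(pb$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("correlation matrix books strata correctly and flags degeneracy", {
  cl <- clinical_table(data.frame(
    patient_id = sprintf("P%02d", 1:10),
    hpv_status = rep(c("positive", "negative"), each = 5),
    uicc_stage = rep(c("I", "III"), 5),
    recurrence = FALSE, dfs_time = 10, dfs_event = FALSE, has_serum = TRUE))
  tap <- tapconcord:::new_tap_set("I", c("ACDEFGHIK", "CDEFGHIKL"),
                                  list("GENEA", "GENEB"), "TAP_U")
  # GENEB's peptide presented only in HPV- patients
  lig <- ligandome(data.frame(
    sample_id = c("P01", "P02", "P06", "P07", "P06", "P08"),
    hla_class = "I",
    peptide = c("ACDEFGHIK", "ACDEFGHIK", "ACDEFGHIK", "ACDEFGHIK",
                "CDEFGHIKL", "CDEFGHIKL")), level = "sample")
  pm <- presentation_matrix(tap, lig, cl, level = "peptide")
  cont <- matrix(rnorm(20), nrow = 2, dimnames = list(c("GENEA", "GENEB"),
                                                      cl$patient_id))
  cr <- correlation_matrix(pm, cont, cl,
                           strata = c("all", "hpv_pos", "hpv_neg"))
  expect_s3_class(cr, "correlation_result")
  expect_true(all(cr$n[cr$stratum == "all"] == 10))
  expect_true(all(cr$n[cr$stratum == "hpv_pos"] == 5))
  # GENEB presentation is constant (all zero) within HPV+: not computable
  row <- cr[cr$feature_x == "CDEFGHIKL" & cr$stratum == "hpv_pos", ]
  expect_true(is.na(row$r))
  expect_false(row$significant)
  expect_true(all(abs(cr$r[!is.na(cr$r)]) <= 1))
  expect_error(correlation_matrix(pm, cont[, 1:2], cl), "shared")
})

test_that("antibody normalization is a per-array log-ratio to controls", {
  m <- matrix(c(8, 32, 16,    # array P1: analytes 8, 32; control 16
                4, 64, 32),   # array P2 scaled differently
              nrow = 3, dimnames = list(c("AG1", "AG2", "CTL"), c("P1", "P2")))
  am <- normalize_antibody(antibody_matrix(m, "CTL"))
  expect_equal(rownames(am$normalized), c("AG1", "AG2"))
  expect_equal(unname(am$normalized["AG1", ]), c(-1, -3))
  expect_equal(unname(am$normalized["AG2", ]), c(1, 1))

  # scaling a whole array leaves its normalized values unchanged
  m4 <- m; m4[, 2] <- m4[, 2] * 4
  am4 <- normalize_antibody(antibody_matrix(m4, "CTL"))
  expect_equal(am4$normalized, am$normalized)

  # an analyte sitting at the control median normalizes to zero
  m0 <- matrix(c(16, 16), nrow = 2, dimnames = list(c("AG1", "CTL"), "P1"))
  expect_equal(unname(normalize_antibody(
    antibody_matrix(m0, "CTL"))$normalized["AG1", ]), 0)

  expect_error(normalize_antibody(antibody_matrix(
    matrix(c(-1, 2), nrow = 2, dimnames = list(c("AG1", "CTL"), "P1")),
    "CTL")), "positive")
})

test_that("variance filter requires serum variance and array coverage", {
  cl <- clinical_table(data.frame(
    patient_id = sprintf("P%02d", 1:6),
    hpv_status = "positive", uicc_stage = "I", recurrence = FALSE,
    dfs_time = 10, dfs_event = FALSE, has_serum = c(rep(TRUE, 4), FALSE,
                                                    FALSE)))
  tap <- tapconcord:::new_tap_set(
    "II", c("ACDEFGHIKLMN", "CDEFGHIKLMNP", "DEFGHIKLMNPQ"),
    list("ONARRAY", "ONARRAY2", "OFFARRAY"), "TAP_U")
  lig <- ligandome(data.frame(
    sample_id = c("P01", "P02",                       # variance within serum
                  "P01", "P02", "P03", "P04",         # presented in all serum
                  "P01"),                             # off-array gene
    hla_class = "II",
    peptide = c(rep("ACDEFGHIKLMN", 2), rep("CDEFGHIKLMNP", 4),
                "DEFGHIKLMNPQ")), level = "sample")
  pm <- presentation_matrix(tap, lig, cl, level = "peptide")
  serum <- cl$patient_id[cl$has_serum]
  res <- variance_filter_tap_u(pm, serum, c("ONARRAY", "ONARRAY2"))
  expect_equal(res$peptides, "ACDEFGHIKLMN")
  expect_equal(res$genes, "ONARRAY")
  expect_error(variance_filter_tap_u(pm, character(0), "ONARRAY"), "serum")
})

test_that("hypergeometric ORA matches exact combinatorics and enumeration", {
  sets <- list(pw = paste0("g", 1:5))
  universe <- paste0("g", 1:20)
  res <- ora_hypergeometric(paste0("g", 1:5), sets, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap is never significant
  res0 <- ora_hypergeometric(paste0("g", 6:10), sets, universe)
  expect_equal(res0$k, 0L)
  expect_false(res0$significant)
  expect_true(res0$p > 0 && res0$p <= 1)

  # brute-force enumeration over all draws for small universes
  set.seed(17)
  for (rep in 1:10) {
    N <- sample(6:12, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    pw <- list(pw = sample(uni, K))
    sel <- sample(uni, n)
    k_obs <- length(intersect(pw$pw, sel))
    draws <- utils::combn(N, n)
    in_pw <- uni %in% pw$pw
    tail_p <- mean(apply(draws, 2, function(ix) sum(in_pw[ix]) >= k_obs))
    got <- ora_hypergeometric(sel, pw, uni)
    expect_equal(got$p, tail_p, tolerance = 1e-12)
  }
  expect_error(ora_hypergeometric("x", list(a = "x"), character(0)), "universe")
  expect_error(ora_hypergeometric("zz", list(a = "x"), "x"), "subset")
})
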