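# TPM, size factors, the NB Wald DE stage, BH adjustment and DEG calling.

test_that("TPM has the defining symmetry, scale-invariance and column sums", {
  cnt <- matrix(100L, nrow = 4, ncol = 2,
                dimnames = list(paste0("G", 1:4), c("S1", "S2")))
  len <- stats::setNames(rep(300, 4), paste0("G", 1:4))
  tpm <- compute_tpm(cnt, len)
  expect_equal(unname(tpm), matrix(250000, 4, 2))

  cnt2 <- cnt
  cnt2[, 2] <- cnt2[, 2] * 2L
  expect_equal(compute_tpm(cnt2, len)[, 2], tpm[, 2])

  set.seed(1)
  cnt3 <- matrix(rpois(60, 50), nrow = 6,
                 dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
  len3 <- stats::setNames(sample(200:2000, 6), paste0("G", 1:6))
  expect_equal(unname(colSums(compute_tpm(cnt3, len3))), rep(1e6, 10),
               tolerance = 1e-6)

  expect_error(compute_tpm(cnt, stats::setNames(c(0, 300, 300, 300),
                                                paste0("G", 1:4))),
               "positive")
  cnt4 <- cnt; cnt4[, 1] <- 0L
  expect_warning(z <- compute_tpm(cnt4, len), "all-zero")
  expect_equal(unname(z[, 1]), rep(0, 4))
})

test_that("median-of-ratios size factors match the closed forms", {
  cnt <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), nrow = 3,
                dimnames = list(paste0("G", 1:3), c("S1", "S2")))
  expect_equal(unname(size_factors_median_of_ratios(cnt)), c(1, 1))

  cnt2 <- cnt
  cnt2[, 2] <- cnt2[, 1] * 2L
  expect_equal(unname(size_factors_median_of_ratios(cnt2)),
               c(1 / sqrt(2), sqrt(2)))

  # scaling one sample by c scales its factor relative to the others by c
  set.seed(2)
  cnt3 <- matrix(rpois(50, 100) + 1L, nrow = 10, ncol = 5,
                 dimnames = list(paste0("G", 1:10), paste0("S", 1:5)))
  f <- size_factors_median_of_ratios(cnt3)
  cnt4 <- cnt3
  cnt4[, 3] <- cnt4[, 3] * 7L
  f2 <- size_factors_median_of_ratios(cnt4)
  expect_equal(unname(f2[3] / f2[1]), unname(7 * f[3] / f[1]),
               tolerance = 1e-12)

  expect_error(size_factors_median_of_ratios(diag(0L, 3)), "nonzero")
})

test_that("NB Wald DE is centered under the null and finds designed DEG", {
  set.seed(101)
  n_genes <- 500
  mu <- exp(runif(n_genes, log(50), log(2000)))
  draw <- function(m) matrix(rnbinom(n_genes * 20, mu = rep(m, 20), size = 10),
                             nrow = n_genes)
  null_counts <- cbind(draw(mu), draw(mu))
  dimnames(null_counts) <- list(paste0("g", 1:n_genes), paste0("s", 1:40))
  grp <- stats::setNames(rep(c("tumor", "healthy_mucosa"), each = 20),
                         colnames(null_counts))
  de0 <- nb_wald_de(null_counts, grp)
  expect_lt(abs(median(de0$lfc)), 0.1)
  expect_true(all(de0$q >= de0$p))

  mu_t <- mu
  mu_t[1:30] <- mu_t[1:30] * 4  # designed lfc 2
  alt_counts <- cbind(draw(mu_t), draw(mu))
  dimnames(alt_counts) <- dimnames(null_counts)
  de1 <- nb_wald_de(alt_counts, grp)
  deg <- call_deg(de1)
  expect_gte(mean(paste0("g", 1:30) %in% deg$up), 0.8)
  expect_lt(abs(mean(de1$lfc[1:30]) - 2), 0.5)
})

test_that("degenerate genes and small groups are handled", {
  cnt <- matrix(c(0L, 0L, 0L, 0L, 5L, 6L, 7L, 8L), nrow = 2, byrow = TRUE,
                dimnames = list(c("zero", "ok"), paste0("s", 1:4)))
  grp <- stats::setNames(rep(c("tumor", "healthy_mucosa"), each = 2),
                         paste0("s", 1:4))
  de <- nb_wald_de(cnt, grp)
  expect_equal(de$p[de$gene == "zero"], 1)
  expect_equal(de$lfc[de$gene == "zero"], 0)
  expect_error(nb_wald_de(cnt[, 1:3],
                          stats::setNames(c("tumor", "tumor",
                                            "healthy_mucosa"),
                                          paste0("s", 1:3))),
               "at least 2")
})

test_that("BH adjustment matches the hand step-up and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_bh <- function(p) {
    n <- length(p)
    ord <- order(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
      # step-up: smallest n*p_(j)/j over ranks j at or above p_i's rank
      rank_i <- match(i, ord)
      q[i] <- min(vapply(rank_i:n, function(j) n * p[ord[j]] / j, numeric(1)))
      q[i] <- min(q[i], 1)
    }
    q
  }
  set.seed(9)
  for (len in c(1, 3, 7, 10)) {
    for (rep in 1:20) {
      p <- runif(len)
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    }
  }
})

test_that("DEG calling is strict at the thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   lfc = c(1.0, 1.01, -1.01, 3),
                   q = c(0.01, 0.01, 0.01, 0.05))
  deg <- call_deg(de)
  expect_equal(deg$up, "b")      # lfc exactly 1 not called; q exactly 0.05 not called
  expect_equal(deg$down, "c")
  expect_equal(call_deg(de[0, ]), list(up = character(0),
                                       down = character(0)))
})

test_that("fixture designed-truth DE table yields 40 up and 6 down", {
  b <- paper_fixture()
  deg <- call_deg(b$truth$de_table)
  expect_length(deg$up, 40L)
  expect_length(deg$down, 6L)
  expect_setequal(deg$up, b$truth$deg_up)
  expect_setequal(deg$down, b$truth$deg_down)
})

test_that("DEG/TAP partition is disjoint and sums to the total", {
  part <- intersect_deg_tap(c("A", "B", "C", "D"), c("A", "C", "X"),
                            c("B", "C", "Y"))
  expect_equal(part$class_I_only, "A")
  expect_equal(part$class_II_only, "B")
  expect_equal(part$both, "C")
  expect_equal(part$total, 3L)
  expect_length(intersect(part$class_I_only, part$class_II_only), 0L)
  empty <- intersect_deg_tap(c("A"), c("X"), c("Y"))
  expect_equal(empty$total, 0L)
})
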