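# Readers, writers, validation and round-trip identity for the pipeline
# file formats.

test_that("ligandome TSV reading validates records and normalizes case", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thla_class\tpeptide\tallele",
               "Pat01\tI\tktiqevagy\t"), f)
  lig <- read_ligandome(f)
  expect_s3_class(lig, "ligandome")
  expect_equal(nrow(lig), 1L)
  expect_equal(lig$peptide, "KTIQEVAGY")

  writeLines(c("sample_id\thla_class\tpeptide\tallele",
               "Pat01\tI\tPEPTIDEB1\t"), f)
  expect_error(read_ligandome(f), "line 2")

  writeLines(c("sample_id\thla_class\tpeptide\tallele",
               "Pat01\tI\tKTIQEXAGY\t"), f)  # X outside the 20-letter alphabet
  expect_error(read_ligandome(f), "ACDEFGHIKLMNPQRSTVWY")
})

test_that("schema violations name the missing column, duplicates fail", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpeptide", "Pat01\tKTIQEVAGY"), f)
  expect_error(read_ligandome(f), "hla_class")

  expect_error(
    ligandome(data.frame(sample_id = c("P1", "P1"), hla_class = "I",
                         peptide = "KTIQEVAGY"), level = "sample"),
    "duplicate")
  # same peptide in two samples is fine at sample level, duplicate at union
  two <- data.frame(sample_id = c("P1", "P2"), hla_class = "I",
                    peptide = "KTIQEVAGY")
  expect_s3_class(ligandome(two, level = "sample"), "ligandome")
  expect_error(ligandome(two, level = "cohort-union"), "duplicate")
})

test_that("PTM annotations are stripped before comparison", {
  expect_equal(normalize_peptides("KTIQ(ox)EVAGY"), "KTIQEVAGY")
  expect_equal(normalize_peptides("ktiqevagy[+16]"), "KTIQEVAGY")
})

test_that("tabular containers round-trip through their writers", {
  dir <- withr::local_tempdir()
  p <- function(f) file.path(dir, f)

  lig <- ligandome(data.frame(sample_id = c("P2", "P1", "P1"),
                              hla_class = c("I", "II", "I"),
                              peptide = c("ACDEFGHIK", "ACDEFGHIKLMNPQ",
                                          "WYVTSRQPN")), level = "sample")
  write_outputs(lig, p("lig.tsv"))
  expect_equal(sort(read_ligandome(p("lig.tsv"))$peptide), sort(lig$peptide))

  atl <- benign_atlas(data.frame(tissue = c("lung", "skin"), hla_class = "I",
                                 peptide = c("ACDEFGHIK", "WYVTSRQPN")))
  write_outputs(atl, p("atlas.tsv"))
  expect_equal(as.data.frame(read_benign_atlas(p("atlas.tsv"))),
               as.data.frame(atl))

  bt <- binding_table(data.frame(peptide = c("ACDEFGHIK", "ACDEFGHIK"),
                                 allele = c("HLA-A02:01", "HLA-B07:02"),
                                 affinity_nM = c(42.5, 5000)))
  write_outputs(bt, p("bind.tsv"))
  rt <- read_binding(p("bind.tsv"))
  expect_equal(rt$affinity_nM, bt$affinity_nM)

  vt <- variant_table(data.frame(patient_id = "P1", gene = "GENEA",
                                 protein_pos = 2L, ref_aa = "C",
                                 alt_aa = "W"))
  write_outputs(vt, p("var.tsv"))
  expect_equal(as.data.frame(read_variants(p("var.tsv"))), as.data.frame(vt))

  cl <- clinical_table(data.frame(patient_id = c("P1", "P2"),
                                  hpv_status = c("positive", "negative"),
                                  uicc_stage = c("II", "IV"),
                                  recurrence = c(FALSE, TRUE),
                                  dfs_time = c(30.5, 12),
                                  dfs_event = c(FALSE, TRUE),
                                  has_serum = c(TRUE, FALSE)))
  write_outputs(cl, p("clin.csv"))
  back <- read_clinical(p("clin.csv"))
  expect_equal(as.data.frame(back), as.data.frame(cl))
  expect_equal(back$stage_group, c("low", "high"))
})

test_that("expression, antibody, APC and panel formats round-trip", {
  dir <- withr::local_tempdir()
  p <- function(f) file.path(dir, f)

  cnt <- matrix(1:12, nrow = 3,
                dimnames = list(c("G1", "G2", "G3"), paste0("S", 1:4)))
  em <- expression_matrix(cnt, c(G1 = 300, G2 = 600, G3 = 900),
                          stats::setNames(c("tumor", "tumor", "healthy_mucosa",
                                            "healthy_mucosa"), paste0("S", 1:4)))
  write_outputs(em, p("counts.tsv"), lengths = p("len.tsv"),
                groups = p("grp.csv"))
  back <- read_expression(p("counts.tsv"), lengths = p("len.tsv"),
                          groups = p("grp.csv"))
  expect_equal(back$counts, em$counts)
  expect_equal(back$gene_lengths, em$gene_lengths)
  expect_equal(back$group, em$group)

  am <- antibody_matrix(matrix(c(10, 20, 100, 12, 22, 110), nrow = 3,
                               dimnames = list(c("AG1", "AG2", "CTL"),
                                               c("P1", "P2"))), "CTL")
  write_outputs(am, p("ab.tsv"), controls = p("ctl.txt"))
  back <- read_antibody(p("ab.tsv"), controls = p("ctl.txt"))
  expect_equal(back$intensities[rownames(am$intensities), ], am$intensities)
  expect_equal(back$positive_controls, "CTL")

  ap <- apc_fractions(matrix(0.25, nrow = 4, ncol = 2,
                             dimnames = list(APC_CELL_TYPES, c("P1", "P2"))))
  write_outputs(ap, p("apc.tsv"))
  expect_equal(unclass(read_apc_fractions(p("apc.tsv")))[APC_CELL_TYPES, ],
               unclass(ap)[APC_CELL_TYPES, ])

  pan <- toy_panel()
  write_outputs(pan, p("panel.fasta"))
  expect_equal(unclass(read_panel_fasta(p("panel.fasta")))[names(pan)],
               unclass(pan))
})

test_that("minimal VCF variants parse via the ANN token", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPat07",
               "chr1\t100\t.\tA\tT\t50\tPASS\tDP=30;ANN=GENEA|p2|C|W\tGT\t0/1"),
             f)
  vt <- read_variants(f)
  expect_equal(vt$patient_id, "Pat07")
  expect_equal(vt$gene, "GENEA")
  expect_equal(vt$protein_pos, 2L)
  expect_equal(vt$alt_aa, "W")
  # reference equal to alternate is rejected
  expect_error(variant_table(data.frame(patient_id = "P", gene = "G",
                                        protein_pos = 1, ref_aa = "A",
                                        alt_aa = "A")),
               "differ")
})

test_that("TAP set writing is sorted and handles the empty set", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tap <- tapconcord:::new_tap_set("I", c("WYVTSRQPN", "ACDEFGHIK"),
                                  list("GENEB", "GENEA"), "TAP")
  write_outputs(tap, f)
  lines <- readLines(f)
  expect_length(lines, 3L)  # header + 2 rows
  expect_match(lines[2], "^ACDEFGHIK")

  empty <- tapconcord:::new_tap_set("I", character(0), list(), "TAP")
  write_outputs(empty, f)
  expect_length(readLines(f), 1L)  # header only
})

test_that("HPV count reading requires all eight genes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tE1\tE2\tE4\tE5\tE6\tE7\tL1",
               "P1\t0\t0\t0\t0\t600\t0\t0"), f)
  expect_error(read_hpv_counts(f), "L2")
})
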