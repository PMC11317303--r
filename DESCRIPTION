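Package: tapconcord
Title: Tumor-Associated HLA Peptide Discovery and Multi-Omics Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of tumor-associated HLA-presented
    peptides (TAP) in oropharyngeal squamous cell carcinoma from comparative
    ligandome profiling. Implements peptide-to-panel mapping, comparative
    profiling against a healthy-tonsil reference with cross-class exclusion,
    benign-tissue atlas filtering to tumor-unique peptides (TAP-U),
    negative-binomial Wald differential expression with TPM computation,
    point-biserial concordance between binary presentation and continuous
    omics layers (TPM, antibody response, antigen-presenting-cell fractions),
    hypergeometric over-representation, neoepitope mutation-motif search,
    HPV status calling from oncogene read counts, binder-restriction counts,
    and Kaplan-Meier/log-rank survival by peptide presentation. Includes a
    parameterized synthetic cohort generator and a deterministic fixture
    whose set sizes mirror a published 40-patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
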