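---
title: "Methods: tumor-associated peptide discovery and multi-omics concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-associated peptide discovery and multi-omics concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapconcord)
```

## The problem

Mass-spectrometry immunopeptidomics yields, per tumor sample, the set of
peptides eluted from HLA class I and class II molecules. Turning such lists
into immunotherapy candidates requires a sequence of set-algebraic and
statistical steps: restriction to a curated antigen panel, subtraction of a
healthy reference ligandome, subtraction of a multi-tissue benign atlas,
and integration with expression, serology, immune-infiltration and clinical
layers. `tapconcord` implements that workflow for an OPSCC-style cohort of
40 tumor patients (22 HPV-positive, 27 with serum), 5 healthy tonsils
(ligandome reference) and 6 healthy mucosa samples (RNA reference).

## Comparative profiling and its one consequential convention

Peptide identity throughout is the bare, upper-cased sequence string;
modification annotations in input are stripped before any comparison, since
MS search engines report modified forms inconsistently across datasets and
the comparisons here are cross-dataset. The alphabet is the 20 proteinogenic
residues; B, J, O, U, X and Z are rejected at the door, and lengths outside
7–30 residues are treated as corrupt input.

A tumor peptide of a given class is a **TAP** when its sequence does not
occur in the healthy-tonsil reference on *either* HLA class. This
cross-class union rule is the single most consequential convention in the
package: class II arithmetic demands it (the tonsil overlap of class II
tumor peptides includes sequences seen on tonsil class I), and we apply the
same rule to class I for consistency. A **TAP-U** is a TAP additionally
absent — again by plain sequence equality over all tissues and both classes
— from the benign atlas; `call_tap_u()` optionally folds the reference
ligandome into that stage, which can never change counts because TAP already
exclude reference sequences.

Peptide-to-gene mapping is exact substring search against the panel
proteome. Exact matching (no I/L folding) is the default because reproducing
deterministic counts requires a single convention; an `il_equivalent` switch
exists for sensitivity analysis, since isoleucine and leucine are isobaric
in MS. Multi-gene peptides are kept and flagged ambiguous, and count toward
every matched gene in gene-level summaries. Collapsing nested length
variants (`collapse_variant_families()`) is reporting-only — greedy,
longest-first, ties alphabetical — and never feeds any count.

## Differential expression

The DE stage is a deliberately transparent two-group negative-binomial Wald
test: median-of-ratios size factors (geometric-mean reference over genes
nonzero in every sample), a pooled within-group method-of-moments dispersion
on normalized counts floored at `1e-8`, a log group-mean ratio with
pseudo-count 0.5 for stability at low counts, and the delta-method standard
error `sqrt((1/mu + alpha)/n)` summed over groups. Shrinkage estimators for
fold changes are intentionally not implemented — they carry trained-prior
machinery that would dominate the code without changing which genes clear
the thresholds in the regimes this package simulates — so fold changes are
reported unshrunk, and where a published shrunk fit is being mirrored the
designed-truth DE table stands in for the fit. Thresholds are read
literally and strictly: up-regulated means `lfc > 1` and BH `q < 0.05`.
With 20-vs-20 groups and dispersion 0.1 the test's empirical type-I rate at
nominal 0.05 sits near 0.06 and designed DEG at |lfc| = 2 are recovered
essentially completely; both properties are asserted by the test suite at
2000 and 500 genes respectively.

## Concordance analyses

Presentation is binary per patient (the MS data are semi-quantitative), so
all cross-layer association uses the point-biserial correlation — computed
from its defining formula, which is algebraically Pearson on the 0/1 coding
— with the exact t reference distribution on `n − 2` degrees of freedom.
Following the emulated analysis, significance is per-test `p < 0.05` with
no multiplicity correction across the correlation matrix; `bh_adjust()` is
available but deliberately not applied there. Degenerate pairs (a peptide
presented by all or no patients of a stratum, or a constant continuous
vector) are flagged not-computable and never turned into numbers.

Antibody arrays are normalized per array as
`log2(intensity) − median(log2(controls))`; the source study names its
positive-control proteins but not its arithmetic, so this log-ratio — which
removes any per-array multiplicative factor exactly — is this package's
documented convention. The serum variance filter retains class II TAP-U
whose presence vector over the serum patients contains both a 0 and a 1 and
whose source gene is on the antibody array. Pathway over-representation is
the upper-tail hypergeometric with BH across pathways, significant at
`p < 0.05` and `q < 0.1` jointly.

## Neoepitope search and clinical endpoints

Missense variants (the only variant class supported; the motif search is
defined at single-residue granularity) are applied to panel proteins with
reference-residue checking, and all windows of 8–12 residues (class I) and
12–25 (class II) covering the variant position are searched against the
ligandome by exact match. The window ranges are standard immunopeptidomics
conventions and configurable, since no published values constrain them.

HPV status is positive iff E6 ≥ 500 reads, E7 ≥ 500 reads, or the eight
oncogenes sum to ≥ 500; the thresholds are inclusive and the calling is
monotone in every count. Survival uses the product-limit estimator and the
1-df two-group log-rank test, both re-implemented and cross-checked in the
tests against the `survival` package on random data. Censoring tied with an
event time is processed after the events at that time (the standard
convention; the source is silent). Binder restriction counts distinct TAP-U
per allele at predicted affinity ≤ 500 nM, inclusive.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws: NB counts (default means log-uniform on
50–2000, dispersion 0.1) with designed DEG at ±`deg_lfc` (default 2, in
log2); one class I 9-mer and one class II 15-mer per panel gene, presented
per patient with probability `plogis(qlogis(0.3) +
presentation_coupling * z(log TPM))`; antibody log2-intensities Normal(10,
1) shifted by `antibody_coupling` when the gene is presented on class II;
Dirichlet APC fractions; exponential DFS (median ≈ 25 months) with an
optional hazard ratio on presenting the designated peptide; and HPV read
counts built so exactly `n_hpv_pos` patients pass the calling rule. With
all couplings at zero the significant-correlation rate is 5% — asserted
over 20 seeds — so the pipeline's false-positive behavior is calibrated.

`build_paper_mirror_fixture()` is different in kind: every set size is
engineered by explicit construction (peptides chosen as substrings of
chosen panel proteins, categories assigned to disjoint gene pools), never
by rejection on counts, so the profiling arithmetic
(223 − 40 = 183, 102 − 8 = 94, 183 − 110 = 73, 94 − 32 = 62, 16 + 4 + 6 =
26, 33 peptides from 23 array genes) holds exactly and deterministically.
The gene lengths used for TPM are 3× protein length in nucleotides, a
deterministic convention. The fixture's union peptides are spread over
patients uniformly at random under the build seed; per-sample counts are
not constrained by any published value, and none of the engineered results
depend on them.

Neither generator emulates: MS spectra or identification error, read-level
sequencing data, HLA allele frequencies, shared peptides between unrelated
proteins (panel proteins are i.i.d. random, so multi-mapping is absent by
construction rather than rare), or biologically structured correlation
between layers beyond the explicit couplings. Green tests on synthetic data
therefore certify the *arithmetic and statistical machinery*, not the
biology of any real cohort: real ligandomes will multi-map, carry
modifications, and violate the NB and exponential conveniences in ways the
generator does not.

## Problem sizes and numerical choices

The test suite runs the fixture (312 genes, ~600 distinct peptides, 40 + 5
+ 6 samples) in under a second and the stochastic suites at 200–2000 genes
and 20 seeds, keeping the full suite in well under two minutes on one CPU —
sizes chosen as the smallest at which the asserted rates are stable.
Dispersion floor `1e-8`, pseudo-count 0.5, ratio clamping of point-biserial
r to [−1, 1], and p = 0 at |r| = 1 are the only numerical guards; all
ranking ties anywhere in the package break alphabetically so output is
reproducible byte for byte.

## Known limitations

Multi-gene peptides count toward every gene, which can inflate gene-level
tallies on real panels with homologous members; the DE stage supports only
a two-group design with unshrunk fold changes; the neoepitope module
ignores indels and frameshifts; and the log-rank test is unstratified with
1 df. These match the scope of the workflow the package implements.
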