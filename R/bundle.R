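## Emit a cohort bundle as the full on-disk file set (cohort_io formats)
## plus a designed-truth JSON record.

#' Write a cohort bundle to a directory
#'
#' Emits every layer of the bundle in its pipeline file format:
#' `panel.fasta`, `tumor_ligands.tsv` (sample level), `ht_ligands.tsv`
#' (when present), `atlas.tsv`, `counts.tsv`/`gene_lengths.tsv`/
#' `groups.csv`, `antibody.tsv`/`controls.txt`, `apc.tsv`, `binding.tsv`
#' (when present), `variants.tsv` (when present), `clinical.csv`,
#' `hpv_counts.tsv`, and `truth.json`. Writing is deterministic, so two
#' builds of the same bundle produce byte-identical directories.
#'
#' @param bundle a `"cohort_bundle"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_outputs(bundle$panel, p("panel.fasta"))
  write_outputs(bundle$tumor_ligandome_sample, p("tumor_ligands.tsv"))
  if (!is.null(bundle$ht_ligandome))
    write_outputs(bundle$ht_ligandome, p("ht_ligands.tsv"))
  if (!is.null(bundle$atlas))
    write_outputs(bundle$atlas, p("atlas.tsv"))
  write_outputs(bundle$expression, p("counts.tsv"),
                lengths = p("gene_lengths.tsv"), groups = p("groups.csv"))
  write_outputs(bundle$antibody, p("antibody.tsv"),
                controls = p("controls.txt"))
  write_outputs(bundle$apc, p("apc.tsv"))
  if (!is.null(bundle$binding))
    write_outputs(bundle$binding, p("binding.tsv"))
  if (!is.null(bundle$variants))
    write_outputs(bundle$variants, p("variants.tsv"))
  write_outputs(bundle$clinical, p("clinical.csv"))
  write_outputs(bundle$hpv_counts, p("hpv_counts.tsv"))
  truth <- bundle$truth
  truth$presence <- NULL  # per-peptide presenter lists stay in-memory only
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(dir)
}

#' Read a written cohort bundle back from a directory
#'
#' Counterpart of [write_cohort_bundle()]; files that were not written
#' (binding, variants, tonsil ligandome, atlas) are returned as `NULL`.
#'
#' @param dir directory produced by [write_cohort_bundle()].
#' @return a `"cohort_bundle"` list (without the in-memory truth record;
#'   the JSON truth is attached as `$truth`).
#' @export
read_cohort_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  opt <- function(f, reader, ...) {
    if (file.exists(p(f))) reader(p(f), ...) else NULL
  }
  sample_lig <- read_ligandome(p("tumor_ligands.tsv"), level = "sample")
  structure(list(
    panel = read_panel_fasta(p("panel.fasta")),
    tumor_ligandome_sample = sample_lig,
    tumor_ligandome_union = as_cohort_union(sample_lig),
    ht_ligandome = opt("ht_ligands.tsv", read_ligandome, level = "sample"),
    atlas = opt("atlas.tsv", read_benign_atlas),
    expression = read_expression(p("counts.tsv"),
                                 lengths = p("gene_lengths.tsv"),
                                 groups = p("groups.csv")),
    antibody = read_antibody(p("antibody.tsv"), controls = p("controls.txt")),
    apc = read_apc_fractions(p("apc.tsv")),
    binding = opt("binding.tsv", read_binding),
    variants = opt("variants.tsv", read_variants),
    clinical = read_clinical(p("clinical.csv")),
    hpv_counts = read_hpv_counts(p("hpv_counts.tsv")),
    truth = if (file.exists(p("truth.json")))
      jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL),
    class = "cohort_bundle")
}
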