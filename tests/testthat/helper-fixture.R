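# Shared fixtures, built once per test run.

paper_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_paper_mirror_fixture()
    cache
  }
})

# Full profiling pipeline on the paper-mirror fixture, cached.
fixture_profile <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    b <- paper_fixture()
    idx <- build_proteome_index(b$panel)
    union_lig <- b$tumor_ligandome_union
    mapping <- map_peptides(union_lig$peptide, idx)
    filt <- filter_to_panel(union_lig, mapping)
    ht_union <- as_cohort_union(b$ht_ligandome)
    ht <- filter_to_panel(ht_union, map_peptides(ht_union$peptide, idx))
    tap1 <- call_tap(filt, ht, "I", mapping)
    tap2 <- call_tap(filt, ht, "II", mapping)
    tapu1 <- call_tap_u(tap1, b$atlas, reference = ht)
    tapu2 <- call_tap_u(tap2, b$atlas, reference = ht)
    cache <<- list(bundle = b, index = idx, mapping = mapping,
                   mapped_union = filt, ht = ht,
                   tap1 = tap1, tap2 = tap2, tapu1 = tapu1, tapu2 = tapu2)
    cache
  }
})

# A tiny hand-built panel used across IO and mapping tests.
toy_panel <- function() {
  structure(c(GENEA = "ACDEFGHIKLMNPQRSTVWY",
              GENEB = "WYVTSRQPNMLKIHGFEDCA"),
            class = "panel_proteome")
}
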