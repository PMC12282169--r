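# Fixtures are generated in code at test time; nothing is read from disk.
# The standard learning panel (the package's default synthetic study
# conditions) is expensive, so it is built once per test run and shared.

.fixture_cache <- new.env(parent = emptyenv())

# 8 samples at the default fixture scale: samples 1-7 are the learning set,
# sample 8 is held out for depletion evaluation.
standard_learning_set <- function() {
  if (is.null(.fixture_cache$ls)) {
    .fixture_cache$ls <- make_learning_set(n_samples = 8, seed = 20250601)
  }
  .fixture_cache$ls
}

# The rRNA-binning + coverage + region-extraction chain for one simulated
# sample, using truth categories (error-free reads) as the rRNA bin.
sample_rrna_regions <- function(sim, rrna_refs, min_depth) {
  rrna_ids <- sim$truth$read_id[sim$truth$category == "rRNA"]
  aln <- sim$alignments[sim$alignments$read_id %in% rrna_ids, , drop = FALSE]
  extract_regions(
    compute_coverage(aln, rrna_refs), rrna_refs,
    min_depth = min_depth, sample_id = sim$sample_id
  )
}

learning_set_rrna_refs <- function(ls) {
  refs <- ls$references
  refs[refs$category == "rRNA", c("ref_id", "sequence")]
}

# Per-sample abundant regions of the standard panel at the synthetic-scale
# depth threshold (50x; abundant taxa sit at ~180-700x, rare at ~4x).
standard_regions <- function(samples = 1:7) {
  key <- paste0("regs_", paste(samples, collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    ls <- standard_learning_set()
    refs <- learning_set_rrna_refs(ls)
    .fixture_cache[[key]] <- lapply(
      ls$samples[samples], sample_rrna_regions, rrna_refs = refs, min_depth = 50
    )
  }
  .fixture_cache[[key]]
}

# Minimal read tibble with uniform quality q.
make_reads <- function(seqs, q = 35, ids = sprintf("r%d", seq_along(seqs))) {
  tibble::tibble(
    read_id = ids,
    sequence = seqs,
    qualities = lapply(nchar(seqs), function(n) rep(as.integer(q), n))
  )
}

# Region tibble from explicit sequences (start at 0 on a synthetic ref).
make_regions <- function(seqs, sample_id = "s1", ref_ids = sprintf("ref%d", seq_along(seqs)),
                         median_depth = rev(seq_along(seqs)) * 100) {
  tibble::tibble(
    ref_id = ref_ids,
    start = 0L,
    end = nchar(seqs),
    sequence = seqs,
    median_depth = median_depth,
    sample_id = sample_id
  )
}
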