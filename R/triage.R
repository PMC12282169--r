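# Read triage: length/quality filtering, downsampling, and k-mer containment
# classification of reads into rRNA / host / retained bins. The k-mer
# classifier plays the role that an aligner-based rRNA screen (against an
# SSU/LSU reference database) plays in a production pipeline: it is exactly
# specified and therefore exactly testable.

#' Filter reads by length and mean quality
#'
#' A read is kept iff its length is at least `min_length` and its mean
#' per-base Phred score is at least `min_mean_quality` (the classic
#' "50 bases / Q20" triage rule). Order is preserved and the operation is
#' idempotent.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `qualities`).
#' @param min_length Minimum read length in bases (default 50).
#' @param min_mean_quality Minimum mean Phred score (default 20).
#' @return The kept reads, with the number of removed reads in attribute
#'   `n_removed`.
#' @export
quality_filter <- function(reads, min_length = 50, min_mean_quality = 20) {
  assert_reads(reads)
  if (min_length < 1) abort("min_length must be >= 1")
  if (min_mean_quality < 0) abort("min_mean_quality must be >= 0")
  if (nrow(reads) == 0) {
    return(structure(reads, n_removed = 0L))
  }
  len_ok <- nchar(reads$sequence) >= min_length
  mean_q <- vapply(reads$qualities, function(q) mean(as.numeric(q)), numeric(1))
  keep <- len_ok & mean_q >= min_mean_quality
  structure(reads[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Downsample reads to a fixed number
#'
#' Uniform random subset of exactly `n` reads (all reads if `n` exceeds the
#' input size), reproducible for a fixed seed. Relative input order is
#' preserved.
#'
#' @param reads Read tibble.
#' @param n Target number of reads.
#' @param seed Integer seed.
#' @return A read tibble with `min(n, nrow(reads))` rows.
#' @export
downsample_reads <- function(reads, n, seed) {
  if (n < 0) abort("n must be non-negative")
  if (n >= nrow(reads)) return(reads)
  idx <- withr::with_seed(seed, sort(sample.int(nrow(reads), n)))
  reads[idx, , drop = FALSE]
}

#' Build a canonical k-mer index from reference sequences
#'
#' Stores the canonical form (lexicographic min of a k-mer and its reverse
#' complement) of every length-`k` substring of every reference. K-mers
#' containing `N` are skipped.
#'
#' @param refs Reference tibble (`ref_id`, `sequence`).
#' @param k K-mer length (default 21).
#' @param label Category label the index votes for (e.g. `"rRNA"`, `"host"`).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(refs, k = 21, label = "rRNA") {
  assert_refs(refs)
  if (k < 1) abort("k must be >= 1")
  kmers <- unlist(lapply(refs$sequence, seq_kmers, k = k), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  kmers <- unique(canonical_kmer(unique(kmers)))
  structure(list(k = as.integer(k), kmers = kmers, label = label), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> label=%s k=%d distinct canonical k-mers=%d\n",
              x$label, x$k, length(x$kmers)))
  invisible(x)
}

#' Classify reads by k-mer containment
#'
#' Indexes are checked in the given priority order; a read takes the label of
#' the first index for which the fraction of its (N-free, canonical) k-mers
#' found in the index reaches `min_hit_fraction`. Reads matching no index —
#' including reads shorter than `k` — are labelled `"retained"`.
#'
#' @param reads Read tibble.
#' @param indexes A `kmer_index` or list of them, highest priority first
#'   (conventionally rRNA before host). All must share the same `k`.
#' @param min_hit_fraction Minimum fraction of a read's k-mers that must match
#'   (default 0.25).
#' @return Tibble `read_id`, `category`.
#' @export
classify_reads <- function(reads, indexes, min_hit_fraction = 0.25) {
  assert_reads(reads)
  if (inherits(indexes, "kmer_index")) indexes <- list(indexes)
  ks <- vapply(indexes, function(ix) ix$k, integer(1))
  if (length(unique(ks)) != 1) abort("all k-mer indexes must share the same k")
  k <- ks[1]
  n_reads <- nrow(reads)
  category <- rep("retained", n_reads)
  if (n_reads == 0) return(tibble(read_id = character(0), category = character(0)))
  too_short <- nchar(reads$sequence) < k
  if (any(too_short)) {
    warn(sprintf("%d read(s) shorter than k=%d labelled 'retained'", sum(too_short), k))
  }
  # Explode all k-mers of a chunk of reads in one vectorised substring() call,
  # canonicalise, and tally hits per read and index.
  chunk_size <- 2000L
  idx_all <- which(!too_short)
  for (chunk in split(idx_all, ceiling(seq_along(idx_all) / chunk_size))) {
    seqs <- reads$sequence[chunk]
    nk <- nchar(seqs) - k + 1L
    owner <- rep(seq_along(chunk), nk)
    starts <- sequence(nk)
    kmers <- substring(rep(seqs, nk), starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    kmers <- canonical_kmer(kmers[ok])
    owner <- owner[ok]
    denom <- tabulate(owner, nbins = length(chunk))
    assigned <- rep(FALSE, length(chunk))
    for (ix in indexes) {
      hits <- tabulate(owner[kmers %in% ix$kmers], nbins = length(chunk))
      frac <- ifelse(denom > 0, hits / denom, 0)
      take <- !assigned & frac >= min_hit_fraction
      category[chunk[take]] <- ix$label
      assigned <- assigned | take
    }
  }
  tibble(read_id = reads$read_id, category = category)
}

#' Per-sample read partition report
#'
#' Tallies reads per category (`rRNA`, `host`, `retained`) with fractions of
#' the classified total. The retained fraction is the proportion of reads that
#' are neither rRNA nor host, i.e. usable for metatranscriptome analysis.
#'
#' @param classified Tibble with a `category` column (e.g. from
#'   [classify_reads()]), or a character vector of categories.
#' @param sample_id Sample label recorded in the report.
#' @return Tibble `sample_id`, `category`, `n`, `fraction` with one row per
#'   category (fractions are `NA` for an empty input, flagged by a warning).
#' @export
partition_report <- function(classified, sample_id) {
  cats <- if (is.data.frame(classified)) classified$category else as.character(classified)
  levels <- c("rRNA", "host", "retained")
  if (!all(cats %in% levels)) {
    abort(sprintf("categories must be drawn from {%s}", paste(levels, collapse = ", ")))
  }
  n <- vapply(levels, function(l) sum(cats == l), integer(1))
  total <- sum(n)
  if (total == 0) {
    warn(sprintf("sample %s has no classified reads; fractions undefined", sample_id))
    frac <- rep(NA_real_, length(levels))
  } else {
    frac <- n / total
  }
  tibble(sample_id = sample_id, category = levels, n = unname(n), fraction = unname(frac))
}

#' Select learning-set samples by rRNA burden
#'
#' Returns the samples whose rRNA read fraction strictly exceeds
#' `min_rrna_frac` (default 0.30, the threshold used to pick high-burden
#' donors as a probe-design learning set), in descending rRNA-fraction order.
#'
#' @param reports A partition report tibble, typically `bind_rows()` of
#'   [partition_report()] outputs across samples.
#' @param min_rrna_frac Strict lower bound on the rRNA fraction.
#' @return Character vector of sample ids.
#' @export
select_learning_samples <- function(reports, min_rrna_frac = 0.30) {
  sel <- reports |>
    filter(.data$category == "rRNA", .data$fraction > min_rrna_frac) |>
    arrange(desc(.data$fraction))
  if (nrow(sel) == 0) warn("no sample exceeds the rRNA-fraction threshold")
  sel$sample_id
}
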