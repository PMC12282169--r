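# In-silico assessment of a probe set: simulated depletion by interval
# overlap, partition accounting before/after, diversity of the residual
# taxa, and generic profile normalisation/correlation utilities.

#' Simulate probe depletion by interval overlap
#'
#' A read is depleted iff any of its alignment intervals overlaps any probe
#' target interval on the same reference by at least `min_overlap` bases.
#' This is a transparent hybridisation surrogate — no thermodynamics or
#' mismatch model — with `min_overlap` defaulting to half a probe (25 nt).
#' Reads with no alignment are never depleted.
#'
#' @param alignments Alignment tibble (0-based half-open intervals).
#' @param categories Tibble `read_id`, `category` (or a named character
#'   vector) covering the reads being accounted.
#' @param probes A `probe_set` or probe tibble with `ref_id`,
#'   `target_start`, `target_end`.
#' @param min_overlap Minimum overlap in bases (default 25).
#' @return A `depletion_report`: per-category before/after counts, summary
#'   fractions, and the depleted read ids. Supports [tidy()] and [glance()].
#' @export
insilico_depletion <- function(alignments, categories, probes, min_overlap = 25) {
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  if (inherits(probes, "probe_set")) probes <- probes$probes
  if (!is.data.frame(categories)) {
    categories <- tibble(read_id = names(categories), category = unname(categories))
  }
  depleted_ids <- character(0)
  if (nrow(probes) > 0 && nrow(alignments) > 0) {
    for (rid in intersect(unique(alignments$ref_id), unique(probes$ref_id))) {
      a <- alignments[alignments$ref_id == rid, , drop = FALSE]
      p <- probes[probes$ref_id == rid, , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = a$ref_start + 1L, end = a$ref_end),
        IRanges::IRanges(start = p$target_start + 1L, end = p$target_end),
        minoverlap = min_overlap
      )
      depleted_ids <- c(depleted_ids, a$read_id[unique(S4Vectors::queryHits(hits))])
    }
  }
  depleted_ids <- unique(depleted_ids)
  is_depleted <- categories$read_id %in% depleted_ids
  levels <- c("rRNA", "host", "retained")
  before <- vapply(levels, function(l) sum(categories$category == l), integer(1))
  after <- vapply(levels, function(l) sum(categories$category == l & !is_depleted), integer(1))
  total_before <- sum(before)
  total_after <- sum(after)
  summary <- tibble(
    depleted_read_count = sum(is_depleted),
    rrna_fraction_before = if (total_before > 0) before[["rRNA"]] / total_before else NA_real_,
    rrna_fraction_after = if (total_after > 0) after[["rRNA"]] / total_after else NA_real_,
    retained_fraction_before = if (total_before > 0) before[["retained"]] / total_before else NA_real_,
    retained_fraction_after = if (total_after > 0) after[["retained"]] / total_after else NA_real_
  )
  structure(
    list(
      by_category = tibble(category = levels, before = unname(before), after = unname(after)),
      summary = summary,
      depleted_read_ids = categories$read_id[is_depleted],
      min_overlap = min_overlap
    ),
    class = "depletion_report"
  )
}

#' @export
print.depletion_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<depletion_report> %d reads depleted; rRNA %.3f -> %.3f; retained %.3f -> %.3f (min_overlap %d)\n",
    s$depleted_read_count, s$rrna_fraction_before, s$rrna_fraction_after,
    s$retained_fraction_before, s$retained_fraction_after, x$min_overlap
  ))
  invisible(x)
}

#' @describeIn insilico_depletion Per-category before/after counts.
#' @param x A `depletion_report`.
#' @param ... Unused.
#' @export
tidy.depletion_report <- function(x, ...) x$by_category

#' @describeIn insilico_depletion One-row summary of fractions and counts.
#' @export
glance.depletion_report <- function(x, ...) x$summary

#' Fraction of truth-region bases inside the designed footprint
#'
#' Measures how much of a set of ground-truth abundant intervals the design
#' reached. With `mode = "footprint"` (default) each tiled region contributes
#' the span from its first probe's start to its last probe's end — the
#' "did the design miss abundant sequence" question; inter-probe gaps are
#' deliberate spacing, not misses. With `mode = "target"` only the exact
#' probe target intervals count (bounded above by
#' `probe_length / (probe_length + gap)` for interior bases, by
#' construction).
#'
#' @param probes A `probe_set` or probe tibble with provenance columns.
#' @param truth_regions Tibble `ref_id`, `start`, `end` of ground-truth
#'   abundant intervals (0-based half-open).
#' @param mode `"footprint"` or `"target"`.
#' @return Proportion of truth bases covered, in \[0, 1\].
#' @export
probe_footprint_coverage <- function(probes, truth_regions, mode = c("footprint", "target")) {
  mode <- match.arg(mode)
  if (inherits(probes, "probe_set")) probes <- probes$probes
  total <- sum(truth_regions$end - truth_regions$start)
  if (total == 0) abort("truth_regions is empty")
  if (nrow(probes) == 0) return(0)
  if (mode == "footprint") {
    spans <- probes |>
      group_by(.data$ref_id, .data$region_start, .data$region_end) |>
      summarise(
        start = min(.data$target_start), end = max(.data$target_end), .groups = "drop"
      )
  } else {
    spans <- tibble(ref_id = probes$ref_id, start = probes$target_start, end = probes$target_end)
  }
  covered <- 0
  for (rid in unique(truth_regions$ref_id)) {
    tr <- truth_regions[truth_regions$ref_id == rid, , drop = FALSE]
    sp <- spans[spans$ref_id == rid, , drop = FALSE]
    if (nrow(sp) == 0) next
    covered <- covered + sum(IRanges::width(IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(start = tr$start + 1L, end = tr$end)),
      IRanges::reduce(IRanges::IRanges(start = sp$start + 1L, end = sp$end))
    )))
  }
  covered / total
}

#' Shannon diversity of a taxonomic profile
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive count, natural log,
#' with `p_i` the count proportions. Computed via [vegan::diversity()].
#'
#' @param profile Named numeric vector of counts, or a tibble with columns
#'   `taxon` and `count`.
#' @return Shannon index (dimensionless, natural log).
#' @export
#' @examples
#' shannon_index(c(a = 10, b = 10, c = 10, d = 10))  # ln 4
shannon_index <- function(profile) {
  counts <- if (is.data.frame(profile)) profile$count else as.numeric(profile)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (sum(counts) <= 0) abort("profile has zero total count")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Total-sum-scaling normalisation
#'
#' Divides each sample column by its own sum so every column totals 1
#' (relative abundances), controlling for sequencing-depth differences.
#' Idempotent and scale-invariant.
#'
#' @param table Feature-by-sample numeric matrix or data frame of
#'   non-negative abundances.
#' @return Object of the same shape with unit column sums.
#' @export
tss_normalize <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) abort("abundance table must be numeric")
  if (any(m < 0)) abort("abundance table must be non-negative")
  totals <- colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[which(totals == 0)[1]] %||% as.character(which(totals == 0)[1])
    abort(sprintf("sample %s has zero total abundance", bad))
  }
  out <- sweep(m, 2, totals, "/")
  if (is.data.frame(table)) as.data.frame(out) else out
}

#' Correlate two abundance profiles
#'
#' Spearman rank correlation (average ranks for ties) or Pearson linear
#' correlation of paired feature vectors, as used to compare gene-family
#' profiles between depletion conditions.
#'
#' @param a,b Numeric vectors over the same features (length >= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation in \[-1, 1\].
#' @export
compare_profiles <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) abort("profiles must have equal feature sets")
  if (length(a) < 3) abort("need at least 3 features")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("correlation undefined for a constant profile")
  }
  cor(a, b, method = method)
}
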