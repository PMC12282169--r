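# Per-base coverage pileup and extraction of contiguous high-depth
# ("abundant") regions, the templates for probe design. Every alignment
# record contributes its full span; multi-mapping policy is whatever the
# upstream aligner emitted.

#' Compute per-base coverage from alignment records
#'
#' @param alignments Alignment tibble (`read_id`, `ref_id`, `ref_start`,
#'   `ref_end`; 0-based half-open).
#' @param refs Reference tibble (`ref_id`, `sequence`).
#' @return Tibble `ref_id`, `length`, `depth` with one row per reference;
#'   `depth` is a list-column of integer vectors (`depth[[i]][p]` is the
#'   number of alignments covering 0-based position `p - 1`). References with
#'   no alignments get an all-zero track.
#' @export
compute_coverage <- function(alignments, refs) {
  assert_refs(refs)
  ref_len <- setNames(nchar(refs$sequence), refs$ref_id)
  unknown <- setdiff(unique(alignments$ref_id), refs$ref_id)
  if (length(unknown)) {
    abort(sprintf("alignment to unknown reference: %s", unknown[1]))
  }
  oob <- alignments$ref_end > ref_len[alignments$ref_id] | alignments$ref_start < 0
  if (any(oob)) {
    abort(sprintf("alignment interval out of bounds on %s", alignments$ref_id[which(oob)[1]]))
  }
  depth <- lapply(refs$ref_id, function(rid) {
    a <- alignments[alignments$ref_id == rid, , drop = FALSE]
    if (nrow(a) == 0) return(integer(ref_len[[rid]]))
    cov <- IRanges::coverage(
      IRanges::IRanges(start = a$ref_start + 1L, end = a$ref_end),
      width = ref_len[[rid]]
    )
    as.integer(cov)
  })
  tibble(ref_id = refs$ref_id, length = unname(ref_len), depth = depth)
}

#' Extract contiguous high-depth regions from coverage tracks
#'
#' Finds maximal runs of positions with depth strictly greater than
#' `min_depth` (the ">500x" rule at production scale), merges runs separated
#' by at most `merge_gap` positions, drops merged runs shorter than
#' `min_region_length`, and annotates each surviving region with its
#' sense-strand sequence and the median depth over its own positions.
#'
#' @param coverage Coverage tibble from [compute_coverage()].
#' @param refs Reference tibble supplying region sequences.
#' @param min_depth Strict depth threshold (default 500).
#' @param merge_gap Maximum below-threshold gap bridged when merging
#'   (default 0: any dip splits).
#' @param min_region_length Minimum region length in bases; defaults to 50 so
#'   every region can hold at least one probe.
#' @param sample_id Sample label carried on each region.
#' @return Region tibble `ref_id`, `start`, `end`, `sequence`,
#'   `median_depth`, `sample_id`, disjoint and sorted within each reference.
#' @export
extract_regions <- function(coverage, refs, min_depth = 500, merge_gap = 0,
                            min_region_length = 50, sample_id = "sample") {
  assert_refs(refs)
  ref_seq <- setNames(refs$sequence, refs$ref_id)
  out <- purrr::map2(coverage$ref_id, coverage$depth, function(rid, depth) {
    above <- depth > min_depth
    if (!any(above)) return(NULL)
    runs <- as(S4Vectors::Rle(above), "IRanges")  # ranges of TRUE runs
    merged <- IRanges::reduce(runs, min.gapwidth = merge_gap + 1L)
    merged <- merged[IRanges::width(merged) >= min_region_length]
    if (length(merged) == 0) return(NULL)
    start0 <- IRanges::start(merged) - 1L
    end0 <- IRanges::end(merged)
    tibble(
      ref_id = rid,
      start = start0,
      end = end0,
      sequence = substring(ref_seq[[rid]], start0 + 1L, end0),
      median_depth = purrr::map2_dbl(start0, end0, function(s, e) median(depth[(s + 1L):e])),
      sample_id = sample_id
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(
      ref_id = character(0), start = integer(0), end = integer(0),
      sequence = character(0), median_depth = numeric(0), sample_id = character(0)
    ))
  }
  arrange(res, .data$ref_id, .data$start)
}

#' Depth order statistics over regions
#'
#' @param regions Region tibble (`ref_id`, `start`, `end`).
#' @param coverage Coverage tibble from [compute_coverage()].
#' @return `regions` with `median_depth`, `mean_depth`, `max_depth` columns
#'   (exact order statistics; the median of an even-length window is the mean
#'   of its two central values).
#' @export
region_depth_stats <- function(regions, coverage) {
  if (any(regions$end <= regions$start)) abort("empty region interval")
  depth_by_ref <- setNames(coverage$depth, coverage$ref_id)
  stats <- purrr::pmap(
    list(regions$ref_id, regions$start, regions$end),
    function(rid, s, e) {
      d <- depth_by_ref[[rid]]
      if (is.null(d) || e > length(d)) abort(sprintf("region out of track bounds on %s", rid))
      w <- d[(s + 1L):e]
      tibble(median_depth = median(w), mean_depth = mean(w), max_depth = max(w))
    }
  )
  dplyr::bind_cols(
    regions[setdiff(names(regions), c("median_depth", "mean_depth", "max_depth"))],
    bind_rows(stats)
  )
}
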