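test_that("ranking keeps the top N by median depth with deterministic ties", {
  regions <- make_regions(
    replicate(3, random_dna_str(100)),
    ref_ids = c("a", "b", "c"), median_depth = c(900, 700, 800)
  )
  top2 <- rank_and_select(regions, 2)
  expect_equal(top2$median_depth, c(900, 800))
  expect_equal(nrow(rank_and_select(regions, 10)), 3)
  expect_error(rank_and_select(regions, 0), "top_n")

  # random regions with ties equal a full-sort-then-slice oracle
  set.seed(31)
  big <- make_regions(
    replicate(100, random_dna_str(60)),
    ref_ids = sprintf("ref%03d", sample(100)),
    median_depth = sample(1:20, 100, replace = TRUE)
  )
  for (top_n in c(1, 7, 50, 100)) {
    got <- rank_and_select(big, top_n)
    ord <- order(-big$median_depth, big$ref_id, big$start)
    want <- big[ord[seq_len(min(top_n, 100))], ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("pooling concatenates selections preserving provenance", {
  sel <- lapply(1:7, function(s) {
    make_regions(replicate(20, random_dna_str(60)), sample_id = sprintf("s%d", s),
                 ref_ids = sprintf("s%d_ref%d", s, 1:20))
  })
  pooled <- pool_samples(sel)
  expect_equal(nrow(pooled), 140)
  expect_equal(sort(pooled$ref_id), sort(unlist(lapply(sel, `[[`, "ref_id"))))
  sel[[3]] <- sel[[3]][0, ]
  expect_equal(nrow(pool_samples(sel)), 120)
})

test_that("pairwise identity matches the pinned global-alignment scoring", {
  s <- random_dna_str(100)
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_error(pairwise_identity("", "ACGT"), "nonempty")

  set.seed(32)
  for (i in 1:10) {
    a <- random_dna_str(150)
    b <- mutate_sequence(a, 0.10, seed = 1000 + i)
    got <- pairwise_identity(a, b)
    want <- oracle_global_alignment(a, b)
    expect_equal(got, want$identity, tolerance = 1e-12)
    expect_equal(pairwise_identity(b, a), got)  # symmetric
  }
})

test_that("redundancy collapse keeps one region per identity component", {
  set.seed(33)
  s <- random_dna_str(80)
  two_same <- make_regions(c(s, s), ref_ids = c("x", "y"))
  expect_equal(nrow(deduplicate_regions(two_same, seed = 4)), 1)

  a <- random_dna_str(80)
  ab <- mutate_sequence(a, 0.10, seed = 9)   # ~90% identity with a
  c_ <- random_dna_str(80)
  trio <- make_regions(c(a, ab, c_), ref_ids = c("a", "b", "c"))
  kept <- deduplicate_regions(trio, identity_threshold = 0.80, seed = 2)
  expect_equal(nrow(kept), 2)
  expect_true("c" %in% kept$ref_id)
})

test_that("collapse equals an all-pairs union-find oracle and is seed-deterministic", {
  set.seed(34)
  for (rep in 1:25) {
    n_base <- sample(3:6, 1)
    bases <- replicate(n_base, random_dna_str(70))
    seqs <- unlist(lapply(bases, function(b) {
      n_copy <- sample(1:3, 1)
      c(b, vapply(seq_len(n_copy - 1), function(j) {
        mutate_sequence(b, runif(1, 0.02, 0.12), seed = sample.int(1e6, 1))
      }, character(1)))
    }))
    seqs <- sample(seqs)
    regions <- make_regions(seqs, ref_ids = sprintf("r%02d", seq_along(seqs)))
    n <- nrow(regions)
    pairs <- t(utils::combn(n, 2))
    idents <- apply(pairs, 1, function(p) {
      oracle_global_alignment(seqs[p[1]], seqs[p[2]])$identity
    })
    edges <- pairs[idents >= 0.80, , drop = FALSE]
    want_n <- oracle_component_count(n, edges)
    kept <- deduplicate_regions(regions, identity_threshold = 0.80, seed = 77)
    expect_equal(nrow(kept), want_n)
    # no retained pair is redundant
    if (nrow(kept) > 1) {
      kp <- t(utils::combn(nrow(kept), 2))
      ki <- apply(kp, 1, function(p) pairwise_identity(kept$sequence[p[1]], kept$sequence[p[2]]))
      expect_true(all(ki < 0.80))
    }
    # deterministic per seed; output preserves input order
    expect_equal(kept, deduplicate_regions(regions, 0.80, seed = 77))
    expect_equal(kept$ref_id, regions$ref_id[regions$ref_id %in% kept$ref_id])
  }
})

test_that("probe tiling follows the stride formula and reverse-complements targets", {
  r150 <- make_regions(random_dna_str(150), ref_ids = "refA")
  p <- tile_probes(r150, probe_length = 50, gap = 50)
  expect_equal(nrow(p), 2)
  expect_equal(p$target_start, c(0L, 100L))
  expect_equal(p$target_end, c(50L, 150L))

  expect_equal(nrow(tile_probes(make_regions(random_dna_str(49)), 50, 25)), 0)

  p500 <- tile_probes(make_regions(random_dna_str(500), ref_ids = "refB"), 50, 25)
  expect_equal(nrow(p500), 7)
  # brute-force placement loop
  pos <- c()
  at <- 0
  while (at + 50 <= 500) {
    pos <- c(pos, at)
    at <- at + 75
  }
  expect_equal(p500$target_start, as.integer(pos))

  toy <- make_regions("AACG", ref_ids = "t")
  expect_equal(tile_probes(toy, probe_length = 4, gap = 10)$sequence, "CGTT")
  expect_error(tile_probes(toy, probe_length = 0, gap = 5), "probe_length")
})

test_that("tiling satisfies spacing, bounds and antisense invariants", {
  set.seed(35)
  for (i in 1:30) {
    L <- sample(40:900, 1)
    g <- sample(c(0, 25, 30, 50), 1)
    start0 <- sample(0:50, 1)
    seq <- random_dna_str(L)
    region <- tibble::tibble(
      ref_id = "ref", start = start0, end = start0 + L, sequence = seq,
      median_depth = 100, sample_id = "s"
    )
    p <- tile_probes(region, 50, g)
    expect_equal(nrow(p), if (L < 50) 0L else (L - 50L) %/% (50L + g) + 1L)
    if (nrow(p)) {
      expect_true(all(p$target_end - p$target_start == 50))
      expect_true(all(p$target_start >= start0 & p$target_end <= start0 + L))
      if (nrow(p) > 1) expect_true(all(diff(p$target_start) == 50 + g))
      sense <- substring(seq, p$target_start - start0 + 1, p$target_end - start0)
      expect_equal(p$sequence, revcomp_chr(sense))
      # re-complementing recovers the sense-strand target window
      expect_equal(revcomp_chr(p$sequence), sense)
    }
  }
})

test_that("the designed probe set equals the staged pipeline run by hand", {
  set.seed(36)
  base <- random_dna_str(200)
  per_sample <- lapply(1:3, function(s) {
    make_regions(
      c(mutate_sequence(base, 0.05, seed = s), random_dna_str(150 + 10 * s)),
      sample_id = sprintf("s%d", s),
      ref_ids = c("shared_ref", sprintf("priv%d", s)),
      median_depth = c(900, 300)
    )
  })
  cfg <- design_config(top_n = 2, gap = 25, seed = 5, coverage_min = 100)
  ps <- design_probe_set(per_sample, cfg)
  # staged oracle: rank/pool/dedup/tile with the same primitives called directly
  staged <- deduplicate_regions(
    pool_samples(lapply(per_sample, rank_and_select, top_n = 2)),
    identity_threshold = 0.80, seed = 5
  )
  staged_probes <- tile_probes(staged, 50, 25)
  expect_equal(ps$probes$probe_id, staged_probes$probe_id)
  expect_equal(nrow(ps$regions), 4)  # shared collapses 3 -> 1, three private
  expect_equal(
    ps$report$count,
    c(6L, 6L, 4L, nrow(staged_probes))
  )
  g <- glance(ps)
  expect_equal(g$n_probes, nrow(tidy(ps)))
  expect_equal(g$top_n, 2L)

  # identical duplicated samples collapse before tiling
  dup <- design_probe_set(list(per_sample[[1]], per_sample[[1]]), cfg)
  expect_equal(nrow(dup$regions), 2)

  expect_warning(empty <- design_probe_set(list(), cfg), "no input regions")
  expect_equal(nrow(empty$probes), 0)

  small_cfg <- design_config(top_n = 2, gap = 0, max_pool_size = 2, seed = 5)
  expect_warning(design_probe_set(per_sample, small_cfg), "exceeds the synthesis pool limit")
})

test_that("design matrix cells equal independent designs and trend monotonically", {
  set.seed(37)
  one_region <- list(make_regions(random_dna_str(500), ref_ids = "solo"))
  cfg <- design_config(seed = 11)
  mx1 <- design_matrix(one_region, top_n_options = 20, gap_options = seq(25, 50, 5), cfg = cfg)
  expect_true(all(diff(mx1$n_probes) <= 0))  # non-increasing in gap

  base <- random_dna_str(300)
  per_sample <- lapply(1:2, function(s) {
    make_regions(
      replicate(6, random_dna_str(sample(100:400, 1))),
      sample_id = sprintf("s%d", s),
      ref_ids = sprintf("s%d_r%d", s, 1:6),
      median_depth = sample(100:900, 6)
    )
  })
  mx <- design_matrix(per_sample, top_n_options = c(2, 4, 6), gap_options = c(25, 50), cfg = cfg)
  expect_equal(nrow(mx), 6)
  expect_true("425" %in% mx$pool_name)
  for (r in seq_len(nrow(mx))) {
    cell_cfg <- design_config(top_n = mx$top_n[r], gap = mx$gap[r], seed = 11)
    indep <- design_probe_set(per_sample, cell_cfg)
    expect_equal(mx$n_probes[r], nrow(indep$probes))
  }
  # non-decreasing in top_n at fixed gap, non-increasing in gap at fixed top_n
  wide <- tidyr::pivot_wider(mx, id_cols = top_n, names_from = gap, values_from = n_probes)
  expect_true(all(diff(wide$`25`) >= 0))
  expect_true(all(diff(wide$`50`) >= 0))
  expect_true(all(wide$`50` <= wide$`25`))
})

test_that("identical inputs, config and seed give byte-identical probe FASTA", {
  set.seed(38)
  per_sample <- lapply(1:2, function(s) {
    make_regions(
      c(random_dna_str(300), random_dna_str(200)),
      sample_id = sprintf("s%d", s), ref_ids = sprintf("s%d_r%d", s, 1:2)
    )
  })
  cfg <- design_config(top_n = 2, gap = 30, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_probe_set(design_probe_set(per_sample, cfg), f1, "fasta")
  write_probe_set(design_probe_set(per_sample, cfg), f2, "fasta")
  expect_identical(readLines(f1), readLines(f2))
})
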