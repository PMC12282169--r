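test_that("sequence mutation hits the requested divergence", {
  set.seed(51)
  s <- random_dna_str(200)
  expect_equal(mutate_sequence(s, 0, seed = 1), s)
  all_changed <- mutate_sequence(s, 1, seed = 2)
  expect_true(all(strsplit(all_changed, "")[[1]] != strsplit(s, "")[[1]]))
  expect_equal(mutate_sequence(s, 0.3, seed = 3), mutate_sequence(s, 0.3, seed = 3))

  big <- random_dna_str(10000)
  mut <- mutate_sequence(big, 0.1, seed = 4)
  n_diff <- sum(strsplit(big, "")[[1]] != strsplit(mut, "")[[1]])
  sd3 <- 3 * sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(n_diff - 1000), sd3)
})

test_that("community generation gives the stated abundance structure", {
  single <- simulate_community(n_abundant = 1, n_rare = 0, ref_length = 200, seed = 1)
  expect_equal(nrow(single$references), 1)
  expect_equal(single$references$abundance, 1.0)

  geo <- simulate_community(
    n_abundant = 5, n_rare = 0, ref_length = 100, abundance_skew = 2, seed = 2
  )
  expect_equal(geo$references$abundance, c(16, 8, 4, 2, 1) / 31, tolerance = 1e-12)

  # planted divergence pair has ~90% pairwise identity by construction
  div <- simulate_community(
    n_abundant = 2, n_rare = 0, ref_length = 1500,
    divergence_grid = 0.1, seed = 3
  )
  refs <- div$references
  expect_equal(nrow(refs), 3)
  id <- pairwise_identity(
    refs$sequence[refs$ref_id == "rrna_ab01"],
    refs$sequence[startsWith(refs$ref_id, "rrna_ab01_div")]
  )
  expect_equal(id, 0.9, tolerance = 0.02)

  mixed <- simulate_community(
    n_abundant = 3, n_rare = 10, n_host = 1, n_mrna = 4,
    rrna_fraction = 0.97, ref_length = 300, seed = 4
  )
  expect_equal(sum(mixed$references$abundance), 1, tolerance = 1e-9)
  expect_equal(
    sum(mixed$references$abundance[mixed$references$category == "rRNA"]),
    0.97, tolerance = 1e-9
  )
})

test_that("simulated reads are faithful to the community and its truth table", {
  comm <- simulate_community(n_abundant = 2, n_rare = 0, ref_length = 400, seed = 5)
  expect_equal(nrow(simulate_reads(comm, 0, seed = 1)$reads), 0)
  expect_error(simulate_reads(comm, 10, read_length = 500, seed = 1), "read_length")

  sim <- simulate_reads(comm, 500, read_length = 100, error_rate = 0, seed = 6)
  refseq <- setNames(comm$references$sequence, comm$references$ref_id)
  # every error-free read is the exact substring at its truth interval
  expect_true(all(
    sim$reads$sequence ==
      substring(refseq[sim$truth$ref_id], sim$truth$start + 1, sim$truth$end)
  ))
  expect_true(all(sim$truth$end <= nchar(refseq[sim$truth$ref_id])))
  # alignments are the truth intervals (perfect-aligner surrogate)
  expect_equal(sim$alignments$ref_start, sim$truth$start)
  expect_equal(sim$alignments$ref_end, sim$truth$end)

  # with errors, reads differ from the reference at about error_rate positions
  noisy <- simulate_reads(comm, 300, read_length = 100, error_rate = 0.05, seed = 7)
  diffs <- mapply(function(s, rid, st) {
    sum(strsplit(s, "")[[1]] != strsplit(substr(refseq[rid], st + 1, st + 100), "")[[1]])
  }, noisy$reads$sequence, noisy$truth$ref_id, noisy$truth$start)
  expect_equal(mean(diffs) / 100, 0.05, tolerance = 0.01)
})

test_that("per-taxon read counts and coverage match sampling expectations", {
  comm <- simulate_community(
    n_abundant = 5, n_rare = 0, ref_length = 1000, abundance_skew = 2, seed = 8
  )
  n_reads <- 40000
  sim <- simulate_reads(comm, n_reads, read_length = 100, seed = 9)
  counts <- table(factor(sim$truth$ref_id, levels = comm$references$ref_id))
  for (i in 1:5) {
    p <- comm$references$abundance[i]
    expect_lt(
      abs(counts[[i]] - n_reads * p),
      4 * sqrt(n_reads * p * (1 - p))
    )
  }
  # interior coverage of the top taxon matches the uniform-start closed form
  cov <- compute_coverage(
    sim$alignments[sim$alignments$ref_id == "rrna_ab01", ],
    comm$references[1, c("ref_id", "sequence")]
  )
  interior <- cov$depth[[1]][100:900]
  expected <- n_reads * comm$references$abundance[1] * 100 / (1000 - 100 + 1)
  expect_equal(mean(interior), expected, tolerance = 0.05)
})

test_that("reads flagged to fail triage are exactly the quality-filter casualties", {
  comm <- simulate_community(n_abundant = 2, n_rare = 0, ref_length = 400, seed = 10)
  sim <- simulate_reads(
    comm, 2000, read_length = 150, low_quality_fraction = 0.2, seed = 11
  )
  expect_gt(sum(sim$truth$qc_fail), 0)
  kept <- quality_filter(sim$reads)
  expect_setequal(kept$read_id, sim$truth$read_id[!sim$truth$qc_fail])
  expect_equal(attr(kept, "n_removed"), sum(sim$truth$qc_fail))
})

test_that("learning sets share core taxa and land in the rRNA-fraction window", {
  one <- make_learning_set(n_samples = 1, n_reads = 2000, seed = 12)
  expect_equal(length(one$samples), 1)
  expect_true(all(one$samples$s1$truth$ref_id %in% one$references$ref_id))

  # shared_taxa_fraction = 1: no private taxa, identical taxon sets
  shared <- make_learning_set(
    n_samples = 3, n_reads = 1000, shared_taxa_fraction = 1, seed = 13
  )
  taxa_sets <- lapply(shared$samples, function(s) {
    sort(unique(s$community$references$ref_id[s$community$references$abundance > 0]))
  })
  expect_equal(taxa_sets[[1]], taxa_sets[[2]])
  expect_equal(taxa_sets[[2]], taxa_sets[[3]])
  expect_false(any(grepl("priv", unlist(taxa_sets))))

  ls <- make_learning_set(n_samples = 7, n_reads = 4000, seed = 14)
  reports <- dplyr::bind_rows(lapply(ls$samples, function(s) {
    partition_report(s$truth$category, s$sample_id)
  }))
  # truth rRNA fractions recover the generator window within multinomial error
  rrna <- reports$fraction[reports$category == "rRNA"]
  expect_true(all(rrna > 0.32 - 0.03 & rrna < 0.55 + 0.03))
  expect_equal(sort(select_learning_samples(reports, 0.30)), sort(names(ls$samples)))
})

test_that("region extraction recovers abundant taxa and no rare-only regions", {
  comm <- simulate_community(
    n_abundant = 3, n_rare = 10, rrna_fraction = 0.97, ref_length = 1500,
    abundance_skew = 1.5, seed = 15
  )
  sim <- simulate_reads(comm, 20000, read_length = 150, seed = 16)
  refs <- comm$references[, c("ref_id", "sequence")]
  cov <- compute_coverage(sim$alignments, refs)
  # abundant taxa sit near 200-500x, rare near 20x: threshold 100 splits them
  regions <- extract_regions(cov, refs, min_depth = 100, sample_id = "s")
  expect_true(all(startsWith(regions$ref_id, "rrna_ab")))
  ab_ids <- comm$references$ref_id[comm$references$tier == "abundant"]
  expect_setequal(unique(regions$ref_id), ab_ids)
  recovered <- sum(regions$end - regions$start)
  expect_gte(recovered / (length(ab_ids) * 1500), 0.90)
})
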