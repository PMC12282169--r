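# Seeded generators for communities, references, reads and alignments with
# the statistical structure the pipeline assumes: rRNA-dominated samples, a
# skewed taxon-abundance distribution, and taxa with controlled pairwise
# identity. Emitted alignments are the truth intervals (a perfect-aligner
# surrogate), which decouples coverage/design logic from any real aligner.
# All randomness flows from one top-level seed via derive_seed().

#' Mutate a sequence at a fixed per-base divergence
#'
#' Each position is independently substituted to one of the three other
#' bases with probability `divergence`; length is preserved. Used to plant
#' taxa with known pairwise identity (about `1 - divergence`).
#'
#' @param seq DNA string.
#' @param divergence Per-base substitution probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The mutated DNA string.
#' @export
mutate_sequence <- function(seq, divergence, seed) {
  if (divergence < 0 || divergence > 1) abort("divergence must be in [0, 1]")
  if (divergence == 0) return(seq)
  withr::with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    bases <- c("A", "C", "G", "T")
    hit <- runif(length(chars)) < divergence
    if (any(hit)) {
      old_idx <- match(chars[hit], bases)
      chars[hit] <- bases[(old_idx - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L + 1L]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate a microbial community with ground truth
#'
#' Generates rRNA references split into an abundant tier (geometric
#' abundances with ratio `abundance_skew`, so e.g. skew 2 over five taxa
#' gives 16:8:4:2:1) and a rare tier sharing `rare_mass` of the rRNA reads
#' equally, plus optional host and mRNA references. For each entry of
#' `divergence_grid` an extra abundant taxon is added as a mutated copy of
#' the first abundant reference, planting known pairwise-identity structure
#' for the redundancy filter.
#'
#' @param n_abundant Number of abundant rRNA taxa (>= 1 unless `n_rare` > 0).
#' @param n_rare Number of rare rRNA taxa.
#' @param ref_length Reference length in bases (default 1500, SSU scale).
#' @param abundance_skew Geometric ratio between successive abundant taxa.
#' @param divergence_grid Per-base divergences for planted near-duplicate
#'   taxa (e.g. `c(0.1)` plants a pair at ~90% identity).
#' @param seed Integer seed.
#' @param n_host,n_mrna Numbers of host / microbial-mRNA references.
#' @param rrna_fraction Fraction of reads drawn from rRNA references
#'   (default 0.97, the typical burden of an undepleted microbiome sample).
#' @param rare_mass Fraction of rRNA reads drawn from the rare tier.
#' @param host_mass Fraction of non-rRNA reads drawn from host references.
#' @return A `community_truth` object: `references` tibble (`ref_id`,
#'   `taxon`, `category`, `tier`, `abundance`, `sequence`) and `seed`.
#' @export
simulate_community <- function(n_abundant = 3, n_rare = 40, ref_length = 1500,
                               abundance_skew = 1.5, divergence_grid = numeric(0),
                               seed = 1, n_host = 0, n_mrna = 0,
                               rrna_fraction = 0.97, rare_mass = 0.10,
                               host_mass = 0.10) {
  if (n_abundant + n_rare < 1) abort("need at least one rRNA taxon")
  n_extra <- length(divergence_grid)
  refs <- withr::with_seed(seed, {
    ab_seq <- replicate(n_abundant, random_dna(ref_length))
    rare_seq <- if (n_rare > 0) replicate(n_rare, random_dna(ref_length)) else character(0)
    host_seq <- if (n_host > 0) replicate(n_host, random_dna(ref_length)) else character(0)
    mrna_seq <- if (n_mrna > 0) replicate(n_mrna, random_dna(ref_length)) else character(0)
    list(ab = ab_seq, rare = rare_seq, host = host_seq, mrna = mrna_seq)
  })
  mut_seq <- purrr::imap_chr(divergence_grid, function(d, i) {
    mutate_sequence(refs$ab[[1]], d, derive_seed(seed, 100 + i))
  })
  n_ab_all <- n_abundant + n_extra
  ab_ids <- c(
    sprintf("rrna_ab%02d", seq_len(n_abundant)),
    if (n_extra) sprintf("rrna_ab01_div%02.0f", 100 * divergence_grid)
  )
  ab_seqs <- c(refs$ab, mut_seq)
  # Geometric abundances within the abundant tier; rare taxa split rare_mass
  # equally; host/mRNA split the non-rRNA remainder.
  ab_w <- abundance_skew^(n_ab_all - seq_len(n_ab_all))
  ab_w <- ab_w / sum(ab_w)
  rrna_ab_mass <- if (n_rare > 0) rrna_fraction * (1 - rare_mass) else rrna_fraction
  non_rrna <- 1 - rrna_fraction
  host_total <- if (n_host > 0) non_rrna * host_mass else 0
  mrna_total <- non_rrna - host_total
  if (n_mrna == 0 && n_host > 0) {
    host_total <- non_rrna
    mrna_total <- 0
  }
  references <- bind_rows(
    tibble(
      ref_id = ab_ids, category = "rRNA", tier = "abundant",
      abundance = ab_w * rrna_ab_mass, sequence = ab_seqs
    ),
    if (n_rare > 0) tibble(
      ref_id = sprintf("rrna_rare%02d", seq_len(n_rare)), category = "rRNA",
      tier = "rare", abundance = rrna_fraction * rare_mass / n_rare,
      sequence = refs$rare
    ),
    if (n_host > 0) tibble(
      ref_id = sprintf("host_tx%02d", seq_len(n_host)), category = "host",
      tier = "host", abundance = host_total / n_host, sequence = refs$host
    ),
    if (n_mrna > 0) tibble(
      ref_id = sprintf("mrna%02d", seq_len(n_mrna)), category = "mRNA",
      tier = "mRNA", abundance = mrna_total / n_mrna, sequence = refs$mrna
    )
  )
  references$taxon <- sprintf("taxon_%02d", seq_len(nrow(references)))
  references$abundance <- references$abundance / sum(references$abundance)
  structure(list(references = references, seed = seed), class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  r <- x$references
  cat(sprintf(
    "<community_truth> %d references (%d rRNA / %d host / %d mRNA), rRNA mass %.3f\n",
    nrow(r), sum(r$category == "rRNA"), sum(r$category == "host"),
    sum(r$category == "mRNA"), sum(r$abundance[r$category == "rRNA"])
  ))
  invisible(x)
}

#' Simulate reads from a community
#'
#' Read start positions are uniform within a source reference chosen in
#' proportion to abundance; substitution errors are applied at `error_rate`;
#' per-base qualities are drawn around `mean_quality`. A fraction
#' `low_quality_fraction` of reads is constructed to fail the standard
#' 50-base/Q20 triage rule (alternately truncated below 50 nt or assigned
#' mean quality Q10) and flagged `qc_fail` in the truth table. The emitted
#' alignments are the truth intervals — a perfect-aligner surrogate.
#'
#' @param truth A `community_truth`.
#' @param n_reads Number of reads.
#' @param read_length Read length in bases (default 150).
#' @param error_rate Per-base substitution error probability.
#' @param mean_quality Mean Phred score of ordinary reads.
#' @param low_quality_fraction Fraction of reads built to fail triage.
#' @param seed Integer seed.
#' @param sample_id Prefix for read ids and label for downstream reports.
#' @return A `sim_sample`: `reads` (read tibble), `alignments` (alignment
#'   tibble), `truth` (per-read `read_id`, `ref_id`, `start`, `end`,
#'   `category`, `qc_fail`), the `community`, and `sample_id`.
#' @export
simulate_reads <- function(truth, n_reads, read_length = 150, error_rate = 0,
                           mean_quality = 35, low_quality_fraction = 0,
                           seed = 1, sample_id = "s1") {
  refs <- truth$references
  if (read_length > min(nchar(refs$sequence))) {
    abort("read_length exceeds the shortest reference length")
  }
  if (n_reads == 0) {
    return(structure(list(
      reads = tibble(read_id = character(0), sequence = character(0), qualities = list()),
      alignments = tibble(
        read_id = character(0), ref_id = character(0),
        ref_start = integer(0), ref_end = integer(0), strand = character(0)
      ),
      truth = tibble(
        read_id = character(0), ref_id = character(0), start = integer(0),
        end = integer(0), category = character(0), qc_fail = logical(0)
      ),
      community = truth, sample_id = sample_id
    ), class = "sim_sample"))
  }
  withr::with_seed(seed, {
    src <- sample.int(nrow(refs), n_reads, replace = TRUE, prob = refs$abundance)
    ref_len <- nchar(refs$sequence)[src]
    start <- floor(runif(n_reads) * (ref_len - read_length + 1))
    lens <- rep(as.integer(read_length), n_reads)
    qc_fail <- runif(n_reads) < low_quality_fraction
    short_mode <- qc_fail & (seq_len(n_reads) %% 2L == 0L)
    lens[short_mode] <- 30L
    seqs <- substring(refs$sequence[src], start + 1L, start + lens)
    if (error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      seqs <- vapply(seqs, function(s) {
        chars <- strsplit(s, "")[[1]]
        hit <- runif(length(chars)) < error_rate
        if (any(hit)) {
          old_idx <- match(chars[hit], bases)
          chars[hit] <- bases[(old_idx - 1L + sample.int(3L, sum(hit), TRUE)) %% 4L + 1L]
        }
        paste(chars, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    mean_q <- rep(mean_quality, n_reads)
    mean_q[qc_fail & !short_mode] <- 10
    quals <- lapply(seq_len(n_reads), function(i) {
      pmin(40L, pmax(2L, as.integer(round(rnorm(lens[i], mean_q[i], 2)))))
    })
    read_id <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
    structure(list(
      reads = tibble(read_id = read_id, sequence = seqs, qualities = quals),
      alignments = tibble(
        read_id = read_id, ref_id = refs$ref_id[src],
        ref_start = as.integer(start), ref_end = as.integer(start + lens),
        strand = "+"
      ),
      truth = tibble(
        read_id = read_id, ref_id = refs$ref_id[src],
        start = as.integer(start), end = as.integer(start + lens),
        category = ifelse(refs$category[src] == "mRNA", "retained", refs$category[src]),
        qc_fail = qc_fail
      ),
      community = truth, sample_id = sample_id
    ), class = "sim_sample")
  })
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf(
    "<sim_sample> %s: %d reads over %d references (rRNA truth fraction %.3f)\n",
    x$sample_id, nrow(x$reads), nrow(x$community$references),
    mean(x$truth$category == "rRNA")
  ))
  invisible(x)
}

#' Generate a multi-sample learning set
#'
#' Emulates a panel of high-rRNA-burden donors for probe-pool training:
#' every sample shares a core of abundant rRNA taxa (so equivalent regions
#' exist to pool across samples) plus sample-private abundant taxa, a common
#' rare-taxon background, and host/mRNA content. Per-sample rRNA fractions
#' are drawn uniformly within `rrna_frac_range`. The default shape — 7
#' samples, 3 shared ~1.5 kb abundant taxa, 40 rare taxa, 50,000 reads of
#' 150 nt per sample, rRNA fractions in (0.32, 0.55) — mirrors a
#' cecal-donor learning panel at desk scale.
#'
#' @param n_samples Number of samples.
#' @param n_reads Reads per sample.
#' @param read_length Read length in bases.
#' @param ref_length Reference length in bases.
#' @param n_shared_abundant Shared abundant rRNA taxa.
#' @param shared_taxa_fraction Fraction of each sample's abundant taxa that
#'   comes from the shared core (1 = identical taxon sets across samples).
#' @param n_rare Rare rRNA taxa in the common background.
#' @param rrna_frac_range Length-2 range the per-sample rRNA read fraction
#'   is drawn from.
#' @param abundance_skew Geometric ratio within each sample's abundant tier.
#' @param error_rate,mean_quality,low_quality_fraction Passed to
#'   [simulate_reads()].
#' @param seed Integer top-level seed.
#' @return A list with `samples` (named list of `sim_sample`) and
#'   `references` (master reference tibble across all samples).
#' @export
make_learning_set <- function(n_samples = 7, n_reads = 50000, read_length = 150,
                              ref_length = 1500, n_shared_abundant = 3,
                              shared_taxa_fraction = 0.75, n_rare = 40,
                              rrna_frac_range = c(0.32, 0.55),
                              abundance_skew = 1.5, error_rate = 0,
                              mean_quality = 35, low_quality_fraction = 0,
                              seed = 1) {
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (shared_taxa_fraction <= 0 || shared_taxa_fraction > 1) {
    abort("shared_taxa_fraction must be in (0, 1]")
  }
  n_private <- as.integer(round(
    n_shared_abundant * (1 - shared_taxa_fraction) / shared_taxa_fraction
  ))
  master <- withr::with_seed(derive_seed(seed, 1), {
    bind_rows(
      tibble(
        ref_id = sprintf("rrna_core%02d", seq_len(n_shared_abundant)),
        category = "rRNA", tier = "abundant",
        sequence = replicate(n_shared_abundant, random_dna(ref_length))
      ),
      if (n_private > 0) tibble(
        ref_id = sprintf(
          "rrna_priv_s%02d_%02d",
          rep(seq_len(n_samples), each = n_private), rep(seq_len(n_private), n_samples)
        ),
        category = "rRNA", tier = "abundant",
        sequence = replicate(n_samples * n_private, random_dna(ref_length))
      ),
      if (n_rare > 0) tibble(
        ref_id = sprintf("rrna_rare%02d", seq_len(n_rare)),
        category = "rRNA", tier = "rare",
        sequence = replicate(n_rare, random_dna(ref_length))
      ),
      tibble(
        ref_id = "host_tx01", category = "host", tier = "host",
        sequence = random_dna(ref_length)
      ),
      tibble(
        ref_id = sprintf("mrna%02d", 1:5), category = "mRNA", tier = "mRNA",
        sequence = replicate(5, random_dna(ref_length))
      )
    )
  })
  master$taxon <- sprintf("taxon_%02d", seq_len(nrow(master)))
  rrna_fracs <- withr::with_seed(
    derive_seed(seed, 2),
    runif(n_samples, rrna_frac_range[1], rrna_frac_range[2])
  )
  samples <- lapply(seq_len(n_samples), function(s) {
    sid <- sprintf("s%d", s)
    ab_ids <- c(
      sprintf("rrna_core%02d", seq_len(n_shared_abundant)),
      if (n_private > 0) sprintf("rrna_priv_s%02d_%02d", s, seq_len(n_private))
    )
    n_ab <- length(ab_ids)
    # Random rank order per sample so abundance profiles differ across donors
    # while the shared core stays abundant everywhere.
    ab_w <- withr::with_seed(derive_seed(seed, 10 + s), {
      w <- abundance_skew^(n_ab - seq_len(n_ab))
      sample(w / sum(w))
    })
    rrna_frac <- rrna_fracs[s]
    refs <- master[master$ref_id %in% c(ab_ids, master$ref_id[master$tier != "abundant"]), ]
    abundance <- numeric(nrow(refs))
    abundance[match(ab_ids, refs$ref_id)] <- ab_w * rrna_frac * 0.9
    rare_idx <- which(refs$tier == "rare")
    if (length(rare_idx)) abundance[rare_idx] <- rrna_frac * 0.1 / length(rare_idx)
    host_idx <- which(refs$tier == "host")
    mrna_idx <- which(refs$tier == "mRNA")
    non_rrna <- 1 - rrna_frac
    abundance[host_idx] <- non_rrna * 0.1 / length(host_idx)
    abundance[mrna_idx] <- non_rrna * 0.9 / length(mrna_idx)
    community <- structure(
      list(
        references = mutate(refs, abundance = abundance / sum(abundance)),
        seed = derive_seed(seed, 10 + s)
      ),
      class = "community_truth"
    )
    simulate_reads(
      community, n_reads = n_reads, read_length = read_length,
      error_rate = error_rate, mean_quality = mean_quality,
      low_quality_fraction = low_quality_fraction,
      seed = derive_seed(seed, 1000 + s), sample_id = sid
    )
  })
  names(samples) <- vapply(samples, function(x) x$sample_id, character(1))
  list(samples = samples, references = master)
}
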