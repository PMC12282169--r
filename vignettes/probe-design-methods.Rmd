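---
title: "Abundance-guided rRNA depletion probe design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance-guided rRNA depletion probe design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotile)
library(dplyr)
```

## Overview

`ribotile` designs antisense oligonucleotide pools for enzymatic (RNase H)
depletion of microbial rRNA from total-RNA sequencing libraries. The design
principle is *taxonomic neutrality*: probes target whatever sequence is
abundant in pilot sequencing data, regardless of which organisms produced
it. This sidesteps two failure modes of taxonomy-driven design — the
combinatorial explosion of probes in communities with hundreds of species,
and the blind spots created when the community differs from the reference
panel the probes were built against.

This vignette explains the model behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design space was
genuinely open.

## Read triage

Reads are first filtered on length and quality, then binned.

* **Quality filter.** A read is kept iff its length is at least
  `min_length` (default 50 bases) and its *mean* per-base Phred score is at
  least `min_mean_quality` (default 20). "Below Q20" could equally be read
  as a per-base trimming rule; the read-level mean is the simplest contract
  that is exactly testable, and it is declared as such rather than inferred.
  The filter is idempotent and order-preserving.
* **k-mer binning.** Production pipelines bin reads by alignment against an
  rRNA database. `ribotile` replaces the aligner with a canonical k-mer
  containment classifier (`build_kmer_index()`, `classify_reads()`): a read
  takes the label of the first index (priority order rRNA → host) for which
  the fraction of its canonical k-mers found in the index reaches
  `min_hit_fraction`. Defaults are k = 21 — long enough that chance matches
  against a ~100 kb reference set are negligible (a random 21-mer hits a
  given set of ~10^5 distinct k-mers with probability ~10^-8) — and
  `min_hit_fraction` = 0.25, low enough that a 150-nt read with a third of
  its length in rRNA still bins as rRNA. Canonical form (lexicographic min
  of k-mer and reverse complement) makes matching strand-insensitive.
  K-mers containing `N` contribute nothing, and reads shorter than k fall
  through to "retained" with a warning.
* **Categories** are fixed to {rRNA, host, retained}; finer breakdowns
  (SSU/LSU per kingdom, other RNA families) collapse onto this set because
  only the rRNA bin feeds probe design. "Retained" is the MetaT-usable
  remainder.

Learning samples for probe design are those whose rRNA fraction *strictly*
exceeds `learning_set_min_rrna_frac` (default 0.30), ranked by burden.

## Coverage and abundant regions

Alignments of binned rRNA reads are piled into per-base depth over each
rRNA reference (`compute_coverage()`; every record counts, so multi-mapping
policy is delegated to whatever produced the alignments). Abundant regions
are maximal runs of positions with depth *strictly* greater than
`min_depth` (`extract_regions()`):

* `min_depth` defaults to 500 reads, the production-scale threshold for
  ~20 M-read samples. Because an absolute depth cutoff scales with
  sequencing depth, analyses at other read counts should scale it to sit
  between the expected coverage of abundant and rare taxa; the package's
  own synthetic-scale runs (50,000 reads/sample) use 50, below which no
  abundant taxon falls and above which no rare taxon rises by a wide
  margin (expected depths ~180–700× vs ~4×).
* `merge_gap` (default 0) controls whether short dips below threshold
  split a region. Whether single-base dips should split is genuinely
  unknowable from a depth track alone, so the knob is exposed; 0 is the
  literal reading of "regions covered above the threshold".
* `min_region_length` defaults to the probe length (50): a region too short
  to hold one probe cannot contribute to the design.
* The ranking statistic is the **median** depth over the region's own
  positions (even-length windows take the mean of the central pair).
  Median, not mean or maximum, because a region's rank should reflect its
  typical abundance rather than one pileup spike.

## Probe design

`design_probe_set()` composes four stages, all individually exported:

1. `rank_and_select()` — per sample, sort by median depth descending (ties
   broken by reference id and start for determinism) and keep the top
   `top_n`.
2. `pool_samples()` — concatenate selections across samples, keeping
   provenance. Deduplication happens *after* pooling: the published
   pipeline describes redundancy filtering on the combined set, and
   collapsing early would hide cross-sample agreement from the collapse
   step.
3. `deduplicate_regions()` — global pairwise alignment of every region
   pair with pinned scoring (match +1, mismatch −1, −1 per gap column, end
   gaps penalised); identity = matched columns / total alignment columns.
   Pairs at or above `identity_threshold` (default 0.80) become graph
   edges, and one representative per *connected component* is kept,
   sampled uniformly under `seed`. Components (transitive closure) rather
   than greedy pair scanning make the retained count independent of input
   order; the seed makes the random choice reproducible and is recorded in
   the result. Sequences are compared sense-strand only, since regions
   inherit a common orientation from the reference database.
4. `tile_probes()` — probes of `probe_length` (default 50 nt) are placed
   left-to-right from each region's 5′ end with stride
   `probe_length + gap`; a trailing stretch shorter than one probe is
   dropped (no end-anchored final probe — the simplest reading of "spaced
   g nt apart"; an end-anchored variant would double-cover the tail and
   break the uniform-spacing invariant). Probe sequences are reverse
   complements of their sense-strand windows; ids default to
   `ref:start-end`.

`design_matrix()` runs the grid `top_n` ∈ {20, 25, 30, 50} ×
`gap` ∈ {25, 30, …, 50} with one shared seed, naming each cell's pool
`<top_n><gap>` (so `5050` and `2025` are the corner pools). Probe counts
are non-increasing in gap and non-decreasing in top_n by construction.
A count above `max_pool_size` (default 384, a synthesis-format and
DNase-saturation consideration, not a correctness bound) warns rather than
fails.

Two open points resolved here as package conventions: identity is computed
with the pinned scoring above because "pairwise alignment" alone does not
fix an algorithm, and the alignment-column identity denominator (gaps
included) is the strictest of the common conventions; and exact duplicate
probes arising from overlapping retained regions are emitted once, since
they denote the same oligo.

## Evaluation

* `insilico_depletion()` marks a read depleted iff any of its alignment
  intervals overlaps any probe target by at least `min_overlap` bases
  (default 25, half a probe). This is a transparent geometric surrogate
  for hybridisation — no thermodynamics, melting temperature, or mismatch
  model — chosen because it is exactly oracle-checkable and because no
  quantitative binding model is available for the pools being emulated.
  Reported fractions after depletion are computed on the post-depletion
  total, mirroring how sequencing reallocates library share.
* `probe_footprint_coverage()` asks how much truly abundant sequence the
  design reached. Its default "footprint" mode credits the span from a
  tiled region's first probe start to its last probe end: inter-probe gaps
  are deliberate spacing (RNase H fragments hybridised RNA without needing
  contiguous probe cover), so they are not design misses. The exact-target
  mode is also available and is bounded above by
  `probe_length/(probe_length + gap)` (= 2/3 at 50/25) for interior bases
  by construction.
* `shannon_index()` uses the natural logarithm (the convention must be
  pinned for values to be comparable; base-2 values differ by a factor
  log2(e)). `tss_normalize()` divides each sample column by its sum;
  `compare_profiles()` exposes Spearman (average ranks on ties) and
  Pearson correlations.

## The synthetic community generator

The generator (`simulate_community()`, `simulate_reads()`,
`make_learning_set()`) produces the statistical structure the pipeline
assumes, with full ground truth:

* **Standard learning panel** (`make_learning_set()` defaults): 7 samples;
  3 shared abundant rRNA taxa of 1,500 bases (SSU scale) plus one
  sample-private abundant taxon each (`shared_taxa_fraction` 0.75); 40
  rare rRNA taxa as a common background; one host and five mRNA
  references; 50,000 reads of 150 nt per sample (echoing 2 × 150 bp
  sequencing at desk scale); per-sample rRNA fractions drawn uniformly in
  (0.32, 0.55), the burden range of the donors a depletion pool would be
  trained on. Within the abundant tier, abundances are geometric with
  ratio 1.5 and a per-sample random rank order, so donors share taxa but
  differ in profile; the abundant tier carries 90% of the rRNA mass and
  host carries 10% of the non-rRNA mass. These sizes are package choices,
  fixed once, stated here; tests and the acceptance script run at exactly
  these conditions.
* **Reads** start uniformly within a reference chosen proportionally to
  abundance, with optional uniform substitution errors and a controllable
  fraction of reads constructed to fail the 50-base/Q20 rule (flagged in
  the truth table, so filter exactness is testable). Emitted alignments
  are the truth intervals — a perfect-aligner surrogate that decouples
  every downstream stage from any third-party aligner.
* **Planted identity structure**: `mutate_sequence()` and the
  `divergence_grid` argument create taxon pairs at known pairwise
  identity (divergence d gives identity ≈ 1 − d), exercising the 80%
  collapse rule with known component structure.
* **All randomness** flows from one top-level seed through a deterministic
  splitting scheme, so any sub-simulation is independently reproducible.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: coverage unevenness from rRNA secondary
structure and reverse-transcriptase drop-off (starts are uniform, so each
abundant reference yields roughly one region per sample rather than the
many sub-transcript regions seen in practice; one visible consequence is
that all `top_n` values select every region at desk scale, flattening the
design matrix's top_n axis while leaving its gap axis informative);
indels and paired-end structure; chimeras; PCR duplicates; alignment
error; and real phylogenetic sequence similarity (references are i.i.d.
random DNA, so cross-taxon identity is far from the 80% threshold except
where planted). Conclusions about threshold behaviour on real Silva-style
references — where inter-species identity genuinely straddles 80% —
require real data.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open everywhere; SAM (1-based inclusive) is
  converted at the parser boundary, FASTQ qualities are Phred+33 only
  (Phred+64 is detected heuristically and rejected).
* Ranking ties break on (ref_id, start); dedup representative choice is
  the only randomness in design and is seed-pinned; identical inputs,
  config and seed give byte-identical probe FASTA.
* Identity of two optimal alignments is computed as
  matches / (2·matches − score), an exact identity for the pinned scoring
  that avoids any ambiguity in how aligned strings represent end gaps.
  Co-optimal alignments can differ slightly in match count; the package
  reports the value for the alignment its aligner returns, with the pair
  lexicographically ordered first so the result is exactly symmetric.
* Empty inputs degrade explicitly: empty probe sets write header-only
  tables with a warning; zero-read partitions flag undefined fractions
  rather than emitting NaN; all-zero coverage yields no regions;
  zero-total abundance columns are an error naming the sample.
* Synthetic-scale runs in tests and the acceptance script use 50,000
  reads/sample, 1.5 kb references and a depth threshold of 50; these are
  the package's standard study conditions (see above), chosen from the
  expected-coverage calculation, not tuned to outcomes.

## Known limitations

The depletion simulator's overlap rule ignores hybridisation chemistry, so
absolute depletion fractions are optimistic for probes with mismatches or
structure. The classifier is containment-based and will mislabel heavily
diverged rRNA that shares few exact 21-mers with the reference set —
real pipelines use seeded alignment precisely to tolerate divergence. The
generator's uniform-coverage model understates the number of distinct
regions per transcript, so desk-scale probe counts are smaller than
production ones at the same grid point; trends across the grid, and all
exact combinatorial properties (tiling, collapse, ranking), transfer.
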