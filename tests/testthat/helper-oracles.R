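# Independent brute-force oracles. Each recomputes a quantity from first
# principles, by enumeration or textbook dynamic programming, sharing no code
# path with the implementation it checks.

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Global Needleman-Wunsch with match +1 / mismatch -1 / -1 per gap column,
# end gaps penalised. Lexicographic (score, matches) objective so the
# reported identity is the max-match one among co-optimal alignments.
oracle_global_alignment <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)
  Cc <- matrix(0L, n + 1, m + 1)
  S[1, ] <- -(0:m); Cc[1, ] <- 0:m
  S[, 1] <- -(0:n); Cc[, 1] <- 0:n
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- A[i] == B[j]
      cand_s <- c(S[i, j] + if (hit) 1 else -1, S[i, j + 1] - 1, S[i + 1, j] - 1)
      cand_m <- c(M[i, j] + as.integer(hit), M[i, j + 1], M[i + 1, j])
      cand_c <- c(Cc[i, j] + 1L, Cc[i, j + 1] + 1L, Cc[i + 1, j] + 1L)
      best <- which(cand_s == max(cand_s))
      k <- best[which.max(cand_m[best])]
      S[i + 1, j + 1] <- cand_s[k]
      M[i + 1, j + 1] <- cand_m[k]
      Cc[i + 1, j + 1] <- cand_c[k]
    }
  }
  list(score = S[n + 1, m + 1], identity = M[n + 1, m + 1] / Cc[n + 1, m + 1])
}

# Per-position membership counting pileup.
oracle_pileup <- function(starts, ends, len) {
  depth <- integer(len)
  for (p in seq_len(len)) {
    depth[p] <- sum(starts < p & ends >= p)  # 0-based [start, end) vs 1-based p
  }
  depth
}

# Explicit scan for maximal above-threshold runs, gap merging, length filter.
oracle_regions <- function(depth, min_depth, merge_gap, min_len) {
  runs <- list()
  in_run <- FALSE
  for (p in seq_along(depth)) {
    if (depth[p] > min_depth) {
      if (!in_run) {
        runs[[length(runs) + 1]] <- c(p - 1L, p)
        in_run <- TRUE
      } else {
        runs[[length(runs)]][2] <- p
      }
    } else {
      in_run <- FALSE
    }
  }
  if (length(runs) == 0) return(matrix(integer(0), ncol = 2))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] <= merge_gap) {
      merged[[length(merged)]][2] <- r[2]
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- do.call(rbind, merged)
  out[out[, 2] - out[, 1] >= min_len, , drop = FALSE]
}

# Distinct canonical k-mers by direct enumeration.
oracle_canonical_kmers <- function(seqs, k) {
  all_k <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(character(0))
    substring(s, 1:n, 1:n + k - 1L)
  }))
  all_k <- all_k[!grepl("N", all_k, fixed = TRUE)]
  rc <- revcomp_chr(all_k)
  unique(pmin(all_k, rc))
}

# Connected components via union-find over an explicit edge list.
oracle_component_count <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1])
      rb <- find(edges[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Spearman/Pearson from their definitions.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))
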