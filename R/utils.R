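# Shared low-level helpers. All genomic intervals in this package are 0-based
# half-open (BED convention); conversions to the 1-based worlds of IRanges and
# SAM happen only at these boundaries.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()]. `N` is
#' preserved as `N`.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("AACG", "ACGT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical form of a k-mer: lexicographic min of the k-mer and its reverse
# complement, so matching is strand-insensitive.
canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# All k-mers of one sequence as a character vector (possibly length 0).
seq_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

# Deterministic seed-splitting: every sub-simulation draws its own 31-bit seed
# from the top-level one, so components are independently reproducible.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483587)
}

# Random DNA of length n under the current RNG state.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phred_to_char <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

char_to_phred <- function(s) {
  lapply(s, function(v) utf8ToInt(v) - 33L)
}

assert_reads <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) || !all(c("read_id", "sequence") %in% names(reads))) {
    abort(sprintf("`%s` must be a data frame with columns read_id and sequence.", arg))
  }
  invisible(reads)
}

assert_refs <- function(refs, arg = "refs") {
  if (!is.data.frame(refs) || !all(c("ref_id", "sequence") %in% names(refs))) {
    abort(sprintf("`%s` must be a data frame with columns ref_id and sequence.", arg))
  }
  if (anyDuplicated(refs$ref_id)) abort("reference ids must be unique")
  invisible(refs)
}
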