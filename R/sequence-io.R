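#' Read sequences from FASTA or FASTQ
#'
#' FASTA files yield a reference tibble (`ref_id`, `sequence`, `taxon`); the
#' taxon label is taken from the description after the first whitespace when
#' present. FASTQ files yield a read tibble (`read_id`, `sequence`,
#' `qualities`) with qualities decoded from Phred+33 into integer vectors.
#' Phred+64 encodings are detected heuristically and rejected.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"fastq"`.
#' @return A tibble; one row per record, identifiers and sequences verbatim.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 Bacteroides", "ACGT"), fa)
#' read_sequences(fa, "fasta")
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "fasta") {
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
    )
    ids <- names(seqs) %||% character(0)
    first_word <- sub("\\s.*$", "", ids)
    taxon <- ifelse(grepl("\\s", ids), sub("^\\S+\\s+", "", ids), NA_character_)
    if (any(!nzchar(first_word))) abort(sprintf("empty record id in %s", path))
    if (anyDuplicated(first_word)) abort(sprintf("duplicate ref_id in %s", path))
    tibble(ref_id = first_word, sequence = unname(as.character(seqs)), taxon = taxon)
  } else {
    check_fastq_shape(path)
    fq <- tryCatch(
      ShortRead::readFastq(path),
      error = function(e) abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
    )
    ids <- sub("\\s.*$", "", as.character(ShortRead::id(fq)))
    if (any(!nzchar(ids))) abort(sprintf("empty read id in %s", path))
    if (anyDuplicated(ids)) abort(sprintf("duplicate read_id in %s", path))
    qual_chr <- as.character(Biostrings::quality(Biostrings::quality(fq)))
    codes <- utf8ToInt(paste(qual_chr, collapse = ""))
    if (length(codes) && min(codes) >= 64 && max(codes) > 74) {
      abort(sprintf("%s appears to be Phred+64 encoded; only Phred+33 is supported", path))
    }
    tibble(
      read_id = ids,
      sequence = as.character(ShortRead::sread(fq)),
      qualities = char_to_phred(qual_chr)
    )
  }
}

# FASTQ files are strictly 4 lines per record here; a mismatched quality
# string is reported with the 1-based line number of the offending record.
check_fastq_shape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ in %s: %d lines is not a multiple of 4", path, length(lines)))
  }
  n_rec <- length(lines) %/% 4
  for (i in seq_len(n_rec)) {
    base <- (i - 1L) * 4L
    if (!startsWith(lines[base + 1L], "@")) {
      abort(sprintf("malformed FASTQ in %s: line %d does not start with '@'", path, base + 1L))
    }
    if (nchar(lines[base + 2L]) != nchar(lines[base + 4L])) {
      abort(sprintf(
        "format error in %s: sequence/quality length mismatch for record at line %d",
        path, base + 1L
      ))
    }
  }
  invisible(TRUE)
}

#' Write reads or references to FASTA/FASTQ
#'
#' @param x A read tibble (`read_id`, `sequence`, `qualities`) or reference
#'   tibble (`ref_id`, `sequence`).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"` (reads only; Phred+33).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  id_col <- if ("read_id" %in% names(x)) "read_id" else "ref_id"
  if (format == "fasta") {
    seqs <- Biostrings::DNAStringSet(x$sequence)
    names(seqs) <- x[[id_col]]
    Biostrings::writeXStringSet(seqs, path)
  } else {
    if (!"qualities" %in% names(x)) abort("FASTQ output needs a qualities column")
    fq <- ShortRead::ShortReadQ(
      sread = Biostrings::DNAStringSet(x$sequence),
      quality = Biostrings::BStringSet(phred_to_char(x$qualities)),
      id = Biostrings::BStringSet(x[[id_col]])
    )
    ShortRead::writeFastq(fq, path, compress = FALSE)
  }
  invisible(path)
}

#' Read alignment records
#'
#' Alignments are carried as a tibble of `read_id`, `ref_id`, `ref_start`,
#' `ref_end`, `strand` with 0-based half-open coordinates. SAM input is
#' converted at this boundary (1-based POS, CIGAR reference width); unmapped,
#' secondary and supplementary records are skipped with a message.
#'
#' @param path Path to a TSV (with header) or SAM file.
#' @param format `"tsv"` or `"sam"`.
#' @return A tibble of alignment records.
#' @export
read_alignments <- function(path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    aln <- readr::read_tsv(
      path, show_col_types = FALSE,
      col_types = readr::cols(
        read_id = readr::col_character(), ref_id = readr::col_character(),
        ref_start = readr::col_integer(), ref_end = readr::col_integer(),
        strand = readr::col_character()
      )
    )
    need <- c("read_id", "ref_id", "ref_start", "ref_end", "strand")
    if (!all(need %in% names(aln))) {
      abort(sprintf("alignment TSV must have columns %s", paste(need, collapse = ", ")))
    }
    aln <- as_tibble(aln[need])
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    n_total <- Rsamtools::countBam(bam)$records
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flag, what = "qname")
    )
    n_skipped <- n_total - length(ga)
    if (n_skipped > 0) {
      inform(sprintf("skipped %d unmapped/secondary/supplementary SAM record(s)", n_skipped))
    }
    aln <- tibble(
      read_id = S4Vectors::mcols(ga)$qname,
      ref_id = as.character(GenomicAlignments::seqnames(ga)),
      ref_start = GenomicAlignments::start(ga) - 1L,
      ref_end = as.integer(GenomicAlignments::end(ga)),
      strand = as.character(GenomicAlignments::strand(ga))
    )
  }
  bad <- which(aln$ref_end <= aln$ref_start | aln$ref_start < 0)
  if (length(bad)) {
    abort(sprintf("format error: empty or negative interval at alignment row %d", bad[1]))
  }
  if (!all(aln$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  aln
}

#' Write a probe set
#'
#' Supported formats: `fasta` (`>probe_id` / sequence), `tsv` (full table:
#' probe_id, ref_id, target_start, target_end, sequence), `opools_csv` (an
#' order-sheet-style two-column name,sequence CSV for oligo pool synthesis),
#' and `bed` (ref_id, target_start, target_end, probe_id; 0-based half-open).
#'
#' @param probes A probe tibble (as produced by [tile_probes()] or
#'   `tidy()` of a [design_probe_set()] result) or a `probe_set` object.
#' @param path Output path.
#' @param format One of `"fasta"`, `"tsv"`, `"opools_csv"`, `"bed"`.
#' @return `path`, invisibly.
#' @export
write_probe_set <- function(probes, path, format = c("fasta", "tsv", "opools_csv", "bed")) {
  format <- match.arg(format)
  if (inherits(probes, "probe_set")) probes <- probes$probes
  if (anyDuplicated(probes$probe_id)) abort("duplicate probe_id in probe set")
  if (nrow(probes) == 0) warn("writing an empty probe set")
  switch(format,
    fasta = {
      seqs <- Biostrings::DNAStringSet(probes$sequence)
      names(seqs) <- probes$probe_id
      Biostrings::writeXStringSet(seqs, path)
    },
    tsv = readr::write_tsv(
      probes[c("probe_id", "ref_id", "target_start", "target_end", "sequence")], path
    ),
    opools_csv = readr::write_csv(
      tibble(name = probes$probe_id, sequence = probes$sequence), path
    ),
    bed = readr::write_tsv(
      probes[c("ref_id", "target_start", "target_end", "probe_id")], path,
      col_names = FALSE
    )
  )
  invisible(path)
}

#' Read a probe table written by [write_probe_set()] in TSV format
#'
#' @param path Path to the probe TSV.
#' @return A probe tibble.
#' @export
read_probe_set <- function(path) {
  as_tibble(readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      probe_id = readr::col_character(), ref_id = readr::col_character(),
      target_start = readr::col_integer(), target_end = readr::col_integer(),
      sequence = readr::col_character()
    )
  ))
}
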