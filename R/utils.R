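# Low-level sequence helpers shared across modules.  All genomic
# coordinates in this package are 1-based inclusive; strand "+"/"-";
# windows are expressed in transcript orientation and mapped to the
# genome (with reverse complement) at the last moment.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character sequences
#'
#' @param x character vector of DNA sequences (ACGTN, uppercase).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fraction of A in a sequence
#'
#' @param x character vector of sequences; empty strings give 0.
#' @return numeric vector of A fractions.
#' @keywords internal
a_fraction <- function(x) {
  n <- nchar(x)
  na <- nchar(x) - nchar(gsub("A", "", x, fixed = TRUE))
  ifelse(n > 0L, na / n, 0)
}

# Extract a transcript-orientation window around a genomic anchor.
# `from`/`to` are offsets in transcript orientation (0 = anchor base,
# negative = upstream of the anchor, positive = downstream).  The window
# is truncated at contig edges; `n_available` reports how many bases
# survived truncation.
transcript_window <- function(genome, contig, strand, anchor, from, to) {
  stopifnot(from <= to)
  seqlen <- nchar(genome[[contig]])
  if (strand == "+") {
    gs <- anchor + from
    ge <- anchor + to
  } else {
    gs <- anchor - to
    ge <- anchor - from
  }
  cs <- max(gs, 1L)
  ce <- min(ge, seqlen)
  if (cs > ce) {
    return(list(seq = "", n_available = 0L))
  }
  s <- substr(genome[[contig]], cs, ce)
  if (strand == "-") s <- revcomp(s)
  list(seq = s, n_available = ce - cs + 1L)
}

# Replace bases of `contig_seq` over genomic interval [gs, ge] with
# `replacement` given in transcript orientation for `strand`.
plant_sequence <- function(contig_seq, gs, strand, replacement) {
  if (strand == "-") replacement <- revcomp(replacement)
  ge <- gs + nchar(replacement) - 1L
  stopifnot(gs >= 1L, ge <= nchar(contig_seq))
  substr(contig_seq, gs, ge) <- replacement
  contig_seq
}

# Hamming distance between equal-length strings (vectorised over `x`).
hamming <- function(x, ref) {
  r <- utf8ToInt(ref)
  vapply(x, function(s) sum(utf8ToInt(s) != r), integer(1), USE.NAMES = FALSE)
}

# Deterministic derived seed kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% .Machine$integer.max)
}
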