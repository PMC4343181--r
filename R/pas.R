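# PAS hexamer detection/classification and cleavage-context nucleotide
# profiling.  The canonical polyadenylation signal is AAUAAA (DNA sense
# AATAAA), typically ending ~19 nt upstream of the cleavage site;
# "permutations" are single-base substitutions (Hamming distance).

CANONICAL_PAS <- "AATAAA"

#' Classify the PAS hexamer of one or more isoforms
#'
#' Scans, in transcript orientation on the sense strand, every hexamer
#' whose last base lies within \code{search_window} (offsets relative to
#' the cleavage site, default [-40, -10]) and picks the one with minimal
#' Hamming distance to AATAAA, ties broken by end position closest to
#' -19 (the canonical placement).  Distance 0/1/2 maps to class
#' canonical/one_permutation/two_plus_permutations; no hexamer within
#' \code{max_distance} gives class "none", as does insufficient upstream
#' sequence.
#'
#' @param isoforms data frame with gene_id, contig, strand,
#'   cleavage_site columns (see \code{\link{isoforms_with_coords}}).
#' @param genome named character vector of contig sequences.
#' @param search_window integer c(from, to) of allowed hexamer-end
#'   offsets (negative, transcript orientation).
#' @param max_distance maximum Hamming distance (default 2).
#' @return the input with pas_hexamer, pas_class and pas_position
#'   (hexamer-end offset) columns.
#' @export
classify_pas <- function(isoforms, genome, search_window = c(-40L, -10L),
                         max_distance = 2L) {
  stopifnot(search_window[1] <= search_window[2], search_window[2] < 0L)
  ends <- seq(search_window[1], search_window[2])
  n <- nrow(isoforms)
  hex <- rep(NA_character_, n); cls <- rep("none", n); pp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    w <- transcript_window(genome, isoforms$contig[i], isoforms$strand[i],
                           isoforms$cleavage_site[i],
                           search_window[1] - 5L, search_window[2])
    need <- search_window[2] - (search_window[1] - 5L) + 1L
    if (w$n_available < need) next  # insufficient upstream sequence
    starts <- seq_len(nchar(w$seq) - 5L)
    kmers <- substring(w$seq, starts, starts + 5L)
    d <- hamming(kmers, CANONICAL_PAS)
    if (min(d) > max_distance) next
    cand <- which(d == min(d))
    best <- cand[order(abs(ends[cand] + 19L), ends[cand])][1]
    hex[i] <- kmers[best]
    pp[i] <- ends[best]
    cls[i] <- c("canonical", "one_permutation",
                "two_plus_permutations")[min(d[best], 2L) + 1L]
  }
  isoforms$pas_hexamer <- hex
  isoforms$pas_class <- cls
  isoforms$pas_position <- pp
  isoforms
}

#' PAS class frequencies
#'
#' @param calls data frame with a pas_class column.
#' @return named numeric proportions over the four classes (canonical,
#'   one_permutation, two_plus_permutations, none), summing to 1;
#'   \code{NULL} for empty input.
#' @export
pas_class_frequencies <- function(calls) {
  if (nrow(calls) == 0L) return(NULL)
  lv <- c("canonical", "one_permutation", "two_plus_permutations", "none")
  tab <- table(factor(calls$pas_class, levels = lv))
  as.numeric(tab) / nrow(calls) -> p
  setNames(p, lv)
}

#' Nucleotide frequency profile around cleavage sites
#'
#' Extracts the 70-nt transcript-orientation context covering offsets
#' -50..-1 and +1..+20 around each cleavage site (the cleavage base
#' itself, offset 0, is excluded) and tabulates per-position nucleotide
#' frequencies; isoforms lacking the full window are excluded and
#' counted.
#'
#' @param isoforms data frame with contig, strand, cleavage_site.
#' @param genome named character vector of contig sequences.
#' @return list with \code{profile} (4 x 70 matrix, rows A/C/G/T, columns
#'   named by offset; each column sums to 1), \code{n_used} and
#'   \code{n_excluded}.
#' @export
cleavage_context_profile <- function(isoforms, genome) {
  offs <- c(-50:-1, 1:20)
  seqs <- character(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(isoforms))) {
    up <- transcript_window(genome, isoforms$contig[i], isoforms$strand[i],
                            isoforms$cleavage_site[i], -50L, -1L)
    dn <- transcript_window(genome, isoforms$contig[i], isoforms$strand[i],
                            isoforms$cleavage_site[i], 1L, 20L)
    if (up$n_available < 50L || dn$n_available < 20L) {
      n_excluded <- n_excluded + 1L
    } else {
      seqs <- c(seqs, paste0(up$seq, dn$seq))
    }
  }
  if (length(seqs) == 0L)
    return(list(profile = NULL, n_used = 0L, n_excluded = n_excluded))
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                    baseOnly = TRUE)[DNA_BASES, , drop = FALSE]
  profile <- sweep(cm, 2L, colSums(cm), "/")
  colnames(profile) <- offs
  list(profile = profile, n_used = length(seqs), n_excluded = n_excluded)
}

#' Attach genomic coordinates to an isoform catalog
#'
#' Convenience join adding contig and strand from the annotation to a
#' catalog keyed by gene_id (cleavage_site is already genomic).
#'
#' @param isoforms isoform data frame (gene_id, cleavage_site, ...).
#' @param annotation parsed annotation.
#' @return the isoform data frame with contig and strand columns.
#' @export
isoforms_with_coords <- function(isoforms, annotation) {
  gi <- match(isoforms$gene_id, annotation$genes$gene_id)
  isoforms$contig <- annotation$genes$contig[gi]
  isoforms$strand <- annotation$genes$strand[gi]
  isoforms
}
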