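# Built-in exact seed-and-extend aligner.  Contract: unique best
# exact-or-near-exact locus (exact 18-nt 5' seed, at most one substitution
# in the extension); two or more equally good loci make the read
# multi-mapped and it is discarded with a counted reason.  Adequate for
# the synthetic genome; externally produced SAM is accepted through
# parse_alignments() as an alternative entry point.

#' Build a k-mer index of the genome
#'
#' Indexes every k-mer of the forward and reverse-complement strand of
#' each contig for seed lookup.
#'
#' @param genome named character vector of contig sequences.
#' @param seed_length seed k-mer length (default 18 nt, matching the
#'   minimum consecutively mapped stretch the pipeline requires).
#' @return object of class \code{genome_index}.
#' @export
build_genome_index <- function(genome, seed_length = 18L) {
  stopifnot(length(genome) > 0L, !is.null(names(genome)))
  tabs <- list()
  for (cn in names(genome)) {
    fw <- genome[[cn]]
    n <- nchar(fw)
    if (n < seed_length) next
    rv <- revcomp(fw)
    starts <- seq_len(n - seed_length + 1L)
    tabs[[paste0(cn, "+")]] <- data.table::data.table(
      kmer = substring(fw, starts, starts + seed_length - 1L),
      contig = cn, strand = "+", spos = starts)
    tabs[[paste0(cn, "-")]] <- data.table::data.table(
      kmer = substring(rv, starts, starts + seed_length - 1L),
      contig = cn, strand = "-", spos = starts)
  }
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  structure(list(index = idx, seed_length = seed_length,
                 strands = c(lapply(genome, identity),
                             setNames(lapply(genome, revcomp),
                                      paste0(names(genome), ".rc"))),
                 contig_lengths = setNames(nchar(genome), names(genome))),
            class = "genome_index")
}

#' Align reads with the built-in seed-and-extend aligner
#'
#' Looks up the exact 5' seed of each read in the genome index, verifies
#' candidate loci allowing at most \code{max_mismatch} substitutions in
#' the extension, and reports the unique best locus.  Reads shorter than
#' the seed, without any seed hit, or with two or more equally good loci
#' are returned in the accounting, not the alignment table.
#'
#' @param reads named character vector of read sequences (names = ids).
#' @param index a \code{\link{build_genome_index}} object.
#' @param max_mismatch maximum substitutions outside the seed (default 1).
#' @return list with \code{alignments} (data frame: read_id, contig,
#'   strand, pos = 1-based leftmost genomic, span,
#'   longest_consecutive_match, mismatches) and \code{unaligned} /
#'   \code{multi_mapped} / \code{too_short} id vectors.
#' @export
align_reads <- function(reads, index, max_mismatch = 1L) {
  k <- index$seed_length
  ids <- names(reads)
  lens <- nchar(reads)
  too_short <- ids[lens < k]
  keep <- lens >= k
  reads <- reads[keep]; ids <- ids[keep]; lens <- lens[keep]
  if (length(reads) == 0L) {
    return(list(alignments = empty_alignments(), unaligned = character(0),
                multi_mapped = character(0), too_short = too_short))
  }
  qdt <- data.table::data.table(kmer = substr(reads, 1L, k),
                                rid = seq_along(reads))
  hits <- index$index[qdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) {
    return(list(alignments = empty_alignments(), unaligned = ids,
                multi_mapped = character(0), too_short = too_short))
  }
  hits[, len := lens[rid]]
  hits[, clen := index$contig_lengths[contig]]
  hits <- hits[spos + len - 1L <= clen]
  # verify extensions in strand-oriented coordinates
  sseq <- ifelse(hits$strand == "+", hits$contig, paste0(hits$contig, ".rc"))
  gext <- substring(vapply(sseq, function(s) index$strands[[s]], character(1)),
                    hits$spos + k, hits$spos + hits$len - 1L)
  rext <- substr(reads[hits$rid], k + 1L, hits$len)
  mm <- integer(nrow(hits)); first_mm <- integer(nrow(hits)); last_mm <- integer(nrow(hits))
  neq <- which(gext != rext)
  for (i in neq) {
    d <- which(utf8ToInt(gext[i]) != utf8ToInt(rext[i]))
    mm[i] <- length(d)
    first_mm[i] <- d[1]; last_mm[i] <- d[length(d)]
  }
  hits[, `:=`(mm = mm, first_mm = first_mm)]
  hits <- hits[mm <= max_mismatch]
  if (nrow(hits) == 0L) {
    return(list(alignments = empty_alignments(), unaligned = ids,
                multi_mapped = character(0), too_short = too_short))
  }
  hits[, best := mm == min(mm), by = rid]
  hits <- hits[best == TRUE]
  hits[, nbest := .N, by = rid]
  multi_rid <- unique(hits$rid[hits$nbest > 1L])
  aligned <- hits[nbest == 1L]
  got <- unique(c(aligned$rid, multi_rid))
  unaligned <- ids[setdiff(seq_along(ids), got)]
  lcm <- ifelse(aligned$mm == 0L, aligned$len,
                pmax(k + aligned$first_mm - 1L, aligned$len - (k + aligned$first_mm)))
  gpos <- ifelse(aligned$strand == "+", aligned$spos,
                 aligned$clen - (aligned$spos + aligned$len - 1L) + 1L)
  alignments <- data.frame(read_id = ids[aligned$rid], contig = aligned$contig,
                           strand = aligned$strand, pos = as.integer(gpos),
                           span = aligned$len,
                           longest_consecutive_match = as.integer(lcm),
                           mismatches = aligned$mm, stringsAsFactors = FALSE)
  list(alignments = alignments, unaligned = unaligned,
       multi_mapped = ids[multi_rid], too_short = too_short)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), contig = character(0), strand = character(0),
             pos = integer(0), span = integer(0),
             longest_consecutive_match = integer(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}
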