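# PolyA read extraction, cleavage-site mapping, internal-priming
# filtering, single-linkage clustering, gene assignment and cluster-level
# filters.  Thresholds follow the printed rules exactly and with strict
# inequalities: a read is retained iff its maximal terminal A-run is
# >= 30 nt; a cleavage event fails iff the A fraction in the 30-nt window
# on either side is >= 65% or the longest consecutively mapped stretch is
# < 18 nt; a cluster is filtered iff its usage share is < 5% of the
# gene's polyA reads or its genomic footprint is > 40% A.

#' Extract polyA-tailed reads and trim their tails
#'
#' A read is retained iff its maximal terminal A-run is at least
#' \code{min_tail} nt; the run is then removed.  Reads whose trimmed
#' remainder is shorter than \code{min_trimmed} (the aligner seed) are
#' dropped with a counted reason, as are reads containing characters
#' outside ACGTN.
#'
#' @param reads named character vector of read sequences.
#' @param min_tail minimum terminal A-run (default 30 nt).
#' @param min_trimmed minimum alignable remainder (default 18 nt).
#' @return list with \code{reads} (data frame: read_id, trimmed,
#'   tail_length) and \code{accounting} (named counts: retained, no_tail,
#'   too_short, non_acgt).
#' @export
extract_polya_reads <- function(reads, min_tail = 30L, min_trimmed = 18L) {
  stopifnot(min_tail >= 1L)
  ids <- names(reads)
  ok_alpha <- !grepl("[^ACGTN]", reads)
  m <- regexpr("A+$", reads)
  tail_len <- ifelse(m > 0L, attr(m, "match.length"), 0L)
  has_tail <- ok_alpha & tail_len >= min_tail
  trimmed <- substr(reads, 1L, nchar(reads) - tail_len)
  long_enough <- nchar(trimmed) >= min_trimmed
  keep <- has_tail & long_enough
  acc <- c(retained = sum(keep),
           no_tail = sum(ok_alpha & !has_tail),
           too_short = sum(has_tail & !long_enough),
           non_acgt = sum(!ok_alpha))
  list(reads = data.frame(read_id = ids[keep], trimmed = unname(trimmed[keep]),
                          tail_length = as.integer(tail_len[keep]),
                          stringsAsFactors = FALSE),
       accounting = acc)
}

#' Compute cleavage sites from alignments
#'
#' The cleavage position is the genomic coordinate of the last
#' transcribed base: on "+" the rightmost aligned base
#' (\code{pos + span - 1}), on "-" the leftmost (\code{pos}).
#'
#' @param alignments alignment data frame (1-based \code{pos}, see
#'   \code{\link{align_reads}}).
#' @return the same data frame with a \code{cleavage_position} column.
#' @export
compute_cleavage_site <- function(alignments) {
  alignments$cleavage_position <- ifelse(alignments$strand == "+",
                                         alignments$pos + alignments$span - 1L,
                                         alignments$pos)
  alignments
}

#' Internal-priming and mapping-quality filter
#'
#' A cleavage event fails if the A fraction (transcript-orientation sense
#' strand) in the \code{window} nt immediately downstream of the cleavage
#' position is >= \code{a_threshold}, or likewise immediately upstream
#' ("either direction"), or if the alignment's longest consecutively
#' mapped stretch is < \code{min_consecutive} nt.  Windows are truncated
#' at contig edges and the fraction is taken over the available bases.
#'
#' @param events data frame with contig, strand, cleavage_position and
#'   longest_consecutive_match columns.
#' @param genome named character vector of contig sequences.
#' @param a_threshold A-fraction threshold (default 0.65).
#' @param window window length on each side (default 30 nt).
#' @param min_consecutive minimum consecutively mapped stretch (default 18).
#' @return the events data frame with a \code{filter_reason} column:
#'   "pass", "a_rich_downstream", "a_rich_upstream" or "short_match".
#' @export
filter_internal_priming <- function(events, genome, a_threshold = 0.65,
                                    window = 30L, min_consecutive = 18L) {
  n <- nrow(events)
  if (n == 0L) {
    events$filter_reason <- character(0)
    return(events)
  }
  cs <- events$cleavage_position
  plus <- events$strand == "+"
  clen <- nchar(genome)[events$contig]
  # genomic windows; "downstream"/"upstream" in transcript orientation
  dn_s <- ifelse(plus, cs + 1L, cs - window)
  dn_e <- ifelse(plus, cs + window, cs - 1L)
  up_s <- ifelse(plus, cs - window, cs + 1L)
  up_e <- ifelse(plus, cs - 1L, cs + window)
  frac <- function(s, e) {
    s2 <- pmax(s, 1L); e2 <- pmin(e, clen)
    avail <- pmax(e2 - s2 + 1L, 0L)
    seqs <- substring(genome[events$contig], s2, pmax(e2, s2))
    # sense-strand A count: A on "+", T on "-" (no reverse complement needed)
    na <- ifelse(plus,
                 nchar(seqs) - nchar(gsub("A", "", seqs, fixed = TRUE)),
                 nchar(seqs) - nchar(gsub("T", "", seqs, fixed = TRUE)))
    ifelse(avail > 0L, na / avail, 0)
  }
  reason <- rep("pass", n)
  short <- events$longest_consecutive_match < min_consecutive
  reason[short] <- "short_match"
  reason[frac(up_s, up_e) >= a_threshold] <- "a_rich_upstream"
  reason[frac(dn_s, dn_e) >= a_threshold] <- "a_rich_downstream"
  events$filter_reason <- reason
  events
}

#' Single-linkage clustering of cleavage positions
#'
#' Within each (contig, strand), sorted positions are joined into one
#' cluster while consecutive gaps are <= \code{max_gap}.  The
#' representative site is the modal member position, ties broken toward
#' the transcript-3'-most position; the span is [min, max] of members.
#'
#' @param events data frame of passing cleavage events (contig, strand,
#'   cleavage_position; one row per read).
#' @param max_gap maximum joining gap (default 25 nt).
#' @return data frame of clusters: cluster_id, contig, strand,
#'   representative_site, span_start, span_end, read_count.
#' @export
cluster_cleavage_sites <- function(events, max_gap = 25L) {
  if (nrow(events) == 0L) {
    return(data.frame(cluster_id = character(0), contig = character(0),
                      strand = character(0), representative_site = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      read_count = integer(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (key in unique(paste(events$contig, events$strand))) {
    sel <- paste(events$contig, events$strand) == key
    contig <- events$contig[sel][1]; strand <- events$strand[sel][1]
    pos <- sort(events$cleavage_position[sel])
    grp <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      tab <- table(p)
      modal <- as.integer(names(tab)[tab == max(tab)])
      rep_site <- if (strand == "+") max(modal) else min(modal)
      out[[length(out) + 1L]] <- data.frame(
        contig = contig, strand = strand, representative_site = rep_site,
        span_start = min(p), span_end = max(p), read_count = length(p),
        stringsAsFactors = FALSE)
    }
  }
  cl <- do.call(rbind, out)
  cl <- cl[order(cl$contig, cl$strand, cl$span_start), ]
  cl <- cbind(cluster_id = sprintf("cl%05d", seq_len(nrow(cl))), cl,
              stringsAsFactors = FALSE)
  rownames(cl) <- NULL
  cl
}

#' Attach clusters to the closest gene within range
#'
#' Candidate genes share the cluster's contig and strand.  A cluster's
#' distance to a gene is 0 if its representative site lies inside the
#' transcript-orientation interval from the stop codon to
#' \code{max_distance} nt past the gene 3' end, else the gap to that
#' interval.  The nearest candidate wins; exact ties go to the gene whose
#' 3' terminus is nearest upstream of the site; distance beyond
#' \code{max_distance} leaves the cluster unassigned.
#'
#' @param clusters cluster data frame from
#'   \code{\link{cluster_cleavage_sites}}.
#' @param annotation parsed annotation.
#' @param max_distance maximum attachment distance (default 1,600 nt).
#' @return clusters with \code{assigned_gene} and \code{distance_to_gene}
#'   columns.
#' @export
assign_clusters_to_genes <- function(clusters, annotation, max_distance = 1600L) {
  g <- annotation$genes
  clusters$assigned_gene <- NA_character_
  clusters$distance_to_gene <- NA_integer_
  for (i in seq_len(nrow(clusters))) {
    cand <- g[g$contig == clusters$contig[i] & g$strand == clusters$strand[i] &
                g$has_stop, ]
    if (nrow(cand) == 0L) next
    site <- clusters$representative_site[i]
    if (clusters$strand[i] == "+") {
      lo <- cand$stop_codon_end; hi <- cand$gene_end + max_distance
      terminus <- cand$gene_end
      upstream_of_site <- terminus <= site
    } else {
      lo <- cand$gene_start - max_distance; hi <- cand$stop_codon_end
      terminus <- cand$gene_start
      upstream_of_site <- terminus >= site
    }
    dist <- pmax(lo - site, site - hi, 0L)
    ok <- dist <= max_distance
    if (!any(ok)) next
    best <- which(ok & dist == min(dist[ok]))
    if (length(best) > 1L) {
      # tie: prefer the gene whose 3' terminus is nearest upstream
      ups <- best[upstream_of_site[best]]
      pool <- if (length(ups) > 0L) ups else best
      tdist <- abs(terminus[pool] - site)
      best <- pool[order(tdist, cand$gene_id[pool])][1]
    }
    clusters$assigned_gene[i] <- cand$gene_id[best]
    clusters$distance_to_gene[i] <- dist[best]
  }
  clusters
}

#' Final cluster-level filters and usage renormalization
#'
#' Per gene: clusters whose genomic footprint (sense strand, span_start
#' to span_end) exceeds \code{a_footprint_threshold} A are filtered
#' first; usage fractions are then computed over the remaining clusters'
#' read counts, clusters below \code{min_usage} are filtered, and the
#' survivors' usage fractions are renormalized to sum to 1.
#'
#' @param clusters assigned clusters.
#' @param genome named character vector of contig sequences.
#' @param min_usage minimum usage share (default 0.05).
#' @param a_footprint_threshold maximum footprint A fraction (default 0.40).
#' @return clusters with \code{a_fraction_of_footprint},
#'   \code{usage_fraction} and \code{status} ("retained",
#'   "filtered:a_rich_footprint", "filtered:low_usage", "unassigned").
#' @export
filter_clusters <- function(clusters, genome, min_usage = 0.05,
                            a_footprint_threshold = 0.40) {
  n <- nrow(clusters)
  clusters$a_fraction_of_footprint <- vapply(seq_len(n), function(i) {
    w <- transcript_window(genome, clusters$contig[i], clusters$strand[i],
                           clusters$span_start[i], 0L,
                           clusters$span_end[i] - clusters$span_start[i])
    a_fraction(w$seq)
  }, numeric(1))
  clusters$usage_fraction <- NA_real_
  clusters$status <- ifelse(is.na(clusters$assigned_gene), "unassigned", "retained")
  arich <- clusters$status == "retained" &
    clusters$a_fraction_of_footprint > a_footprint_threshold
  clusters$status[arich] <- "filtered:a_rich_footprint"
  for (g in unique(clusters$assigned_gene[clusters$status == "retained"])) {
    sel <- which(clusters$assigned_gene %in% g & clusters$status == "retained")
    total <- sum(clusters$read_count[sel])
    usage <- clusters$read_count[sel] / total
    low <- usage < min_usage
    clusters$status[sel[low]] <- "filtered:low_usage"
    keep <- sel[!low]
    clusters$usage_fraction[keep] <-
      clusters$read_count[keep] / sum(clusters$read_count[keep])
  }
  clusters
}

#' Map a polyA read library end to end
#'
#' Runs tail extraction, alignment (built-in aligner or supplied external
#' alignments), cleavage-site computation, internal-priming filtering,
#' clustering, gene assignment and cluster filtering, keeping a per-stage
#' read-accounting ledger in which every input read appears exactly once.
#'
#' @param reads named character vector of read sequences.
#' @param genome named character vector of contig sequences.
#' @param annotation parsed annotation.
#' @param index optional prebuilt \code{\link{build_genome_index}}.
#' @param alignments optional externally parsed alignments (from
#'   \code{\link{parse_alignments}}) for the trimmed reads; when given,
#'   the built-in aligner is skipped and reads absent from the table are
#'   counted unaligned.
#' @param min_tail,a_threshold,window,min_consecutive,max_gap,max_distance,min_usage,a_footprint_threshold
#'   stage parameters (see the stage functions for defaults).
#' @return list with \code{clusters}, \code{events} (per-read cleavage
#'   events with filter reasons), and \code{accounting} (named integer
#'   vector over read outcomes summing to \code{length(reads)}).
#' @export
map_polya_reads <- function(reads, genome, annotation, index = NULL,
                            alignments = NULL, min_tail = 30L,
                            a_threshold = 0.65, window = 30L,
                            min_consecutive = 18L, max_gap = 25L,
                            max_distance = 1600L, min_usage = 0.05,
                            a_footprint_threshold = 0.40) {
  ex <- extract_polya_reads(reads, min_tail = min_tail)
  if (is.null(alignments)) {
    if (is.null(index)) index <- build_genome_index(genome)
    trimmed <- setNames(ex$reads$trimmed, ex$reads$read_id)
    al <- align_reads(trimmed, index)
    aln <- al$alignments
    n_unaligned <- length(al$unaligned) + length(al$too_short)
    n_multi <- length(al$multi_mapped)
  } else {
    aln <- alignments[alignments$read_id %in% ex$reads$read_id, ]
    n_unaligned <- nrow(ex$reads) - nrow(aln)
    n_multi <- 0L
  }
  aln$tail_length <- ex$reads$tail_length[match(aln$read_id, ex$reads$read_id)]
  events <- compute_cleavage_site(aln)
  events <- filter_internal_priming(events, genome, a_threshold = a_threshold,
                                    window = window,
                                    min_consecutive = min_consecutive)
  passing <- events[events$filter_reason == "pass", ]
  clusters <- cluster_cleavage_sites(passing, max_gap = max_gap)
  clusters <- assign_clusters_to_genes(clusters, annotation,
                                       max_distance = max_distance)
  clusters <- filter_clusters(clusters, genome, min_usage = min_usage,
                              a_footprint_threshold = a_footprint_threshold)
  accounting <- c(no_tail = unname(ex$accounting["no_tail"]),
                  non_acgt = unname(ex$accounting["non_acgt"]),
                  trimmed_too_short = unname(ex$accounting["too_short"]),
                  unaligned = n_unaligned,
                  multi_mapped = n_multi,
                  filtered_a_rich_downstream = sum(events$filter_reason == "a_rich_downstream"),
                  filtered_a_rich_upstream = sum(events$filter_reason == "a_rich_upstream"),
                  filtered_short_match = sum(events$filter_reason == "short_match"),
                  clustered = nrow(passing))
  list(clusters = clusters, events = events, accounting = accounting)
}
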