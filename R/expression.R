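# Union-exon FPKM quantification, expression thresholding and tissue
# set algebra.  A fragment (= a single-end read here) is assigned to the
# same-strand gene whose union-exon span it overlaps most; ties and
# zero overlap leave it unassigned.  FPKM = C * 1e9 / (L * N) with C the
# gene's fragment count, L its union-exon length and N the total number
# of assigned fragments; genes with FPKM >= 1 are called expressed.

#' Assign fragments to genes by majority union-exon overlap
#'
#' @param alignments alignment data frame (read_id, contig, strand, pos,
#'   span) of primary alignments.
#' @param annotation parsed annotation.
#' @return list with \code{counts} (named integer per gene, zero-filled),
#'   \code{n_assigned}, \code{n_unassigned} and \code{n_total}.
#' @export
assign_fragments <- function(alignments, annotation) {
  e <- annotation$exons
  counts <- setNames(integer(nrow(annotation$genes)), annotation$genes$gene_id)
  n_total <- nrow(alignments)
  if (n_total == 0L || nrow(e) == 0L) {
    return(list(counts = counts, n_assigned = 0L, n_unassigned = n_total,
                n_total = n_total))
  }
  agr <- GenomicRanges::GRanges(alignments$contig,
                                IRanges::IRanges(alignments$pos,
                                                 alignments$pos + alignments$span - 1L),
                                strand = alignments$strand)
  egr <- GenomicRanges::GRanges(e$contig, IRanges::IRanges(e$start, e$end),
                                strand = e$strand)
  ov <- GenomicRanges::findOverlaps(agr, egr)
  if (length(ov) == 0L) {
    return(list(counts = counts, n_assigned = 0L, n_unassigned = n_total,
                n_total = n_total))
  }
  w <- IRanges::width(IRanges::pintersect(agr[S4Vectors::queryHits(ov)],
                                          egr[S4Vectors::subjectHits(ov)]))
  dt <- data.table::data.table(read = S4Vectors::queryHits(ov),
                               gene = e$gene_id[S4Vectors::subjectHits(ov)],
                               w = w)
  per_gene <- dt[, .(w = sum(w)), by = .(read, gene)]
  per_gene[, best := w == max(w), by = read]
  per_gene <- per_gene[best == TRUE]
  per_gene[, nbest := .N, by = read]
  winners <- per_gene[nbest == 1L]
  tab <- table(winners$gene)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, n_assigned = nrow(winners),
       n_unassigned = n_total - nrow(winners), n_total = n_total)
}

#' Compute union-exon FPKM and expressed flags
#'
#' @param counts named integer vector of per-gene fragment counts C.
#' @param annotation parsed annotation (union-exon lengths L are computed
#'   from its exons; genes with L = 0 are skipped with a warning).
#' @param N total assigned fragments (defaults to \code{sum(counts)}).
#' @param threshold expressed iff FPKM >= threshold (default 1).
#' @param tissue optional tissue label carried into the output.
#' @return data frame: gene_id, tissue, C, L, N, fpkm, expressed.
#' @export
compute_fpkm <- function(counts, annotation, N = sum(counts), threshold = 1,
                         tissue = NA_character_) {
  stopifnot(N > 0)
  e <- annotation$exons
  L <- tapply(e$end - e$start + 1L, e$gene_id, sum)
  gene_ids <- names(counts)
  Lv <- as.numeric(L[gene_ids])
  Lv[is.na(Lv)] <- 0
  bad <- Lv <= 0
  if (any(bad)) {
    warning("skipping ", sum(bad), " gene(s) with zero union-exon length")
    gene_ids <- gene_ids[!bad]; Lv <- Lv[!bad]; counts <- counts[!bad]
  }
  fpkm <- as.numeric(counts) * 1e9 / (Lv * N)
  data.frame(gene_id = gene_ids, tissue = tissue, C = as.integer(counts),
             L = as.integer(Lv), N = N, fpkm = fpkm,
             expressed = fpkm >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify one tissue library end to end
#'
#' Aligns all reads (polyA reads after tail trimming, body reads as-is),
#' assigns fragments and computes FPKM.
#'
#' @param reads named character vector of read sequences.
#' @param annotation parsed annotation.
#' @param index genome index from \code{\link{build_genome_index}}.
#' @param min_tail tail-extraction threshold used before alignment.
#' @param threshold FPKM expressed threshold.
#' @param tissue tissue label.
#' @return data frame as from \code{\link{compute_fpkm}}.
#' @export
quantify_expression <- function(reads, annotation, index, min_tail = 30L,
                                threshold = 1, tissue = NA_character_) {
  ex <- extract_polya_reads(reads, min_tail = min_tail)
  tailed <- setNames(ex$reads$trimmed, ex$reads$read_id)
  body <- reads[!names(reads) %in% ex$reads$read_id]
  al <- align_reads(c(tailed, body), index)
  asg <- assign_fragments(al$alignments, annotation)
  compute_fpkm(asg$counts, annotation, N = asg$n_assigned,
               threshold = threshold, tissue = tissue)
}

#' Partition expressed genes by tissue membership pattern
#'
#' @param records data frame with gene_id, tissue and expressed columns
#'   (rows across all tissues).
#' @return list with \code{membership} (data frame gene_id, pattern:
#'   "+"-joined sorted tissue names) and \code{counts} (named integer per
#'   pattern cell of the 2^k - 1 lattice, zero-filled).
#' @export
tissue_gene_sets <- function(records) {
  tissues <- sort(unique(records$tissue))
  if (length(tissues) < 2L) stop("need at least two tissues")
  r <- records[records$expressed, ]
  pat <- tapply(r$tissue, r$gene_id, function(x) paste(sort(unique(x)), collapse = "+"))
  membership <- data.frame(gene_id = names(pat), pattern = unname(pat),
                           stringsAsFactors = FALSE)
  cells <- unlist(lapply(seq_along(tissues), function(k)
    apply(utils::combn(tissues, k), 2L, paste, collapse = "+")))
  counts <- setNames(integer(length(cells)), cells)
  tab <- table(membership$pattern)
  counts[names(tab)] <- as.integer(tab)
  list(membership = membership, counts = counts)
}
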