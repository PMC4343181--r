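# Promoter extraction (-500..+100 around the TSS, 600 nt), positional
# nucleotide profiles, and 100-nt-bin hexamer enrichment against a
# control promoter set.  The TSS is the annotated gene start (gene_end
# on "-"); offset +1 is the TSS base, so the genomic window on "+" is
# [tss - 500, tss + 99], mapped through the reverse complement on "-".

#' Extract promoter regions
#'
#' @param gene_ids genes to extract (default: all genes in the
#'   annotation).
#' @param annotation parsed annotation.
#' @param genome named character vector of contig sequences.
#' @param exclude_operons drop genes flagged \code{in_operon}.
#' @return list with \code{promoters} (data frame gene_id, sequence; each
#'   sequence exactly 600 nt, transcript orientation) and
#'   \code{n_excluded} (genes whose window ran off a contig edge, plus
#'   operon genes when excluded).
#' @export
extract_promoter_regions <- function(gene_ids = NULL, annotation, genome,
                                     exclude_operons = FALSE) {
  g <- annotation$genes
  if (!is.null(gene_ids)) g <- g[g$gene_id %in% gene_ids, ]
  n_excluded <- 0L
  if (exclude_operons) {
    n_excluded <- n_excluded + sum(g$in_operon)
    g <- g[!g$in_operon, ]
  }
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    tss <- if (g$strand[i] == "+") g$gene_start[i] else g$gene_end[i]
    w <- transcript_window(genome, g$contig[i], g$strand[i], tss, -500L, 99L)
    if (w$n_available < 600L) {
      n_excluded <- n_excluded + 1L
      next
    }
    out[[i]] <- data.frame(gene_id = g$gene_id[i], sequence = w$seq,
                           stringsAsFactors = FALSE)
  }
  promoters <- do.call(rbind, out)
  if (is.null(promoters))
    promoters <- data.frame(gene_id = character(0), sequence = character(0),
                            stringsAsFactors = FALSE)
  list(promoters = promoters, n_excluded = n_excluded)
}

#' Positional nucleotide profile of promoters
#'
#' @param promoters promoter data frame from
#'   \code{\link{extract_promoter_regions}}.
#' @return 4 x 600 matrix of per-position nucleotide frequencies (rows
#'   A/C/G/T, columns -500..-1,+1..+100; each column sums to 1), or NULL
#'   for empty input.
#' @export
positional_nucleotide_profile <- function(promoters) {
  if (nrow(promoters) == 0L) return(NULL)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(promoters$sequence),
                                    baseOnly = TRUE)[DNA_BASES, , drop = FALSE]
  profile <- sweep(cm, 2L, colSums(cm), "/")
  colnames(profile) <- c(-500:-1, 1:100)
  profile
}

# Count hexamer windows per (hexamer, bin) over a promoter set.  Windows
# are counted with overlap; a window belongs to the bin containing its
# first base; windows must fit inside the 600-nt region, so bins 1..5
# hold 100 windows per promoter and bin 6 holds 95.
count_hexamer_windows <- function(promoters, n_bins = 6L) {
  region_len <- 600L
  bin_len <- region_len %/% n_bins
  starts <- seq_len(region_len - 5L)
  bins <- (starts - 1L) %/% bin_len + 1L
  tabs <- data.table::data.table(hexamer = character(0), bin = integer(0),
                                 n = integer(0))
  if (nrow(promoters) > 0L) {
    all_kmers <- lapply(promoters$sequence, function(s)
      substring(s, starts, starts + 5L))
    dt <- data.table::data.table(hexamer = unlist(all_kmers),
                                 bin = rep(bins, nrow(promoters)))
    tabs <- dt[, .(n = .N), by = .(hexamer, bin)]
  }
  windows_per_bin <- tabulate(bins, nbins = n_bins)
  list(counts = tabs, windows_per_bin = windows_per_bin * nrow(promoters))
}

#' Hexamer enrichment per 100-nt promoter bin
#'
#' For each of the 4,096 hexamers in each bin, compares occurrence
#' frequencies (matching windows / total windows in the bin) between a
#' target and a control promoter set: enrichment ratio, two-proportion
#' z-test p-value and Benjamini-Hochberg q-value across all hexamer x
#' bin hypotheses.  Ratios are the primary readout; p/q-values are
#' guardrails.
#'
#' @param target,control promoter data frames (see
#'   \code{\link{extract_promoter_regions}}).
#' @param n_bins number of bins tiling the 600-nt region (default 6).
#' @return data frame: hexamer, bin, target_count, control_count,
#'   target_freq, control_freq, enrichment_ratio, p_value, q_value.
#' @export
hexamer_bin_enrichment <- function(target, control, n_bins = 6L) {
  if (nrow(target) == 0L || nrow(control) == 0L)
    stop("target and control promoter sets must be non-empty")
  if (nrow(control) < nrow(target))
    warning("control set smaller than target set; proceeding with given sizes")
  tc <- count_hexamer_windows(target, n_bins)
  cc <- count_hexamer_windows(control, n_bins)
  hexamers <- Biostrings::mkAllStrings(DNA_BASES, 6L)
  grid <- data.table::CJ(hexamer = hexamers, bin = seq_len(n_bins))
  grid <- merge(grid, tc$counts, by = c("hexamer", "bin"), all.x = TRUE)
  data.table::setnames(grid, "n", "target_count")
  grid <- merge(grid, cc$counts, by = c("hexamer", "bin"), all.x = TRUE)
  data.table::setnames(grid, "n", "control_count")
  grid[is.na(target_count), target_count := 0L]
  grid[is.na(control_count), control_count := 0L]
  n1 <- tc$windows_per_bin[grid$bin]
  n2 <- cc$windows_per_bin[grid$bin]
  x1 <- grid$target_count; x2 <- grid$control_count
  p1 <- x1 / n1; p2 <- x2 / n2
  phat <- (x1 + x2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(hexamer = grid$hexamer, bin = grid$bin,
                    target_count = x1, control_count = x2,
                    target_freq = p1, control_freq = p2,
                    enrichment_ratio = ifelse(p2 > 0, p1 / p2,
                                              ifelse(p1 > 0, Inf, NA_real_)),
                    p_value = p, stringsAsFactors = FALSE)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$q_value, out$p_value, -out$enrichment_ratio), ]
}

#' Fraction of promoters containing TATAA
#'
#' Presence (not multiplicity) of the TATAA box anywhere in the 600-nt
#' promoter region.
#'
#' @param promoters promoter data frame.
#' @param motif the box sequence (default "TATAA").
#' @return fraction in [0, 1].
#' @export
tataa_frequency <- function(promoters, motif = "TATAA") {
  if (nrow(promoters) == 0L) return(0)
  mean(grepl(motif, promoters$sequence, fixed = TRUE))
}
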