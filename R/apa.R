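# Per-tissue 3'UTR isoform catalogs, reference-3'UTRome comparison, and
# tissue-specific APA-switch classification.  Isoform comparisons use
# 3'UTR length (transcript-relative distance from the base after the
# stop codon to the cleavage site), so "+" and "-" strand genes are
# handled uniformly; two sites are "the same" iff their lengths differ
# by at most the matching tolerance (default 10 nt).

#' Build a tissue's 3'UTR isoform catalog
#'
#' One isoform per retained, gene-assigned cluster of a gene expressed
#' (FPKM >= threshold) in that tissue.  Clusters whose representative
#' site falls upstream of the stop codon are flagged invalid and
#' excluded, with a count.
#'
#' @param clusters finalized clusters from \code{\link{map_polya_reads}}.
#' @param annotation parsed annotation.
#' @param expression expression records for the tissue (from
#'   \code{\link{compute_fpkm}}); only genes with \code{expressed = TRUE}
#'   contribute isoforms.
#' @param tissue tissue label stored on the catalog.
#' @return list with \code{isoforms} (data frame: gene_id, tissue,
#'   cleavage_site, utr_length, usage_fraction, source_cluster) and
#'   \code{n_invalid} (clusters upstream of the stop codon).
#' @export
build_isoform_catalog <- function(clusters, annotation, expression,
                                  tissue = NA_character_) {
  g <- annotation$genes
  ok <- clusters$status == "retained" & !is.na(clusters$assigned_gene)
  cl <- clusters[ok, ]
  expressed <- expression$gene_id[expression$expressed]
  cl <- cl[cl$assigned_gene %in% expressed, ]
  gi <- match(cl$assigned_gene, g$gene_id)
  utr_length <- ifelse(g$strand[gi] == "+",
                       cl$representative_site - g$stop_codon_end[gi],
                       g$stop_codon_end[gi] - cl$representative_site)
  invalid <- utr_length < 0L
  iso <- data.frame(gene_id = cl$assigned_gene[!invalid],
                    tissue = rep(tissue, sum(!invalid)),
                    cleavage_site = cl$representative_site[!invalid],
                    utr_length = as.integer(utr_length[!invalid]),
                    usage_fraction = cl$usage_fraction[!invalid],
                    source_cluster = cl$cluster_id[!invalid],
                    stringsAsFactors = FALSE, row.names = NULL)
  # renormalize usage within (gene, tissue) if invalid isoforms were dropped
  if (any(invalid) && nrow(iso) > 0L) {
    tot <- tapply(iso$usage_fraction, iso$gene_id, sum)
    iso$usage_fraction <- iso$usage_fraction / as.numeric(tot[iso$gene_id])
  }
  list(isoforms = iso, n_invalid = sum(invalid))
}

#' Match an isoform catalog against a reference 3'UTRome
#'
#' An isoform matches iff the reference holds an entry for the same gene
#' whose cleavage coordinate is within \code{tolerance} nt.
#'
#' @param isoforms isoform data frame (gene_id, cleavage_site).
#' @param reference data frame (gene_id, cleavage_site).
#' @param tolerance matching tolerance (default 10 nt).
#' @return the isoform data frame with a \code{ref_class} column
#'   ("in_ref"/"novel") plus an attribute \code{summary} = named
#'   proportions.
#' @export
match_reference_utrome <- function(isoforms, reference, tolerance = 10L) {
  matched <- vapply(seq_len(nrow(isoforms)), function(i) {
    rs <- reference$cleavage_site[reference$gene_id == isoforms$gene_id[i]]
    length(rs) > 0L && any(abs(rs - isoforms$cleavage_site[i]) <= tolerance)
  }, logical(1))
  isoforms$ref_class <- ifelse(matched, "in_ref", "novel")
  n <- nrow(isoforms)
  attr(isoforms, "summary") <- c(in_ref = if (n) mean(matched) else NA_real_,
                                 novel = if (n) mean(!matched) else NA_real_)
  isoforms
}

#' 3'UTR length summary statistics
#'
#' Median (lower of the middle pair for even n), arithmetic mean and a
#' fixed-width histogram.
#'
#' @param lengths numeric vector of 3'UTR lengths.
#' @param binwidth histogram bin width (default 50 nt).
#' @return list(median, mean, histogram = data frame(bin_start, count));
#'   an empty input yields \code{list(empty = TRUE)}.
#' @export
utr_length_stats <- function(lengths, binwidth = 50L) {
  if (length(lengths) == 0L) return(list(empty = TRUE))
  s <- sort(lengths)
  med <- s[ceiling(length(s) / 2)]  # lower middle value for even n
  bins <- floor(s / binwidth) * binwidth
  tab <- table(bins)
  list(empty = FALSE, median = med, mean = mean(lengths),
       histogram = data.frame(bin_start = as.integer(names(tab)),
                              count = as.integer(tab), stringsAsFactors = FALSE))
}

#' Distribution of isoform counts per gene
#'
#' @param isoforms isoform data frame for one tissue.
#' @return list(n_genes, n_isoforms, ratio, bins = named counts for genes
#'   with 1 / 2 / >= 3 isoforms).
#' @export
isoform_count_distribution <- function(isoforms) {
  per_gene <- table(isoforms$gene_id)
  bins <- c(`1` = sum(per_gene == 1L), `2` = sum(per_gene == 2L),
            `3+` = sum(per_gene >= 3L))
  n_genes <- length(per_gene)
  list(n_genes = n_genes, n_isoforms = nrow(isoforms),
       ratio = if (n_genes) nrow(isoforms) / n_genes else NA_real_, bins = bins)
}

dominant_isoform <- function(iso) {
  # max usage fraction; deterministic tie-break toward the shorter UTR
  o <- order(-iso$usage_fraction, iso$utr_length)
  iso[o[1], ]
}

#' Classify a pairwise 3'UTR isoform switch
#'
#' Compares the dominant (max usage) isoform of a gene between two
#' tissues.  Lengths within \code{tolerance} are "same"; otherwise the
#' tissue with the shorter dominant 3'UTR is called proximal and the
#' other distal.  The call is confident iff the dominant isoform's usage
#' fraction reaches \code{dominance} in both tissues.
#'
#' @param iso_a,iso_b isoform rows (one gene) for tissues A and B.
#' @param tolerance same-length tolerance (default 10 nt).
#' @param dominance usage-fraction confidence threshold (default 0.6).
#' @return one-row data frame: gene_id, tissue_a, tissue_b, site_a,
#'   site_b, utr_length_a, utr_length_b, class ("same" or
#'   "proximal_in:<tissue>"), proximal_tissue (NA for same), confident.
#' @export
classify_pairwise_switch <- function(iso_a, iso_b, tolerance = 10L,
                                     dominance = 0.6) {
  if (nrow(iso_a) == 0L || nrow(iso_b) == 0L)
    stop("gene absent from one tissue: not comparable")
  stopifnot(length(unique(c(iso_a$gene_id, iso_b$gene_id))) == 1L)
  a <- dominant_isoform(iso_a); b <- dominant_isoform(iso_b)
  same <- abs(a$utr_length - b$utr_length) <= tolerance
  proximal <- if (same) NA_character_ else
    if (a$utr_length < b$utr_length) a$tissue else b$tissue
  data.frame(gene_id = a$gene_id, tissue_a = a$tissue, tissue_b = b$tissue,
             site_a = a$cleavage_site, site_b = b$cleavage_site,
             utr_length_a = a$utr_length, utr_length_b = b$utr_length,
             class = if (same) "same" else paste0("proximal_in:", proximal),
             proximal_tissue = proximal,
             confident = a$usage_fraction >= dominance & b$usage_fraction >= dominance,
             stringsAsFactors = FALSE)
}

#' Pairwise switch table for two tissue catalogs
#'
#' Applies \code{\link{classify_pairwise_switch}} to every gene with at
#' least one isoform in both catalogs.
#'
#' @param cat_a,cat_b isoform data frames for the two tissues.
#' @param tolerance,dominance see \code{\link{classify_pairwise_switch}}.
#' @return data frame with one row per comparable gene.
#' @export
pairwise_switch_table <- function(cat_a, cat_b, tolerance = 10L, dominance = 0.6) {
  genes <- intersect(unique(cat_a$gene_id), unique(cat_b$gene_id))
  rows <- lapply(genes, function(g)
    classify_pairwise_switch(cat_a[cat_a$gene_id == g, ], cat_b[cat_b$gene_id == g, ],
                             tolerance = tolerance, dominance = dominance))
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Three-tissue APA category
#'
#' Builds the pairwise same/different matrix of the gene's dominant
#' 3'UTR lengths across three tissues: all pairs same -> "common"; all
#' pairs different -> "all_distinct"; otherwise the tissue with the
#' largest total distance to the other two is the distinct one and the
#' category is "<tissue>_distinct".
#'
#' @param iso_list named list of three isoform data frames (one gene),
#'   names = tissues.
#' @param tolerance same-length tolerance (default 10 nt).
#' @return character category.
#' @export
classify_three_tissue <- function(iso_list, tolerance = 10L) {
  stopifnot(length(iso_list) == 3L, !is.null(names(iso_list)))
  doms <- lapply(iso_list, dominant_isoform)
  len <- vapply(doms, function(d) d$utr_length, numeric(1))
  tiss <- names(iso_list)
  pairs <- utils::combn(3L, 2L)
  same <- apply(pairs, 2L, function(p) abs(len[p[1]] - len[p[2]]) <= tolerance)
  if (all(same)) return("common")
  if (!any(same)) return("all_distinct")
  tot <- vapply(seq_len(3L), function(i) sum(abs(len[i] - len[-i])), numeric(1))
  paste0(tiss[which.max(tot)], "_distinct")
}

#' Three-tissue category table
#'
#' @param catalogs named list of three isoform data frames (tissues).
#' @param tolerance see \code{\link{classify_three_tissue}}.
#' @return data frame (gene_id, category) over genes with at least one
#'   isoform in every tissue; categories partition that gene set.
#' @export
three_tissue_table <- function(catalogs, tolerance = 10L) {
  stopifnot(length(catalogs) == 3L)
  genes <- Reduce(intersect, lapply(catalogs, function(x) unique(x$gene_id)))
  cat_out <- vapply(genes, function(g) {
    classify_three_tissue(lapply(catalogs, function(x) x[x$gene_id == g, ]),
                          tolerance = tolerance)
  }, character(1))
  data.frame(gene_id = genes, category = unname(cat_out), stringsAsFactors = FALSE)
}
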