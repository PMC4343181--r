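# End-to-end orchestration of the simulated study, plus evaluation
# helpers that compare pipeline output to the generator's ground truth.

#' Run the full APA study on a simulated dataset
#'
#' Generates (or accepts) a simulation, then per tissue: simulates reads,
#' maps polyA reads to clusters, quantifies expression and builds the
#' 3'UTR isoform catalog.  Pairwise switch tables are computed for every
#' tissue pair, and the three-tissue category table when exactly three
#' tissues are configured.
#'
#' @param config a \code{\link{sim_config}}.
#' @param sim optional pre-generated simulation (from
#'   \code{\link{generate_genome_and_annotation}}).
#' @return list: sim, index, per-tissue \code{reads_info} (decoded read
#'   ids), \code{polya} (map_polya_reads output), \code{expression},
#'   \code{catalogs}, plus \code{switches} (list keyed "A|B") and
#'   \code{three_tissue} (or NULL).
#' @export
run_apa_study <- function(config = sim_config(), sim = NULL) {
  if (is.null(sim)) sim <- generate_genome_and_annotation(config)
  index <- build_genome_index(sim$genome)
  tissues <- config$tissue_names
  polya <- list(); expression <- list(); catalogs <- list(); reads_info <- list()
  for (tt in tissues) {
    reads <- simulate_tissue_reads(sim, tt, config)
    reads_info[[tt]] <- parse_read_info(names(reads))
    polya[[tt]] <- map_polya_reads(reads, sim$genome, sim$annotation, index = index)
    expression[[tt]] <- quantify_expression(reads, sim$annotation, index,
                                            tissue = tt)
    catalogs[[tt]] <- build_isoform_catalog(polya[[tt]]$clusters, sim$annotation,
                                            expression[[tt]], tissue = tt)$isoforms
  }
  switches <- list()
  pairs <- utils::combn(tissues, 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    switches[[paste(a, b, sep = "|")]] <-
      pairwise_switch_table(catalogs[[a]], catalogs[[b]])
  }
  three <- if (length(tissues) == 3L) three_tissue_table(catalogs) else NULL
  list(sim = sim, index = index, reads_info = reads_info, polya = polya,
       expression = expression, catalogs = catalogs, switches = switches,
       three_tissue = three)
}

#' Fraction of true cleavage sites recovered by retained clusters
#'
#' A true site (of a gene expressed in at least one tissue) counts as
#' recovered if any tissue's retained cluster representative lies within
#' \code{tol} nt of it.
#'
#' @param study output of \code{\link{run_apa_study}}.
#' @param tol matching tolerance (default 10 nt).
#' @return list(rate, n_sites).
#' @export
evaluate_site_recovery <- function(study, tol = 10L) {
  st <- study$sim$truth$sites
  true_sites <- unique(st[st$abundance > 0,
                          c("gene_id", "contig", "strand", "position")])
  reps <- do.call(rbind, lapply(study$polya, function(p) {
    cl <- p$clusters
    cl[cl$status == "retained", c("contig", "strand", "representative_site")]
  }))
  hit <- vapply(seq_len(nrow(true_sites)), function(i) {
    sel <- reps$contig == true_sites$contig[i] & reps$strand == true_sites$strand[i]
    any(abs(reps$representative_site[sel] - true_sites$position[i]) <= tol)
  }, logical(1))
  list(rate = mean(hit), n_sites = nrow(true_sites))
}

#' Fraction of internal-priming artifact reads removed by the filter
#'
#' Among trap-derived reads that reached the cleavage-event stage,
#' the fraction whose event did not pass \code{filter_internal_priming};
#' also reports retained clusters overlapping any planted trap locus.
#'
#' @param study output of \code{\link{run_apa_study}}.
#' @return list(removal_rate, n_trap_events, trap_clusters_retained).
#' @export
evaluate_priming_removal <- function(study) {
  tp <- study$sim$truth$traps
  removed <- 0L; total <- 0L
  for (tt in names(study$polya)) {
    ev <- study$polya[[tt]]$events
    info <- study$reads_info[[tt]]
    trap_ids <- info$read_id[info$kind == "trap"]
    sel <- ev$read_id %in% trap_ids
    total <- total + sum(sel)
    removed <- removed + sum(ev$filter_reason[sel] != "pass")
  }
  # retained clusters on trap loci (within a read length of a planted run)
  n_on_trap <- 0L
  for (tt in names(study$polya)) {
    cl <- study$polya[[tt]]$clusters
    cl <- cl[cl$status == "retained", ]
    for (i in seq_len(nrow(cl))) {
      near <- tp$contig == cl$contig[i] &
        abs(tp$sense_start - cl$representative_site[i]) <= 150L
      if (any(near)) n_on_trap <- n_on_trap + 1L
    }
  }
  list(removal_rate = if (total > 0L) removed / total else NA_real_,
       n_trap_events = total, trap_clusters_retained = n_on_trap)
}

# Truth dominant site index per (gene, tissue); returns utr_length of the
# dominant planted isoform.
truth_dominant <- function(truth_sites, gene, tissue) {
  r <- truth_sites[truth_sites$gene_id == gene & truth_sites$tissue == tissue &
                     truth_sites$abundance > 0, ]
  if (nrow(r) == 0L) return(NA_real_)
  r$utr_length[which.max(r$usage)]
}

#' Accuracy of pairwise switch calls against planted truth
#'
#' For every gene in every pairwise switch table, the truth label is
#' "same" iff the planted dominant isoform has the same UTR length (+-
#' tol) in both tissues, else proximal in the tissue with the shorter
#' dominant UTR; accuracy is the fraction of calls matching.
#'
#' @param study output of \code{\link{run_apa_study}}.
#' @param tol tolerance used for the truth labels (default 10 nt).
#' @return list(accuracy, n_calls).
#' @export
evaluate_switch_accuracy <- function(study, tol = 10L) {
  st <- study$sim$truth$sites
  good <- 0L; total <- 0L
  for (key in names(study$switches)) {
    tab <- study$switches[[key]]
    if (is.null(tab)) next
    ts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(tab))) {
      la <- truth_dominant(st, tab$gene_id[i], ts[1])
      lb <- truth_dominant(st, tab$gene_id[i], ts[2])
      if (is.na(la) || is.na(lb)) next
      truth_class <- if (abs(la - lb) <= tol) "same" else
        paste0("proximal_in:", if (la < lb) ts[1] else ts[2])
      total <- total + 1L
      if (identical(truth_class, tab$class[i])) good <- good + 1L
    }
  }
  list(accuracy = if (total > 0L) good / total else NA_real_, n_calls = total)
}

#' Mean absolute error of estimated isoform usage fractions
#'
#' Joins retained-cluster usage fractions to planted per-site usage for
#' genes with at least \code{min_reads} polyA reads in a tissue.
#'
#' @param study output of \code{\link{run_apa_study}}.
#' @param min_reads minimum polyA reads per (gene, tissue) (default 50).
#' @param tol site-matching tolerance (default 10 nt).
#' @return list(mae, n_pairs).
#' @export
evaluate_usage_error <- function(study, min_reads = 50L, tol = 10L) {
  st <- study$sim$truth$sites
  errs <- numeric(0)
  for (tt in names(study$polya)) {
    cl <- study$polya[[tt]]$clusters
    cl <- cl[cl$status == "retained" & !is.na(cl$assigned_gene), ]
    per_gene <- tapply(cl$read_count, cl$assigned_gene, sum)
    genes <- names(per_gene)[per_gene >= min_reads]
    for (g in genes) {
      truth <- st[st$gene_id == g & st$tissue == tt & st$abundance > 0, ]
      est <- cl[cl$assigned_gene == g, ]
      if (nrow(truth) == 0L) next
      for (i in seq_len(nrow(truth))) {
        d <- abs(est$representative_site - truth$position[i])
        est_u <- if (any(d <= tol)) sum(est$usage_fraction[d <= tol]) else 0
        errs <- c(errs, abs(est_u - truth$usage[i]))
      }
    }
  }
  list(mae = if (length(errs)) mean(errs) else NA_real_, n_pairs = length(errs))
}
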