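# miRNA-target enrichment of APA-switching gene sets against size-matched
# random gene draws: the observed targeted proportion among switch genes
# is compared to R seeded resamples of the expressed background, with a
# two-tailed one-sample t-test over the resampled proportions and an
# empirical two-tailed permutation p-value (+1 corrected) alongside.

#' Targeted proportion of a gene set
#'
#' Gene ids are collapsed to a set; genes absent from the annotation
#' table are treated as untargeted and counted.
#'
#' @param genes character vector of gene ids (non-empty).
#' @param targets data frame (gene_id, set, targeted).
#' @param set prediction-set name to use.
#' @return list(flags = named logical per unique gene, proportion,
#'   n_unannotated).
#' @export
annotate_targets <- function(genes, targets, set) {
  genes <- unique(genes)
  if (length(genes) == 0L) stop("empty gene set")
  tt <- targets[targets$set == set, ]
  flags <- setNames(tt$targeted[match(genes, tt$gene_id)], genes)
  n_unannotated <- sum(is.na(flags))
  flags[is.na(flags)] <- FALSE
  list(flags = flags, proportion = mean(flags), n_unannotated = n_unannotated)
}

#' Resampling enrichment test for miRNA targets
#'
#' Draws \code{R} seeded random subsets of the background, each the size
#' of the switch-gene set, computes each subset's targeted proportion,
#' and compares the observed proportion against that resampling
#' distribution with (i) a two-tailed one-sample t-test of the resampled
#' proportions against the observed value and (ii) an empirical
#' two-tailed p-value, \code{2 * min(P(draw <= obs), P(draw >= obs))}
#' with a +1 correction, capped at 1.
#'
#' @param switch_genes genes with tissue-specific 3'UTR isoforms.
#' @param background_genes expressed genes to resample from (must be at
#'   least as many as \code{switch_genes}).
#' @param targets data frame (gene_id, set, targeted).
#' @param set prediction-set name.
#' @param R number of resamples (>= 100).
#' @param seed integer seed for the resampler.
#' @return list: n_switch_genes, observed_proportion,
#'   resampled_proportions, mean_control_proportion, p_value (t-test),
#'   empirical_p.
#' @export
enrichment_test <- function(switch_genes, background_genes, targets, set,
                            R = 1000L, seed = 1L) {
  switch_genes <- unique(switch_genes)
  background_genes <- unique(background_genes)
  if (R < 100L) stop("R must be >= 100")
  if (length(background_genes) < length(switch_genes))
    stop("background smaller than switch set")
  obs <- annotate_targets(switch_genes, targets, set)$proportion
  tt <- targets[targets$set == set, ]
  bg_flags <- tt$targeted[match(background_genes, tt$gene_id)]
  bg_flags[is.na(bg_flags)] <- FALSE
  k <- length(switch_genes)
  set.seed(seed)
  draws <- vapply(seq_len(R), function(i) mean(sample(bg_flags, k)), numeric(1))
  p_t <- if (stats::sd(draws) > 0) t.test(draws, mu = obs)$p.value else
    as.numeric(mean(draws) == obs)
  lo <- (1 + sum(draws <= obs)) / (R + 1)
  hi <- (1 + sum(draws >= obs)) / (R + 1)
  p_emp <- min(1, 2 * min(lo, hi))
  list(n_switch_genes = k, observed_proportion = obs,
       resampled_proportions = draws, mean_control_proportion = mean(draws),
       p_value = p_t, empirical_p = p_emp)
}
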