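# Synthetic-data generator: toy genome + annotation + per-tissue polyA+
# reads + ground-truth tables.  The generator plants every signal the
# downstream analyses look for: cleavage sites preceded by an AATAAA-class
# hexamer ending 19 nt upstream, genomically templated A-runs acting as
# internal-priming traps, per-tissue expression and isoform-usage
# differences (APA switches), a promoter hexamer in a chosen 100-nt bin,
# and gene-level miRNA-target labels enriched among switching genes.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' \code{\link{generate_genome_and_annotation}} and
#' \code{\link{simulate_tissue_reads}}.  Defaults describe a compact study:
#' two 200-kb contigs carrying 60 non-overlapping genes profiled in three
#' tissues at 20,000 single-end 100-nt reads per tissue, of which 40\% are
#' polyA-tailed 3'-end reads, 5\% internal-priming artifacts and the rest
#' gene-body reads used for expression quantification.
#'
#' @param seed integer seed; a fixed seed yields byte-identical outputs.
#' @param n_contigs,contig_length genome shape (contigs of equal length, nt).
#' @param n_genes total genes, split evenly across contigs.
#' @param pas_site_probs probabilities of a gene carrying 1, 2 or 3
#'   cleavage sites (named or positional, must sum to 1).
#' @param tissue_names character vector of profiled tissues (>= 2).
#' @param expression_log10_mean,expression_log10_sd parameters of the
#'   log10-normal law for per-(gene,tissue) FPKM-scale abundance.
#' @param tissue_all_prob,tissue_two_prob probability a gene is expressed
#'   in all tissues / in exactly two; the remainder is tissue-unique.
#' @param switch_prob probability that a multi-site gene expressed in
#'   >= 2 tissues is planted as an APA switch (tissue-specific dominant
#'   isoform).
#' @param read_length read length (nt).
#' @param n_reads_per_tissue reads simulated per tissue library.
#' @param frac_tail_reads,frac_trap_reads fraction of reads that are
#'   polyA-tailed 3'-end reads / internal-priming artifact reads; the
#'   remainder are body reads.
#' @param tail_length_range integer c(min, max) untemplated A-tail length;
#'   min must be >= 30 so the tail-extraction rule is exercised exactly.
#' @param error_rate per-base substitution probability outside the A-tail.
#' @param tail_error_rate optional substitution rate inside the tail
#'   (default 0: tails are clean A-runs).
#' @param n_priming_traps number of planted genomic A-runs (half inside
#'   transcripts, half intergenic).
#' @param trap_run_length length of each planted A-run (nt, >= 30).
#' @param canonical_pas_prob probability a planted PAS hexamer is the
#'   canonical AATAAA; otherwise a one-substitution variant is planted.
#' @param promoter_motif,promoter_motif_bin,promoter_motif_fraction hexamer
#'   planted into the given 100-nt promoter bin (1..6 tiling -500..+100)
#'   for the given fraction of genes.
#' @param mirna_target_rates named numeric c(switch=, background=): the
#'   probability a switching / non-switching gene is labelled a miRNA
#'   target in each prediction set.
#' @param mirna_prediction_sets names of simulated target-prediction sets.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 200000L,
                       n_genes = 60L,
                       pas_site_probs = c(0.5, 0.35, 0.15),
                       tissue_names = c("intestine", "pharynx", "body_muscle"),
                       expression_log10_mean = 1.3,
                       expression_log10_sd = 0.4,
                       tissue_all_prob = 0.5,
                       tissue_two_prob = 0.15,
                       switch_prob = 0.5,
                       read_length = 100L,
                       n_reads_per_tissue = 20000L,
                       frac_tail_reads = 0.4,
                       frac_trap_reads = 0.05,
                       tail_length_range = c(30L, 45L),
                       error_rate = 0.002,
                       tail_error_rate = 0,
                       n_priming_traps = 20L,
                       trap_run_length = 35L,
                       canonical_pas_prob = 0.8,
                       promoter_motif = "TGATAA",
                       promoter_motif_bin = 5L,
                       promoter_motif_fraction = 0.4,
                       mirna_target_rates = c(switch = 0.5, background = 0.2),
                       mirna_prediction_sets = c("three_species", "five_species", "footprint")) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
              pas_site_probs = pas_site_probs, tissue_names = tissue_names,
              expression_log10_mean = expression_log10_mean,
              expression_log10_sd = expression_log10_sd,
              tissue_all_prob = tissue_all_prob, tissue_two_prob = tissue_two_prob,
              switch_prob = switch_prob, read_length = as.integer(read_length),
              n_reads_per_tissue = as.integer(n_reads_per_tissue),
              frac_tail_reads = frac_tail_reads, frac_trap_reads = frac_trap_reads,
              tail_length_range = as.integer(tail_length_range),
              error_rate = error_rate, tail_error_rate = tail_error_rate,
              n_priming_traps = as.integer(n_priming_traps),
              trap_run_length = as.integer(trap_run_length),
              canonical_pas_prob = canonical_pas_prob,
              promoter_motif = promoter_motif,
              promoter_motif_bin = as.integer(promoter_motif_bin),
              promoter_motif_fraction = promoter_motif_fraction,
              mirna_target_rates = mirna_target_rates,
              mirna_prediction_sets = mirna_prediction_sets)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$pas_site_probs) == 3L)
  if (abs(sum(cfg$pas_site_probs) - 1) > 1e-9)
    stop("pas_site_probs must sum to 1")
  if (cfg$tail_length_range[1] < 30L)
    stop("tail_length_range minimum must be >= 30 nt")
  if (cfg$tail_length_range[1] > cfg$tail_length_range[2])
    stop("tail_length_range must be increasing")
  if (length(cfg$tissue_names) < 2L) stop("need at least two tissues")
  if (cfg$frac_tail_reads + cfg$frac_trap_reads >= 1)
    stop("tail + trap read fractions must leave room for body reads")
  if (cfg$trap_run_length < 30L) stop("trap_run_length must be >= 30")
  if (nchar(cfg$promoter_motif) != 6L) stop("promoter_motif must be a hexamer")
  if (!cfg$promoter_motif_bin %in% 1:6) stop("promoter_motif_bin must be in 1..6")
  if (cfg$tail_length_range[2] + 18L > cfg$read_length)
    stop("read_length too short for tails plus an alignable remainder")
  invisible(cfg)
}

# Gene structural layout limits used both for generation and for the
# sizing check: reserved promoter margin + max gene footprint + trailing
# room for intergenic traps.
MAX_GENE_LEN <- 700L + 250L + 500L + (150L + 2L * 300L) + 40L
SLOT_OVERHEAD <- 600L + 900L

#' Generate a toy genome, annotation and ground truth
#'
#' Draws a random ACGT genome, places non-overlapping genes (two exons,
#' one intron, a stop codon and 1-3 downstream cleavage sites) on both
#' strands, and plants: a PAS hexamer (canonical AATAAA or a
#' one-substitution variant) ending exactly 19 nt upstream of every
#' cleavage site; a non-A base at each cleavage site so the site is
#' recoverable exactly; A-run internal-priming traps inside transcripts
#' and intergenically; and the configured promoter hexamer into the
#' configured 100-nt bin of a fixed fraction of genes.  Per-tissue
#' expression, isoform-usage mixtures (including planted APA switches) and
#' miRNA-target labels are drawn and recorded in the truth tables.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{genome} (named character vector of
#'   contig sequences), \code{annotation} (see
#'   \code{\link{parse_annotation}}), \code{truth} (list of data frames:
#'   \code{genes}, \code{sites}, \code{traps}, \code{targets}) and
#'   \code{config}.
#' @export
generate_genome_and_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_per <- rep(config$n_genes %/% config$n_contigs, config$n_contigs)
  extra <- config$n_genes %% config$n_contigs
  if (extra > 0L) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
  slot <- ifelse(n_per > 0L, config$contig_length %/% pmax(n_per, 1L), config$contig_length)
  if (any(n_per > 0L & slot < MAX_GENE_LEN + SLOT_OVERHEAD))
    stop("sizing error: contigs too short for the requested number of genes")

  contig_names <- sprintf("ctg%02d", seq_len(config$n_contigs))
  genome <- setNames(vapply(seq_len(config$n_contigs), function(i)
    paste(sample(DNA_BASES, config$contig_length, replace = TRUE), collapse = ""),
    character(1)), contig_names)

  nt <- length(config$tissue_names)
  genes <- list(); exons <- list(); sites <- list(); traps <- list()
  gidx <- 0L
  for (ci in seq_len(config$n_contigs)) {
    for (gi in seq_len(n_per[ci])) {
      gidx <- gidx + 1L
      gene_id <- sprintf("g%03d", gidx)
      slot_start <- (gi - 1L) * slot[ci] + 1L
      strand <- sample(c("+", "-"), 1L)
      exon1_len <- sample(400:700, 1L)
      intron_len <- sample(120:250, 1L)
      pre_stop <- sample(300:500, 1L)
      n_sites <- sample(1:3, 1L, prob = config$pas_site_probs)
      utr1 <- sample(70:150, 1L)
      gaps <- if (n_sites > 1L) sample(150:300, n_sites - 1L, replace = TRUE) else integer(0)
      utrs <- utr1 + cumsum(c(0L, gaps))
      ex2_start <- exon1_len + intron_len + 1L
      stop_local <- ex2_start + pre_stop - 1L
      gene_len <- stop_local + max(utrs) + 40L
      gene_start <- slot_start + 600L + sample(0:150, 1L)
      gene_end <- gene_start + gene_len - 1L
      # transcript-local (unspliced) -> genomic
      gmap <- function(u) if (strand == "+") gene_start + u - 1L else gene_end - u + 1L
      stop_codon_end <- gmap(stop_local)
      ex_local <- rbind(c(1L, exon1_len), c(ex2_start, gene_len))
      ex_gen <- t(apply(ex_local, 1L, function(e) sort(c(gmap(e[1]), gmap(e[2])))))
      # plant cleavage sites + PAS hexamers
      for (k in seq_len(n_sites)) {
        s_local <- stop_local + utrs[k]
        s_gen <- gmap(s_local)
        cleave_base <- sample(c("C", "G", "T"), 1L)
        genome[[ci]] <- plant_sequence(genome[[ci]], min(s_gen, s_gen), strand, cleave_base)
        canonical <- runif(1L) < config$canonical_pas_prob
        hex <- "AATAAA"
        if (!canonical) {
          pos <- sample(1:6, 1L)
          old <- substr(hex, pos, pos)
          substr(hex, pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
        }
        hx_start_local <- s_local - 24L
        hs_gen <- gmap(hx_start_local); he_gen <- gmap(hx_start_local + 5L)
        genome[[ci]] <- plant_sequence(genome[[ci]], min(hs_gen, he_gen), strand, hex)
        sites[[length(sites) + 1L]] <- data.frame(
          gene_id = gene_id, site_index = k, contig = contig_names[ci],
          strand = strand, position = s_gen, utr_length = utrs[k],
          pas_class = if (canonical) "canonical" else "one_permutation",
          pas_hexamer = hex, stringsAsFactors = FALSE)
      }
      genes[[gidx]] <- data.frame(
        gene_id = gene_id, contig = contig_names[ci], strand = strand,
        gene_start = gene_start, gene_end = gene_end,
        stop_codon_end = stop_codon_end, has_stop = TRUE, in_operon = FALSE,
        exon1_len = exon1_len, n_sites = n_sites, stringsAsFactors = FALSE)
      exons[[gidx]] <- data.frame(
        gene_id = gene_id, contig = contig_names[ci], strand = strand,
        start = ex_gen[, 1], end = ex_gen[, 2], stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  sites <- do.call(rbind, sites)

  # --- internal-priming traps: A-runs in transcript sense orientation ---
  n_tx_traps <- config$n_priming_traps %/% 2L
  tx_hosts <- if (n_tx_traps > 0L)
    sample(genes$gene_id, min(n_tx_traps, nrow(genes))) else character(0)
  run <- strrep("A", config$trap_run_length)
  tid <- 0L
  for (g in tx_hosts) {
    tid <- tid + 1L
    grow <- genes[genes$gene_id == g, ]
    u0 <- sample(100:(grow$exon1_len - config$trap_run_length - 10L), 1L)
    gmapg <- function(u) if (grow$strand == "+") grow$gene_start + u - 1L else grow$gene_end - u + 1L
    a <- gmapg(u0); b <- gmapg(u0 + config$trap_run_length - 1L)
    guard <- gmapg(u0 - 1L)
    ciname <- grow$contig
    genome[[ciname]] <- plant_sequence(genome[[ciname]], min(a, b), grow$strand, run)
    genome[[ciname]] <- plant_sequence(genome[[ciname]], guard, grow$strand, "C")
    traps[[tid]] <- data.frame(trap_id = sprintf("trap%02d", tid), contig = ciname,
                               strand = grow$strand, sense_start = a,
                               run_length = config$trap_run_length,
                               kind = "transcript", host_gene = g,
                               stringsAsFactors = FALSE)
  }
  n_ig <- config$n_priming_traps - length(tx_hosts)
  ig_hosts <- if (n_ig > 0L) sample(genes$gene_id, min(n_ig, nrow(genes))) else character(0)
  for (g in ig_hosts) {
    tid <- tid + 1L
    grow <- genes[genes$gene_id == g, ]
    strand <- sample(c("+", "-"), 1L)
    gs <- grow$gene_end + 700L  # clear of the gene and its neighbours' promoters
    ge <- gs + config$trap_run_length - 1L
    ciname <- grow$contig
    genome[[ciname]] <- plant_sequence(genome[[ciname]], gs, strand, run)
    sense_start <- if (strand == "+") gs else ge
    guard <- if (strand == "+") gs - 1L else ge + 1L
    genome[[ciname]] <- plant_sequence(genome[[ciname]], guard, strand, "C")
    traps[[tid]] <- data.frame(trap_id = sprintf("trap%02d", tid), contig = ciname,
                               strand = strand, sense_start = sense_start,
                               run_length = config$trap_run_length,
                               kind = "intergenic", host_gene = NA_character_,
                               stringsAsFactors = FALSE)
  }
  traps <- if (tid > 0L) do.call(rbind, traps) else
    data.frame(trap_id = character(0), contig = character(0), strand = character(0),
               sense_start = integer(0), run_length = integer(0),
               kind = character(0), host_gene = character(0), stringsAsFactors = FALSE)

  # --- planted promoter motif: exact fraction of genes, chosen bin ---
  n_carriers <- round(config$promoter_motif_fraction * nrow(genes))
  carriers <- sample(genes$gene_id, n_carriers)
  genes$carries_planted_motif <- genes$gene_id %in% carriers
  bin_lo <- (config$promoter_motif_bin - 1L) * 100L + 1L
  for (g in carriers) {
    grow <- genes[genes$gene_id == g, ]
    w0 <- sample(bin_lo:(bin_lo + 94L), 1L)  # hexamer fits within the bin
    tss <- if (grow$strand == "+") grow$gene_start else grow$gene_end
    if (grow$strand == "+") {
      gs <- tss - 501L + w0
    } else {
      gs <- tss + 501L - (w0 + 5L)
    }
    genome[[grow$contig]] <- plant_sequence(genome[[grow$contig]], gs, grow$strand,
                                            config$promoter_motif)
  }

  # --- per-tissue expression, usage mixtures, switch flags ---
  usage_rows <- list()
  genes$is_switch <- FALSE
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    r <- runif(1L)
    expressed_in <- if (r < config$tissue_all_prob) {
      config$tissue_names
    } else if (r < config$tissue_all_prob + config$tissue_two_prob) {
      sample(config$tissue_names, 2L)
    } else {
      sample(config$tissue_names, 1L)
    }
    ns <- genes$n_sites[i]
    is_switch <- ns > 1L && length(expressed_in) >= 2L && runif(1L) < config$switch_prob
    genes$is_switch[i] <- is_switch
    distinct_tissue <- if (is_switch) sample(expressed_in, 1L) else NA_character_
    for (tt in config$tissue_names) {
      abundance <- if (tt %in% expressed_in)
        10^rnorm(1L, config$expression_log10_mean, config$expression_log10_sd) else 0
      usage <- if (ns == 1L) 1 else if (ns == 2L) {
        if (is_switch && identical(tt, distinct_tissue)) c(0.2, 0.8) else c(0.75, 0.25)
      } else {
        if (is_switch && identical(tt, distinct_tissue)) c(0.1, 0.3, 0.6) else c(0.6, 0.3, 0.1)
      }
      usage_rows[[length(usage_rows) + 1L]] <- data.frame(
        gene_id = g, tissue = tt, site_index = seq_len(ns),
        usage = usage, abundance = abundance, stringsAsFactors = FALSE)
    }
  }
  usage <- do.call(rbind, usage_rows)
  site_truth <- merge(usage, sites, by = c("gene_id", "site_index"), sort = FALSE)
  site_truth <- site_truth[order(site_truth$gene_id, site_truth$tissue,
                                 site_truth$site_index), ]
  rownames(site_truth) <- NULL

  # --- miRNA-target labels per prediction set ---
  target_rows <- list()
  for (ps in config$mirna_prediction_sets) {
    rate <- ifelse(genes$is_switch, config$mirna_target_rates[["switch"]],
                   config$mirna_target_rates[["background"]])
    target_rows[[ps]] <- data.frame(gene_id = genes$gene_id, set = ps,
                                    targeted = runif(nrow(genes)) < rate,
                                    stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, target_rows)
  rownames(targets) <- NULL

  annotation <- new_annotation(
    genes[, c("gene_id", "contig", "strand", "gene_start", "gene_end",
              "stop_codon_end", "has_stop", "in_operon")],
    exons[, c("gene_id", "contig", "strand", "start", "end")])
  truth <- list(genes = genes, sites = site_truth, traps = traps, targets = targets)
  list(genome = genome, annotation = annotation, truth = truth, config = config)
}

# Apply per-base substitutions at `rate` to reads (character vector),
# restricted to the first `protect_from[i]-1` bases when protect_from is
# given (used to keep untemplated tails clean).
apply_substitutions <- function(seqs, rate, protect_from = NULL) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- if (is.null(protect_from)) nchar(seqs) else pmin(nchar(seqs), protect_from - 1L)
  nmut <- rbinom(length(seqs), lens, rate)
  for (i in which(nmut > 0L)) {
    pos <- sample.int(lens[i], nmut[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Simulate one tissue's read library
#'
#' Draws polyA-tailed 3'-end reads per gene proportionally to abundance
#' and per-site usage (each terminating at a true cleavage site with an
#' untemplated A-tail), gene-body reads proportional to abundance times
#' spliced length (for FPKM estimation), and internal-priming artifact
#' reads whose terminal A-run is genomically templated from a planted
#' trap.  Substitution errors are applied outside the untemplated tail.
#'
#' @param sim output of \code{\link{generate_genome_and_annotation}}.
#' @param tissue tissue name (must be in \code{config$tissue_names}).
#' @param config a \code{\link{sim_config}}; defaults to the one inside
#'   \code{sim}.
#' @return named character vector of read sequences; names are read ids of
#'   the form \code{id|kind|gene_or_trap|site}, so every read traces to
#'   exactly one (gene, site) or one trap (see
#'   \code{\link{parse_read_info}}).
#' @export
simulate_tissue_reads <- function(sim, tissue, config = sim$config) {
  ti <- match(tissue, config$tissue_names)
  if (is.na(ti)) stop("unknown tissue: ", tissue)
  set.seed(derive_seed(config$seed, ti))
  rl <- config$read_length
  n_trap <- round(config$n_reads_per_tissue * config$frac_trap_reads)
  if (nrow(sim$truth$traps) == 0L) n_trap <- 0L
  n_tail <- round(config$n_reads_per_tissue * config$frac_tail_reads)
  n_body <- config$n_reads_per_tissue - n_tail - n_trap

  st <- sim$truth$sites
  st <- st[st$tissue == tissue & st$abundance > 0, ]
  w_site <- st$abundance * st$usage

  # polyA-tailed reads ending at a true cleavage site
  pick <- sample.int(nrow(st), n_tail, replace = TRUE, prob = w_site)
  tails <- sample(config$tail_length_range[1]:config$tail_length_range[2],
                  n_tail, replace = TRUE)
  body_len <- rl - tails
  r <- st[pick, ]
  gs <- ifelse(r$strand == "+", r$position - (body_len - 1L), r$position)
  ge <- ifelse(r$strand == "+", r$position, r$position + body_len - 1L)
  tail_seqs <- substring(sim$genome[r$contig], gs, ge)
  neg <- r$strand == "-"
  if (any(neg)) tail_seqs[neg] <- revcomp(tail_seqs[neg])
  tail_seqs <- apply_substitutions(tail_seqs, config$error_rate)
  tail_part <- strrep("A", tails)
  if (config$tail_error_rate > 0)
    tail_part <- apply_substitutions(tail_part, config$tail_error_rate)
  tail_reads <- paste0(tail_seqs, tail_part)
  tail_ids <- sprintf("t%dr%06d|tail|%s|%d", ti, seq_len(n_tail),
                      st$gene_id[pick], st$position[pick])

  # body reads: gene weighted by abundance x spliced length, exon-contained
  ex <- sim$annotation$exons
  ex$len <- ex$end - ex$start + 1L
  ex <- ex[ex$len >= rl, ]
  ab <- unique(st[, c("gene_id", "abundance")])
  ex <- merge(ex, ab, by = "gene_id")
  spl <- tapply(ex$len, ex$gene_id, sum)
  gene_w <- ab$abundance * as.numeric(spl[ab$gene_id])
  gpick <- sample.int(nrow(ab), n_body, replace = TRUE, prob = gene_w)
  body_gene <- ab$gene_id[gpick]
  ex_split <- split(ex, ex$gene_id)
  b_contig <- character(n_body); b_strand <- character(n_body); b_gs <- integer(n_body)
  for (i in seq_len(n_body)) {
    exg <- ex_split[[body_gene[i]]]
    wj <- exg$len - rl + 1L
    j <- if (nrow(exg) == 1L) 1L else sample.int(nrow(exg), 1L, prob = wj)
    off <- sample.int(wj[j], 1L)
    b_contig[i] <- exg$contig[j]; b_strand[i] <- exg$strand[j]
    b_gs[i] <- exg$start[j] + off - 1L
  }
  body_reads <- substring(sim$genome[b_contig], b_gs, b_gs + rl - 1L)
  bneg <- b_strand == "-"
  if (any(bneg)) body_reads[bneg] <- revcomp(body_reads[bneg])
  body_reads <- apply_substitutions(body_reads, config$error_rate)
  body_ids <- sprintf("t%dr%06d|body|%s|NA", ti, n_tail + seq_len(n_body), body_gene)

  # internal-priming artifact reads: end 30..run_length into a planted A-run
  trap_reads <- character(n_trap); trap_ids <- character(n_trap)
  if (n_trap > 0L) {
    tp <- sim$truth$traps
    tpick <- sample.int(nrow(tp), n_trap, replace = TRUE)
    endoff <- sample(30:config$trap_run_length, n_trap, replace = TRUE)
    tr <- tp[tpick, ]
    anchor <- ifelse(tr$strand == "+", tr$sense_start + endoff - 1L,
                     tr$sense_start - endoff + 1L)
    tgs <- ifelse(tr$strand == "+", anchor - (rl - 1L), anchor)
    tge <- ifelse(tr$strand == "+", anchor, anchor + rl - 1L)
    trap_reads <- substring(sim$genome[tr$contig], tgs, tge)
    tneg <- tr$strand == "-"
    if (any(tneg)) trap_reads[tneg] <- revcomp(trap_reads[tneg])
    trap_reads <- apply_substitutions(trap_reads, config$error_rate,
                                      protect_from = rl - endoff + 1L)
    trap_ids <- sprintf("t%dr%06d|trap|%s|NA", ti, n_tail + n_body + seq_len(n_trap),
                        tp$trap_id[tpick])
  }

  setNames(c(tail_reads, body_reads, trap_reads), c(tail_ids, body_ids, trap_ids))
}

#' Decode simulated read ids
#'
#' @param ids character vector of read ids produced by
#'   \code{\link{simulate_tissue_reads}}.
#' @return data frame with columns read_id, kind (tail/body/trap), origin
#'   (gene or trap id) and site (true cleavage position, NA for body/trap).
#' @export
parse_read_info <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed read id(s): ", ids[which(bad)[1]])
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(read_id = ids, kind = m[, 2], origin = m[, 3],
             site = suppressWarnings(as.integer(m[, 4])), stringsAsFactors = FALSE)
}

#' Write / read ground-truth tables
#'
#' @param truth the \code{truth} list from
#'   \code{\link{generate_genome_and_annotation}}.
#' @param dir output directory (created if needed).
#' @return \code{write_truth_tables} returns the written file paths
#'   invisibly; \code{read_truth_tables} returns the truth list.
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("genes", "sites", "traps", "targets")) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    write.table(truth[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' @rdname write_truth_tables
#' @export
read_truth_tables <- function(dir) {
  out <- list()
  for (nm in c("genes", "sites", "traps", "targets")) {
    out[[nm]] <- read.delim(file.path(dir, paste0("truth_", nm, ".tsv")),
                            stringsAsFactors = FALSE)
  }
  out
}

#' Simulate a miRNA target-prediction table
#'
#' Standalone generator for gene -> targeted flags: switch genes are
#' targeted at one rate, all other genes at a background rate.
#'
#' @param genes character vector of gene ids.
#' @param switch_genes subset of \code{genes} labelled as APA-switching.
#' @param rates named numeric c(switch=, background=).
#' @param sets prediction-set names.
#' @param seed integer seed.
#' @return data frame (gene_id, set, targeted).
#' @export
simulate_target_annotation <- function(genes, switch_genes,
                                       rates = c(switch = 0.5, background = 0.2),
                                       sets = "three_species", seed = 1L) {
  set.seed(seed)
  out <- lapply(sets, function(ps) {
    rate <- ifelse(genes %in% switch_genes, rates[["switch"]], rates[["background"]])
    data.frame(gene_id = genes, set = ps, targeted = runif(length(genes)) < rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a complete simulated dataset to disk
#'
#' Emits genome FASTA, annotation GFF3, one FASTQ per tissue and the four
#' truth TSVs.  Outputs are byte-identical for a fixed seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir output directory.
#' @return the in-memory simulation object (invisibly), with an added
#'   \code{files} element listing written paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome_and_annotation(config)
  fa <- file.path(outdir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), fa)
  gff <- file.path(outdir, "annotation.gff3")
  write_annotation_gff3(sim$annotation, gff)
  fq <- character(0)
  for (tt in config$tissue_names) {
    reads <- simulate_tissue_reads(sim, tt, config)
    p <- file.path(outdir, paste0("reads_", tt, ".fastq"))
    write_reads_fastq(reads, p)
    fq[tt] <- p
  }
  truth_paths <- write_truth_tables(sim$truth, outdir)
  sim$files <- list(genome = fa, annotation = gff, reads = fq, truth = truth_paths)
  invisible(sim)
}
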