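# PolyA extraction, cleavage mapping, priming filters, clustering,
# gene assignment and cluster filters: strict boundary behaviour as
# printed, plus oracle equivalence and conservation.

test_that("tail extraction keeps >=30-A tails, trims them, drops degenerates", {
  r30 <- paste0(strrep("CGT", 13), "C", strrep("A", 30))   # 70 nt, exactly 30 A
  r29 <- paste0(strrep("CGT", 13), "CA", strrep("A", 29))  # wait: avoid merging
  r29 <- paste0(strrep("CGT", 13), "CG", strrep("A", 29))  # 29-A tail
  rall <- strrep("A", 40)
  rbad <- paste0(strrep("C", 40), "X", strrep("A", 31))
  out <- extract_polya_reads(setNames(c(r30, r29, rall, rbad),
                                      c("r30", "r29", "rall", "rbad")))
  expect_identical(out$reads$read_id, "r30")
  expect_identical(out$reads$tail_length, 30L)
  expect_identical(nchar(out$reads$trimmed), 40L)
  expect_identical(unname(out$accounting),
                   c(1L, 1L, 1L, 1L))  # retained, no_tail, too_short, non_acgt
})

test_that("tail extraction equals the exhaustive suffix-scan oracle", {
  set.seed(7L)
  reads <- random_reads(2000L)
  out <- extract_polya_reads(reads)
  oracle_runs <- vapply(reads, oracle_terminal_a_run, integer(1))
  oracle_keep <- names(reads)[oracle_runs >= 30L &
                                (nchar(reads) - oracle_runs) >= 18L]
  expect_identical(out$reads$read_id, oracle_keep)
  expect_identical(out$reads$tail_length, unname(oracle_runs[oracle_keep]))
})

test_that("cleavage position is the transcript 3' end on either strand", {
  aln <- data.frame(read_id = c("p", "m"), contig = "c", strand = c("+", "-"),
                    pos = c(1000L, 1000L), span = c(40L, 40L),
                    longest_consecutive_match = 40L, stringsAsFactors = FALSE)
  ev <- compute_cleavage_site(aln)
  expect_identical(ev$cleavage_position, c(1039L, 1000L))
})

test_that("internal-priming filter applies the printed boundaries strictly", {
  # layout: cleavage at 100; downstream window 101..130, upstream 70..99
  mkgen <- function(dn_a, up_a) {
    dn <- paste(c(rep("A", dn_a), rep("C", 30L - dn_a)), collapse = "")
    up <- paste(c(rep("C", 30L - up_a), rep("A", up_a)), collapse = "")
    c(ctg = paste0(strrep("G", 69), up, "T", dn, strrep("G", 100)))
  }
  ev <- function(lcm) data.frame(read_id = "x", contig = "ctg", strand = "+",
                                 cleavage_position = 100L,
                                 longest_consecutive_match = lcm,
                                 stringsAsFactors = FALSE)
  # 20/30 = 66.7% downstream A -> fail
  expect_identical(filter_internal_priming(ev(40L), mkgen(20L, 0L))$filter_reason,
                   "a_rich_downstream")
  # 19/30 = 63.3% in both windows, consecutive match 18 -> pass
  expect_identical(filter_internal_priming(ev(18L), mkgen(19L, 19L))$filter_reason,
                   "pass")
  # upstream-only A-richness also fails ("either direction")
  expect_identical(filter_internal_priming(ev(40L), mkgen(0L, 20L))$filter_reason,
                   "a_rich_upstream")
  # consecutive match 17 -> fail
  expect_identical(filter_internal_priming(ev(17L), mkgen(0L, 0L))$filter_reason,
                   "short_match")
  # exact 65% fails (>= threshold); achieved via an edge-truncated window
  # of 20 available bases containing 13 A
  g65 <- c(ctg = paste0(strrep("G", 69), strrep("C", 30), "T",
                        strrep("A", 13), strrep("C", 7)))  # contig ends at 120
  expect_identical(filter_internal_priming(ev(40L), g65)$filter_reason,
                   "a_rich_downstream")
  # minus-strand windows count sense-strand A (genomic T)
  evm <- data.frame(read_id = "x", contig = "ctg", strand = "-",
                    cleavage_position = 100L, longest_consecutive_match = 40L,
                    stringsAsFactors = FALSE)
  gm <- c(ctg = paste0(strrep("G", 69), strrep("T", 30), "A", strrep("G", 130)))
  expect_identical(filter_internal_priming(evm, gm)$filter_reason,
                   "a_rich_downstream")
})

test_that("windows truncated at contig edges use available bases only", {
  g <- c(ctg = paste0("T", strrep("A", 10), strrep("C", 60)))
  ev <- data.frame(read_id = "x", contig = "ctg", strand = "+",
                   cleavage_position = 1L, longest_consecutive_match = 40L,
                   stringsAsFactors = FALSE)
  # upstream window has zero available bases -> does not fail; downstream
  # holds 10 A / 30 = 33% -> pass
  expect_identical(filter_internal_priming(ev, g)$filter_reason, "pass")
  g2 <- c(ctg = paste0("T", strrep("A", 30), strrep("C", 40)))
  expect_identical(filter_internal_priming(ev, g2)$filter_reason,
                   "a_rich_downstream")
})

test_that("single-linkage clustering follows the worked examples", {
  ev <- function(pos, strand = "+")
    data.frame(contig = "c", strand = strand, cleavage_position = pos,
               stringsAsFactors = FALSE)
  cl <- cluster_cleavage_sites(ev(c(100L, 101L, 101L, 103L, 200L)))
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$representative_site, c(101L, 200L))  # modal member
  expect_identical(cl$read_count, c(4L, 1L))
  expect_identical(cl$span_start, c(100L, 200L))
  # gap 26 > 25 splits
  expect_identical(nrow(cluster_cleavage_sites(ev(c(100L, 126L)))), 2L)
  expect_identical(nrow(cluster_cleavage_sites(ev(c(100L, 125L)))), 1L)
  # modal tie broken toward the transcript 3'-most position
  tie <- cluster_cleavage_sites(ev(c(10L, 10L, 20L, 20L)))
  expect_identical(tie$representative_site, 20L)
  tie_m <- cluster_cleavage_sites(ev(c(10L, 10L, 20L, 20L), strand = "-"))
  expect_identical(tie_m$representative_site, 10L)
})

test_that("clustering matches a transitive-closure oracle and is order-invariant", {
  set.seed(21L)
  pos <- sample(1:2000, 150L, replace = TRUE)
  ev <- data.frame(contig = "c", strand = "+", cleavage_position = pos,
                   stringsAsFactors = FALSE)
  cl <- cluster_cleavage_sites(ev, max_gap = 25L)
  got <- lapply(seq_len(nrow(cl)), function(i)
    sort(pos[pos >= cl$span_start[i] & pos <= cl$span_end[i]]))
  want <- oracle_single_linkage(pos, 25L)
  expect_identical(got[order(vapply(got, min, integer(1)))],
                   unname(want[order(vapply(want, min, integer(1)))]))
  # permutation invariance
  ev2 <- ev[sample(nrow(ev)), ]
  cl2 <- cluster_cleavage_sites(ev2, max_gap = 25L)
  expect_identical(cl[, -1], cl2[, -1])
  # idempotence: clustering the representatives leaves them separate singletons
  ev3 <- data.frame(contig = "c", strand = "+",
                    cleavage_position = cl$representative_site,
                    stringsAsFactors = FALSE)
  expect_identical(nrow(cluster_cleavage_sites(ev3, max_gap = 25L)), nrow(cl))
})

test_that("gene attachment respects range, orientation and the tie rule", {
  genes <- make_genes(gene_id = c("up", "dn"), contig = "c", strand = "+",
                      gene_start = c(1000L, 9000L), gene_end = c(2000L, 9900L),
                      stop_codon_end = c(1800L, 9700L))
  ann <- make_annotation(genes)
  mk <- function(site, strand = "+")
    data.frame(cluster_id = "cl1", contig = "c", strand = strand,
               representative_site = site, span_start = site, span_end = site,
               read_count = 10L, stringsAsFactors = FALSE)
  # within 1,600 nt downstream of gene end -> attached at distance 0..n
  expect_identical(assign_clusters_to_genes(mk(3600L), ann)$assigned_gene, "up")
  # 1,601 nt downstream of the only in-range gene 3' end -> still inside
  # [stop, end+1600] fails only beyond 2000 + 1600
  got <- assign_clusters_to_genes(mk(3601L), ann)
  expect_identical(got$assigned_gene, "up")
  expect_identical(got$distance_to_gene, 1L)
  # truly out of range on both sides -> unassigned
  far <- assign_clusters_to_genes(mk(5300L), ann)
  expect_true(is.na(far$assigned_gene))
  # opposite-strand gene never captures the cluster
  gm <- make_genes(gene_id = "rev", contig = "c", strand = "-",
                   gene_start = 3000L, gene_end = 4000L, stop_codon_end = 3200L)
  both <- make_annotation(rbind(genes, gm))
  expect_identical(assign_clusters_to_genes(mk(2900L), both)$assigned_gene, "up")
  expect_identical(assign_clusters_to_genes(mk(2900L, "-"), both)$assigned_gene,
                   "rev")
  # exact tie -> the gene whose 3' terminus is nearest upstream of the site:
  # at max_distance 4000, up's interval ends at 6000 and dn's starts at 9700,
  # so site 7850 is 1850 from both; the upstream gene wins
  tie <- assign_clusters_to_genes(mk(7850L), ann, max_distance = 4000L)
  expect_identical(tie$assigned_gene, "up")
  expect_identical(tie$distance_to_gene, 1850L)
})

test_that("cluster usage and footprint filters use strict printed boundaries", {
  # genome: footprints all C except where planted
  genome <- c(c = paste(rep("C", 12000), collapse = ""))
  base <- data.frame(contig = "c", strand = "+", read_count = c(96L, 4L),
                     cluster_id = c("a", "b"),
                     representative_site = c(1000L, 1500L),
                     span_start = c(1000L, 1500L), span_end = c(1000L, 1500L),
                     assigned_gene = "g1", stringsAsFactors = FALSE)
  out <- filter_clusters(base, genome)
  expect_identical(out$status, c("retained", "filtered:low_usage"))
  expect_equal(out$usage_fraction[1], 1)
  # usage exactly 5% is retained (filtered iff < 0.05)
  base$read_count <- c(95L, 5L)
  out2 <- filter_clusters(base, genome)
  expect_identical(out2$status, c("retained", "retained"))
  expect_equal(sum(out2$usage_fraction), 1)
  # footprint 41% A filtered, 40% retained (filtered iff > 0.40)
  g41 <- c(c = paste0(strrep("C", 999), paste(c(rep("A", 41), rep("C", 59)),
                                              collapse = ""), strrep("C", 11000)))
  g40 <- c(c = paste0(strrep("C", 999), paste(c(rep("A", 40), rep("C", 60)),
                                              collapse = ""), strrep("C", 11000)))
  span100 <- data.frame(contig = "c", strand = "+", read_count = 50L,
                        cluster_id = "a", representative_site = 1050L,
                        span_start = 1000L, span_end = 1099L,
                        assigned_gene = "g1", stringsAsFactors = FALSE)
  expect_identical(filter_clusters(span100, g41)$status, "filtered:a_rich_footprint")
  expect_identical(filter_clusters(span100, g40)$status, "retained")
})

test_that("usage fractions renormalize to 1 after filtering", {
  genome <- c(c = paste(rep("C", 9000), collapse = ""))
  cl <- data.frame(contig = "c", strand = "+",
                   read_count = c(60L, 37L, 3L),
                   cluster_id = c("a", "b", "d"),
                   representative_site = c(1000L, 2000L, 3000L),
                   span_start = c(1000L, 2000L, 3000L),
                   span_end = c(1000L, 2000L, 3000L),
                   assigned_gene = "g1", stringsAsFactors = FALSE)
  out <- filter_clusters(cl, genome)
  expect_identical(out$status, c("retained", "retained", "filtered:low_usage"))
  kept <- out$usage_fraction[out$status == "retained"]
  expect_equal(sum(kept), 1, tolerance = 1e-9)
  expect_equal(kept, c(60, 37) / 97)
})

test_that("every read is accounted for exactly once end to end", {
  sim <- get_small_sim()
  reads <- simulate_tissue_reads(sim, sim$config$tissue_names[1])
  res <- map_polya_reads(reads, sim$genome, sim$annotation,
                         index = get_small_index())
  expect_identical(sum(res$accounting), length(reads))
  expect_true(all(res$accounting >= 0L))
})
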