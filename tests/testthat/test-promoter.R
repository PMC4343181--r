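# Promoter extraction, positional profiles and binned hexamer enrichment.

test_that("promoter window is -500..+100 around the TSS with +1 = TSS", {
  set.seed(51L)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g <- c(ctg = contig)
  ann <- make_annotation(make_genes(gene_id = "gA", contig = "ctg",
                                    strand = "+", gene_start = 1001L,
                                    gene_end = 2000L, stop_codon_end = 1900L))
  out <- extract_promoter_regions(annotation = ann, genome = g)
  expect_identical(nchar(out$promoters$sequence), 600L)
  # + strand TSS at 1001 -> genomic window 501..1100
  expect_identical(out$promoters$sequence, substr(contig, 501, 1100))
  # - strand gene: reverse complement of the mirrored window
  annm <- make_annotation(make_genes(gene_id = "gB", contig = "ctg",
                                     strand = "-", gene_start = 1001L,
                                     gene_end = 2000L, stop_codon_end = 1100L))
  outm <- extract_promoter_regions(annotation = annm, genome = g)
  expect_identical(outm$promoters$sequence,
                   apamap:::revcomp(substr(contig, 1901, 2500)))
})

test_that("genes whose window leaves the contig are excluded and counted", {
  g <- c(ctg = strrep("ACGT", 500))
  ann <- make_annotation(make_genes(gene_id = c("edge", "ok"), contig = "ctg",
                                    strand = "+", gene_start = c(300L, 900L),
                                    gene_end = c(700L, 1300L),
                                    stop_codon_end = c(600L, 1200L)))
  out <- extract_promoter_regions(annotation = ann, genome = g)
  expect_identical(out$promoters$gene_id, "ok")
  expect_identical(out$n_excluded, 1L)
  # operon exclusion flag
  ann$genes$in_operon <- c(FALSE, TRUE)
  out2 <- extract_promoter_regions(annotation = ann, genome = g,
                                   exclude_operons = TRUE)
  expect_identical(nrow(out2$promoters), 0L)
  expect_identical(out2$n_excluded, 2L)
})

test_that("positional profile columns sum to 1 and match uniform sampling", {
  set.seed(52L)
  n <- 1000L
  proms <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                      sequence = vapply(seq_len(n), function(i)
                        paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                              collapse = ""), character(1)),
                      stringsAsFactors = FALSE)
  prof <- positional_nucleotide_profile(proms)
  expect_identical(dim(prof), c(4L, 600L))
  expect_equal(unname(colSums(prof)), rep(1, 600))
  expect_true(all(abs(prof - 0.25) < 0.05))
  expect_null(positional_nucleotide_profile(proms[0, ]))
})

test_that("hexamer window counts conserve totals per bin", {
  set.seed(53L)
  n <- 20L
  proms <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                      sequence = vapply(seq_len(n), function(i)
                        paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                              collapse = ""), character(1)),
                      stringsAsFactors = FALSE)
  cnt <- apamap:::count_hexamer_windows(proms)
  # start-assigned windows: bins 1..5 hold 100 per promoter, bin 6 holds 95
  expect_identical(cnt$windows_per_bin, as.integer(c(rep(100, 5), 95) * n))
  per_bin <- tapply(cnt$counts$n, cnt$counts$bin, sum)
  expect_identical(as.integer(per_bin), cnt$windows_per_bin)
})

test_that("an A-run of 7 contributes two overlapping AAAAAA windows", {
  proms <- data.frame(gene_id = "g1",
                      sequence = paste0(strrep("C", 100), strrep("A", 7),
                                        strrep("C", 493)),
                      stringsAsFactors = FALSE)
  cnt <- apamap:::count_hexamer_windows(proms)$counts
  expect_identical(cnt$n[cnt$hexamer == "AAAAAA"], 2L)
  expect_identical(unique(cnt$bin[cnt$hexamer == "AAAAAA"]), 2L)
})

test_that("target == control gives unit ratios and no spurious discoveries", {
  set.seed(54L)
  proms <- data.frame(gene_id = sprintf("g%02d", 1:15),
                      sequence = vapply(1:15, function(i)
                        paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                              collapse = ""), character(1)),
                      stringsAsFactors = FALSE)
  enr <- hexamer_bin_enrichment(proms, proms)
  seen <- enr[enr$target_count > 0, ]
  expect_true(all(seen$enrichment_ratio == 1))
  expect_true(all(enr$p_value == 1 | is.na(enr$enrichment_ratio)))
  expect_identical(nrow(enr), 4096L * 6L)
})

test_that("q-values are BH-monotone and the z-test matches prop.test", {
  set.seed(55L)
  mkset <- function(n, plant = FALSE) {
    data.frame(gene_id = sprintf("g%03d", seq_len(n)),
               sequence = vapply(seq_len(n), function(i) {
                 s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
                 if (plant && i <= n * 0.8)
                   substr(s, 450, 455) <- "TGATAA"
                 s
               }, character(1)), stringsAsFactors = FALSE)
  }
  enr <- hexamer_bin_enrichment(mkset(50, plant = TRUE), mkset(50))
  o <- order(enr$p_value)
  expect_true(all(diff(enr$q_value[o]) >= -1e-12))
  # cross-check one cell against prop.test's chi-square (without continuity
  # correction the two-sided z-test is identical)
  row <- enr[enr$hexamer == "TGATAA" & enr$bin == 5, ]
  n1 <- 50 * 100; n2 <- 50 * 100
  pt <- suppressWarnings(prop.test(c(row$target_count, row$control_count),
                                   c(n1, n2), correct = FALSE))
  expect_equal(row$p_value, pt$p.value, tolerance = 1e-9)
  expect_lt(row$q_value, 0.01)
})

test_that("control smaller than target proceeds with a warning", {
  set.seed(56L)
  mk <- function(n) data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                               sequence = vapply(seq_len(n), function(i)
                                 paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                                       collapse = ""), character(1)),
                               stringsAsFactors = FALSE)
  expect_warning(hexamer_bin_enrichment(mk(10), mk(5)), "smaller")
  expect_error(hexamer_bin_enrichment(mk(10), mk(0)), "non-empty")
})

test_that("TATAA frequency is presence-based and exact under planting", {
  base <- strrep("C", 600)
  with_box <- paste0(strrep("C", 100), "TATAA", strrep("C", 495))
  double_box <- paste0(strrep("C", 100), "TATAA", strrep("C", 200), "TATAA",
                       strrep("C", 290))
  proms <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      sequence = c(rep(with_box, 36), double_box,
                                   rep(base, 63)),
                      stringsAsFactors = FALSE)
  expect_equal(tataa_frequency(proms), 0.37)
  expect_equal(tataa_frequency(proms[100, , drop = FALSE]), 0)
})
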