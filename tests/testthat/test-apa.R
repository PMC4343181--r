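# 3'UTR isoform catalogs, reference matching, length statistics, and
# APA-switch classification.

two_gene_ann <- function() {
  make_annotation(make_genes(
    gene_id = c("gp", "gm"), contig = "c", strand = c("+", "-"),
    gene_start = c(1000L, 4000L), gene_end = c(2200L, 5200L),
    stop_codon_end = c(1800L, 5000L)))
}

mk_clusters <- function(gene, site, usage = 1, status = "retained",
                        cluster_id = paste0("cl", seq_along(site))) {
  data.frame(cluster_id = cluster_id, contig = "c",
             strand = if (gene == "gp") "+" else "-",
             representative_site = site, span_start = site, span_end = site,
             read_count = 10L, assigned_gene = gene, usage_fraction = usage,
             status = status, stringsAsFactors = FALSE)
}

expr_rec <- function(gene, fpkm, tissue = "int") {
  data.frame(gene_id = gene, tissue = tissue, fpkm = fpkm,
             expressed = fpkm >= 1, stringsAsFactors = FALSE)
}

test_that("UTR length is transcript-relative on both strands", {
  ann <- two_gene_ann()
  # + strand: stop 1800, cleavage 1900 -> 100
  cat_p <- build_isoform_catalog(mk_clusters("gp", 1900L), ann,
                                 expr_rec("gp", 5), tissue = "int")
  expect_identical(cat_p$isoforms$utr_length, 100L)
  # - strand: stop (last CDS base, transcript orientation) at 5000,
  # cleavage at genomic 4880 -> 120
  cat_m <- build_isoform_catalog(mk_clusters("gm", 4880L), ann,
                                 expr_rec("gm", 5), tissue = "int")
  expect_identical(cat_m$isoforms$utr_length, 120L)
})

test_that("unexpressed genes and pre-stop cleavage sites yield no isoforms", {
  ann <- two_gene_ann()
  none <- build_isoform_catalog(mk_clusters("gp", 1900L), ann,
                                expr_rec("gp", 0.5), tissue = "int")
  expect_identical(nrow(none$isoforms), 0L)
  bad <- build_isoform_catalog(mk_clusters("gp", c(1700L, 1900L), usage = 0.5),
                               ann, expr_rec("gp", 5), tissue = "int")
  expect_identical(bad$n_invalid, 1L)
  expect_identical(bad$isoforms$cleavage_site, 1900L)
  expect_equal(bad$isoforms$usage_fraction, 1)  # renormalized
})

test_that("reference matching is +-10 nt inclusive and symmetric", {
  iso <- data.frame(gene_id = "g", cleavage_site = c(1000L, 1011L),
                    stringsAsFactors = FALSE)
  ref <- data.frame(gene_id = "g", cleavage_site = 1010L,
                    stringsAsFactors = FALSE)
  out <- match_reference_utrome(iso, ref)
  expect_identical(out$ref_class, c("in_ref", "in_ref"))  # |d|=10 and |d|=1
  out11 <- match_reference_utrome(
    data.frame(gene_id = "g", cleavage_site = 1021L, stringsAsFactors = FALSE),
    ref)
  expect_identical(out11$ref_class, "novel")  # |d|=11
  # reflexivity: catalog against itself is 100% matched
  self <- match_reference_utrome(iso, iso)
  expect_identical(unname(attr(self, "summary")["in_ref"]), 1)
  # empty reference -> all novel
  none <- match_reference_utrome(iso, ref[0, ])
  expect_identical(none$ref_class, c("novel", "novel"))
  # symmetry of the matched-pair relation
  fwd <- match_reference_utrome(iso, ref)$ref_class == "in_ref"
  bwd <- match_reference_utrome(ref, iso)$ref_class == "in_ref"
  expect_identical(any(fwd), any(bwd))
})

test_that("UTR length statistics use the lower-median convention", {
  s <- utr_length_stats(c(50, 100, 400))
  expect_equal(s$median, 100)
  expect_equal(s$mean, 550 / 3)
  expect_equal(utr_length_stats(100)$median, 100)
  # lower of the middle pair for even n
  expect_equal(utr_length_stats(c(10, 20, 30, 40))$median, 20)
  # duplicating the median leaves it unchanged
  expect_equal(utr_length_stats(c(50, 100, 100, 400))$median, 100)
  expect_true(utr_length_stats(numeric(0))$empty)
  expect_identical(sum(s$histogram$count), 3L)
})

test_that("isoform-count distribution bins genes by isoform number", {
  iso <- data.frame(gene_id = c("a", "b", "b", "d", "d", "d"),
                    stringsAsFactors = FALSE)
  d <- isoform_count_distribution(iso)
  expect_identical(unname(d$bins), c(1L, 1L, 1L))
  expect_equal(d$ratio, 2)
  expect_identical(d$n_genes, 3L)
})

test_that("pairwise switch calls follow proximal/distal semantics", {
  mkiso <- function(tissue, len, usage = 1)
    data.frame(gene_id = "g", tissue = tissue, cleavage_site = 1800L + len,
               utr_length = len, usage_fraction = usage,
               stringsAsFactors = FALSE)
  # A at stop+80, B at stop+300 -> proximal in A
  call <- classify_pairwise_switch(mkiso("A", 80L), mkiso("B", 300L))
  expect_identical(call$class, "proximal_in:A")
  expect_true(call$confident)
  # mirrored comparison mirrors the labels
  rev <- classify_pairwise_switch(mkiso("B", 300L), mkiso("A", 80L))
  expect_identical(rev$proximal_tissue, "A")
  # |d| = 10 -> same
  expect_identical(classify_pairwise_switch(mkiso("A", 100L),
                                            mkiso("B", 110L))$class, "same")
  expect_identical(classify_pairwise_switch(mkiso("A", 100L),
                                            mkiso("B", 111L))$class,
                   "proximal_in:A")
  # dominance below threshold: call made but not confident
  isoA <- rbind(mkiso("A", 80L, 0.55), mkiso("A", 300L, 0.45))
  call2 <- classify_pairwise_switch(isoA, mkiso("B", 300L, 0.9))
  expect_identical(call2$class, "proximal_in:A")
  expect_false(call2$confident)
  expect_error(classify_pairwise_switch(mkiso("A", 80L)[0, ], mkiso("B", 300L)),
               "not comparable")
})

test_that("three-tissue categories cover common, one-distinct and all-distinct", {
  mkiso <- function(tissue, len)
    data.frame(gene_id = "g", tissue = tissue, cleavage_site = 1800L + len,
               utr_length = len, usage_fraction = 1, stringsAsFactors = FALSE)
  tri <- function(a, b, d)
    list(intestine = mkiso("intestine", a), pharynx = mkiso("pharynx", b),
         body_muscle = mkiso("body_muscle", d))
  expect_identical(classify_three_tissue(tri(200L, 200L, 200L)), "common")
  # intestine distinct, muscle tissues shared
  expect_identical(classify_three_tissue(tri(400L, 200L, 205L)),
                   "intestine_distinct")
  expect_identical(classify_three_tissue(tri(100L, 250L, 400L)), "all_distinct")
})

test_that("three-tissue categories partition the comparable gene set", {
  study <- get_default_study()
  tabs <- study$three_tissue
  comparable <- Reduce(intersect, lapply(study$catalogs,
                                         function(x) unique(x$gene_id)))
  expect_identical(sort(tabs$gene_id), sort(comparable))
  expect_identical(anyDuplicated(tabs$gene_id), 0L)
  expect_true(all(tabs$category %in%
                    c("common", "all_distinct",
                      paste0(names(study$catalogs), "_distinct"))))
})
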