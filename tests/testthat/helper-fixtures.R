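# Shared fixtures and independent oracles.  Heavy objects are memoised in
# a session-local cache so they are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact simulation for unit tests
small_sim_config <- function(seed = 11L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_contigs = 2L, contig_length = 60000L,
                   n_genes = 12L, n_reads_per_tissue = 4000L,
                   n_priming_traps = 6L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

get_small_sim <- function() {
  memo("small_sim", generate_genome_and_annotation(small_sim_config()))
}

get_small_index <- function() {
  memo("small_index", build_genome_index(get_small_sim()$genome))
}

# the default study conditions (used by the end-to-end recovery checks)
get_default_study <- function() {
  memo("default_study", run_apa_study(sim_config(seed = 1L)))
}

random_reads <- function(n, len_range = c(20L, 120L),
                         p = c(A = 0.4, C = 0.2, G = 0.2, T = 0.2)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(names(p), l, replace = TRUE, prob = p), collapse = ""),
    character(1))
  setNames(seqs, sprintf("rr%05d", seq_len(n)))
}

# --- independent oracles ----------------------------------------------------

# exhaustive suffix scan: longest terminal A-run by testing every suffix
oracle_terminal_a_run <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (k in seq_len(n)) {
    suffix <- substr(seq, n - k + 1L, n)
    if (identical(suffix, strrep("A", k))) best <- k else break
  }
  best
}

# brute-force single-linkage via transitive closure of the "gap <= max_gap"
# relation between positions
oracle_single_linkage <- function(pos, max_gap) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= max_gap && grp[i] != grp[j]) {
        grp[grp == max(grp[i], grp[j])] <- min(grp[i], grp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(pos, grp), sort))
}

# plain double-loop per-position nucleotide tally
oracle_profile <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  L <- nchar(seqs[1])
  m <- matrix(0, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) for (j in seq_len(L)) {
    b <- substr(s, j, j)
    m[b, j] <- m[b, j] + 1
  }
  sweep(m, 2L, colSums(m), "/")
}

# minimal annotation builder for constructed fixtures
make_annotation <- function(genes, exons = NULL) {
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, contig = genes$contig,
                        strand = genes$strand, start = genes$gene_start,
                        end = genes$gene_end, stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "apamap_annotation")
}

make_genes <- function(...) {
  g <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(g$has_stop)) g$has_stop <- TRUE
  if (is.null(g$in_operon)) g$in_operon <- FALSE
  g
}
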