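# Readers/writers for the standard formats the pipeline touches, and the
# coordinate-convention boundary.  Internal convention: 1-based inclusive
# genomic coordinates with explicit strand; conversion to 0-based
# half-open happens only at the BED boundary (handled by rtracklayer).

new_annotation <- function(genes, exons) {
  rownames(genes) <- NULL; rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "apamap_annotation")
}

#' @export
print.apamap_annotation <- function(x, ...) {
  cat("apamap annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Emits gene, exon and stop_codon features (1-based inclusive).  The
#' stop_codon feature spans the last three CDS bases; its transcript-3'
#' end is the gene's 3'UTR anchor.
#'
#' @param annotation an annotation object (list of \code{genes} and
#'   \code{exons} data frames) as produced by
#'   \code{\link{generate_genome_and_annotation}} or
#'   \code{\link{parse_annotation}}.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  stop_start <- ifelse(g$strand == "+", g$stop_codon_end - 2L, g$stop_codon_end)
  stop_end <- ifelse(g$strand == "+", g$stop_codon_end, g$stop_codon_end + 2L)
  feat <- rbind(
    data.frame(contig = g$contig, start = g$gene_start, end = g$gene_end,
               strand = g$strand, type = "gene", ID = g$gene_id,
               Parent = NA_character_, in_operon = as.character(g$in_operon),
               stringsAsFactors = FALSE),
    data.frame(contig = e$contig, start = e$start, end = e$end,
               strand = e$strand, type = "exon",
               ID = paste0(e$gene_id, ".e", stats::ave(e$start, e$gene_id, FUN = seq_along)),
               Parent = e$gene_id, in_operon = NA_character_, stringsAsFactors = FALSE),
    data.frame(contig = g$contig, start = stop_start, end = stop_end,
               strand = g$strand, type = "stop_codon",
               ID = paste0(g$gene_id, ".stop"), Parent = g$gene_id,
               in_operon = NA_character_, stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(feat$contig,
                               IRanges::IRanges(feat$start, feat$end),
                               strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$ID
  S4Vectors::mcols(gr)$Parent <- feat$Parent
  S4Vectors::mcols(gr)$in_operon <- feat$in_operon
  gr <- gr[order(feat$contig, feat$start, feat$type)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Parse a GFF3 annotation into gene models
#'
#' Reads gene/exon/stop_codon features and assembles one gene model per
#' gene: contig, strand, span, exon list and the stop-codon 3'UTR anchor
#' (genomic coordinate of the last CDS base in transcript orientation).
#' Genes lacking a stop_codon record are kept but flagged
#' \code{has_stop = FALSE} (unusable for 3'UTR analyses).
#'
#' @param path GFF3 file.
#' @return an annotation object: list with data frames \code{genes}
#'   (gene_id, contig, strand, gene_start, gene_end, stop_codon_end,
#'   has_stop, in_operon) and \code{exons} (gene_id, contig, strand,
#'   start, end; non-overlapping, sorted).
#' @export
parse_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (nrow(df) == 0L) {
    return(new_annotation(
      data.frame(gene_id = character(0), contig = character(0), strand = character(0),
                 gene_start = integer(0), gene_end = integer(0),
                 stop_codon_end = integer(0), has_stop = logical(0),
                 in_operon = logical(0), stringsAsFactors = FALSE),
      data.frame(gene_id = character(0), contig = character(0), strand = character(0),
                 start = integer(0), end = integer(0), stringsAsFactors = FALSE)))
  }
  parent1 <- function(p) vapply(p, function(x) if (length(x)) as.character(x)[1] else NA_character_, character(1))
  gdf <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = as.character(gdf$ID), contig = gdf$seqnames,
                      strand = gdf$strand, gene_start = gdf$start, gene_end = gdf$end,
                      in_operon = if ("in_operon" %in% names(gdf))
                        !is.na(gdf$in_operon) & gdf$in_operon == "TRUE" else
                        rep(FALSE, nrow(gdf)),
                      stringsAsFactors = FALSE)
  edf <- df[df$type == "exon", ]
  exons <- data.frame(gene_id = parent1(edf$Parent), contig = edf$seqnames,
                      strand = edf$strand, start = edf$start, end = edf$end,
                      stringsAsFactors = FALSE)
  sdf <- df[df$type == "stop_codon", ]
  stop_parent <- parent1(sdf$Parent)
  stop_codon_end <- ifelse(sdf$strand == "+", sdf$end, sdf$start)
  genes$stop_codon_end <- stop_codon_end[match(genes$gene_id, stop_parent)]
  genes$has_stop <- !is.na(genes$stop_codon_end)
  # validation
  for (i in seq_len(nrow(genes))) {
    eg <- exons[exons$gene_id == genes$gene_id[i], ]
    if (nrow(eg) == 0L) next
    if (any(eg$start < genes$gene_start[i] | eg$end > genes$gene_end[i]))
      stop("validation error: exon outside gene span for ", genes$gene_id[i])
    eg <- eg[order(eg$start), ]
    if (nrow(eg) > 1L && any(eg$start[-1] <= eg$end[-nrow(eg)]))
      stop("validation error: overlapping exons for ", genes$gene_id[i])
    if (genes$has_stop[i] &&
        (genes$stop_codon_end[i] < genes$gene_start[i] ||
         genes$stop_codon_end[i] > genes$gene_end[i]))
      stop("validation error: stop codon outside gene span for ", genes$gene_id[i])
  }
  exons <- exons[order(exons$gene_id, exons$start), ]
  genes <- genes[order(genes$gene_id),
                 c("gene_id", "contig", "strand", "gene_start", "gene_end",
                   "stop_codon_end", "has_stop", "in_operon")]
  new_annotation(genes, exons)
}

#' Write / read FASTQ reads
#'
#' Thin wrappers over Biostrings (Phred+33; constant quality on write,
#' qualities ignored on read since the pipeline is quality-agnostic).
#'
#' @param reads named character vector of sequences.
#' @param path FASTQ file.
#' @return \code{read_reads_fastq} returns a named character vector.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

# ---- SAM parsing -----------------------------------------------------------

# Longest run of consecutively matched read bases, derived from CIGAR +
# MD.  Insertions, deletions, skips and MD mismatches all break a run.
longest_match_run <- function(cigar, md) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L) stop("unparseable CIGAR: ", cigar)
  lens <- as.integer(sub("[A-Z=]", "", ops))
  kinds <- sub("\\d+", "", ops)
  # token stream of the MD tag: numbers (matches), letters (mismatch),
  # ^SEQ (deletion)
  md_tokens <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  md_runs <- integer(0)  # match-run lengths separated by mismatches/dels
  cur <- 0L
  flush <- function() { md_runs <<- c(md_runs, cur); cur <<- 0L }
  for (tk in md_tokens) {
    if (grepl("^\\d+$", tk)) cur <- cur + as.integer(tk)
    else flush()
  }
  flush()
  # md_runs gives runs within aligned (M) reference bases; CIGAR I breaks
  # runs without consuming MD.  Walk both together.
  runs <- integer(0); acc <- 0L
  md_i <- 1L; md_left <- md_runs[1]
  advance_md <- function(n) {
    # consume n matched-or-mismatched aligned bases, splitting `acc` runs
    while (n > 0L) {
      take <- min(n, md_left)
      acc <<- acc + take
      md_left <<- md_left - take
      n <- n - take
      if (md_left == 0L && md_i < length(md_runs)) {
        # a mismatch (or deletion) boundary follows
        runs <<- c(runs, acc); acc <<- 0L
        if (n > 0L) n <- n - 1L  # the mismatched base itself
        md_i <<- md_i + 1L
        md_left <<- md_runs[md_i]
      } else if (md_left == 0L) break
    }
  }
  for (k in seq_along(kinds)) {
    kind <- kinds[k]; len <- lens[k]
    if (kind %in% c("M", "=", "X")) {
      advance_md(len)
    } else if (kind %in% c("I", "S")) {
      if (kind == "I") { runs <- c(runs, acc); acc <- 0L }
    } else if (kind %in% c("D", "N")) {
      runs <- c(runs, acc); acc <- 0L
      # deletion boundary also consumes an MD token boundary
      if (md_left == 0L && md_i < length(md_runs)) {
        md_i <- md_i + 1L; md_left <- md_runs[md_i]
      }
    }
  }
  runs <- c(runs, acc)
  max(runs)
}

#' Parse SAM alignments
#'
#' Entry point for externally aligned reads.  Unmapped (FLAG 0x4),
#' secondary (0x100) and supplementary (0x800) records are dropped.  The
#' longest consecutively mapped stretch is derived from CIGAR and the MD
#' tag; a missing MD tag on a mapped record is an error naming the record.
#'
#' @param path SAM file (text).
#' @param tail_registry optional named integer vector (read id ->
#'   untemplated tail length carried over from trimming).
#' @return data frame of alignments: read_id, contig, strand, pos
#'   (1-based leftmost), span (reference span), longest_consecutive_match,
#'   tail_length.
#' @export
parse_alignments <- function(path, tail_registry = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record: ", ln)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next          # unmapped
    if (bitwAnd(flag, 256L) != 0L) next        # secondary
    if (bitwAnd(flag, 2048L) != 0L) next       # supplementary
    md <- grep("^MD:Z:", f[-(1:11)], value = TRUE)
    if (length(md) == 0L)
      stop("missing MD tag for mapped record ", f[1])
    md <- sub("^MD:Z:", "", md[1])
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    kinds <- sub("\\d+", "", ops)
    ref_span <- sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
    out[[length(out) + 1L]] <- data.frame(
      read_id = f[1], contig = f[3],
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      pos = as.integer(f[4]), span = ref_span,
      longest_consecutive_match = longest_match_run(cigar, md),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    aln <- data.frame(read_id = character(0), contig = character(0),
                      strand = character(0), pos = integer(0), span = integer(0),
                      longest_consecutive_match = integer(0), stringsAsFactors = FALSE)
  } else aln <- do.call(rbind, out)
  aln$tail_length <- if (is.null(tail_registry)) NA_integer_ else
    as.integer(tail_registry[aln$read_id])
  aln
}

#' Write PAS clusters to BED6
#'
#' One interval per cluster at its representative site (0-based half-open
#' on disk; conversion handled by rtracklayer), name
#' \code{gene_id|cluster_id}, score = read count, strand preserved;
#' sorted by contig then start.
#'
#' @param clusters cluster data frame (see \code{\link{map_polya_reads}}).
#' @param path output BED file.
#' @return path, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (nrow(clusters) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(clusters$contig,
                               IRanges::IRanges(clusters$representative_site,
                                                clusters$representative_site),
                               strand = clusters$strand)
  S4Vectors::mcols(gr)$name <- paste(ifelse(is.na(clusters$assigned_gene), ".",
                                            clusters$assigned_gene),
                                     clusters$cluster_id, sep = "|")
  S4Vectors::mcols(gr)$score <- clusters$read_count
  gr <- gr[order(clusters$contig, clusters$representative_site)]
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 cluster file back into 1-based representative sites
#'
#' @param path BED file written by \code{\link{write_clusters_bed}}.
#' @return data frame (contig, representative_site, name, score, strand),
#'   coordinates 1-based inclusive.
#' @export
read_clusters_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(0), representative_site = integer(0),
                      name = character(0), score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             representative_site = GenomicRanges::start(gr),
             name = gr$name, score = as.numeric(gr$score),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
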