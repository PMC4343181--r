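---
title: "Mapping polyA sites and tissue-specific 3'UTR isoforms with apamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polyA sites and tissue-specific 3'UTR isoforms with apamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apamap)
```

## The problem

Most metazoan genes produce several mRNA 3'UTR isoforms through
alternative polyadenylation (APA): the cleavage/polyadenylation machinery
can select among several polyadenylation sites downstream of the stop
codon, usually directed by an AAUAAA-class hexamer (the PAS) ending about
19 nt upstream of the cleavage site. Because 3'UTRs carry regulatory
elements - miRNA target sites above all - the choice of a proximal
(short) versus distal (long) isoform can rewire post-transcriptional
regulation in a tissue-specific way.

`apamap` implements the computational half of a tissue-resolved 3'-end
profiling experiment: starting from polyA-selected reads it maps cleavage
sites, removes internal-priming artifacts, clusters sites into PAS
clusters attached to genes, quantifies gene expression, builds per-tissue
3'UTR isoform catalogs, classifies APA switches between tissues,
characterises PAS hexamers and cleavage context, scans promoters for
positionally enriched hexamers, and asks whether switching genes are
enriched for miRNA targets. A seeded simulator generates a complete toy
study - genome, annotation, per-tissue reads and ground-truth tables - so
that every stage is testable against known truth.

## The polyA mapping procedure

1. **Tail extraction.** A read is a polyA read iff its maximal terminal
   A-run is at least 30 nt; the run is removed before alignment. The
   boundary is strict: a 29-A tail is rejected. Reads whose trimmed
   remainder is shorter than the 18-nt aligner seed are dropped with a
   counted reason.
2. **Alignment.** Trimmed reads are aligned with a built-in exact
   seed-and-extend aligner (exact 18-nt 5' seed, at most one substitution
   in the extension). A read with two or more equally good loci is
   discarded as multi-mapped. Externally produced SAM (with MD tags) is
   accepted through `parse_alignments()` as an alternative entry point;
   downstream stages consume only the alignment contract (locus, strand,
   span, longest consecutive match), not the aligner.
3. **Cleavage site.** The last transcribed base: the rightmost aligned
   base on "+", the leftmost on "-".
4. **Internal-priming filter.** A cleavage event fails if the A fraction
   in the 30 nt immediately downstream *or* upstream (transcript
   orientation, sense strand) is >= 65%, or if fewer than 18 read bases
   map consecutively. Truncated windows at contig edges use the available
   bases. The window length (30 nt) is a package choice matching the
   30-A tail threshold; the 65% and 18-nt thresholds are strict
   boundaries.
5. **Clustering.** Single-linkage: sorted positions on a (contig, strand)
   are joined while consecutive gaps are <= 25 nt. The representative
   site is the modal member position, ties broken toward the transcript
   3' end (the mode is the best-supported cleavage base; the distal
   tie-break is conservative for switch calls). Clustering is
   order-invariant and idempotent: representatives of adjacent clusters
   are necessarily more than the gap apart.
6. **Gene attachment.** A cluster attaches to the nearest same-strand
   gene whose window from the stop codon to 1,600 nt past the gene 3' end
   contains (or is nearest to) the representative site; exact ties go to
   the gene whose 3' terminus is nearest upstream.
7. **Cluster filters.** Per gene, clusters whose genomic footprint
   exceeds 40% A are removed first, then clusters carrying less than 5%
   of the gene's polyA reads; the survivors' usage fractions are
   renormalized to sum to 1. The ordering (footprint filter before the
   usage filter) is a package decision; both orders give identical
   results whenever the A-rich cluster is also a minor one.

Every read ends up in exactly one accounting class (no tail, too short,
unaligned, multi-mapped, filtered with reason, clustered); the test suite
asserts this conservation on every run.

## Expression and isoform catalogs

Expression is quantified as union-exon FPKM: each primary alignment is
assigned to the same-strand gene whose union-exon span it overlaps most
(ties unassigned), and FPKM = C x 10^9 / (L x N) with C the gene's
fragment count, L its union-exon length and N the total assigned
fragments. Genes with FPKM >= 1 are called expressed; the threshold is
inclusive. Isoform-resolved estimation and differential testing are out
of scope - downstream stages consume only the gene-level threshold.

A tissue's 3'UTR isoform catalog holds one isoform per retained cluster
of an expressed gene, with a transcript-relative UTR length (base after
the stop codon to the cleavage site, inclusive). Working on UTR lengths
rather than raw genomic coordinates makes "+" and "-" strand genes
uniform. Catalogs are compared against a reference 3'UTRome with a
+-10 nt tolerance, inclusive on both sides. The median reported by
`utr_length_stats()` is the lower middle value for even n (deterministic
and order-statistic exact).

## Switch classification

Pairwise: each tissue is represented by its dominant isoform (maximal
usage fraction); dominant UTR lengths within 10 nt are "same", otherwise
the tissue with the shorter dominant UTR is the proximal one. The
original coverage-ratio confidence rule is underspecified in the
literature this follows, so the package implements it as a dominance
threshold: a call is *confident* iff the dominant isoform holds >= 60%
usage in both tissues (the usage fraction is the only coverage ratio
defined at this stage). The call itself is always made; confidence is a
flag, not a filter.

Three tissues: the pairwise same/different matrix of dominant UTR lengths
gives "common" (all same), "all_distinct" (all different), or
"<tissue>_distinct" otherwise, where the distinct tissue is the one with
the largest total distance to the other two - this also resolves the rare
non-transitive chains a fixed tolerance can produce (A~B, B~C, A!~C) with
a deterministic rule.

## PAS hexamers and cleavage context

The PAS caller scans every hexamer whose last base falls in offsets -40
to -10 from the cleavage site and keeps the one with minimal Hamming
distance to AATAAA; ties resolve to the end position closest to -19
(the canonical placement). Distance 0/1/2 maps to
canonical/one-permutation/two-plus; nothing within distance 2 gives
"none". The search window and the reading of "permutation" as single-base
substitution are conventions of the 3'UTRome literature, exposed as
parameters, not facts of any one dataset.

The cleavage-context profile covers offsets -50..-1 and +1..+20: exactly
70 positions, with the cleavage base itself (offset 0) excluded - the
natural reading of a "70 nt" window spanning -50 to +20. Columns are
per-position nucleotide frequencies and sum to 1; the implementation
(Biostrings `consensusMatrix`) is tested against a plain per-position
tally oracle.

## Promoter analysis

Promoters are the 600-nt windows from -500 to +100 around the annotated
TSS, with +1 the TSS base (so a "+"-strand TSS at 1,001 yields genomic
501..1100); genes whose window leaves the contig are excluded and
counted, and operon-internal genes can be excluded by flag. Hexamer
occurrences are counted with overlap in six 100-nt bins, a window
belonging to the bin of its first base; since windows must fit inside the
region, bins 1-5 hold 100 windows per promoter and bin 6 holds 95, and
the per-bin totals are conserved exactly (595 windows per promoter).

Enrichment against a control promoter set reports, per hexamer x bin, the
frequency ratio plus a two-proportion z-test p-value and
Benjamini-Hochberg q-value over all 4,096 x 6 hypotheses. Ratios are the
primary readout; the test treats overlapping windows as independent
trials, which is anti-conservative for self-overlapping hexamers (AAAAAA
and friends) - a documented approximation, acceptable because the
q-values guard ranking rather than estimate error rates. The z statistic
is identical to `prop.test(correct = FALSE)` and is cross-checked against
it in the tests.

## miRNA-target enrichment

Given a gene -> targeted table per prediction set, the enrichment test
draws R seeded random subsets of the expressed background, each the size
of the switch-gene set, and compares the observed targeted proportion to
the resampling distribution twice: a two-tailed one-sample t-test of the
resampled proportions against the observed value (the construction the
original analysis implies, with its distributional assumption), and an
empirical two-tailed p-value 2 x min(lower, upper tail) with a +1
correction - the robust alternative. Under a null configuration the
empirical p is approximately uniform but slightly conservative because
proportions tie frequently; the suite checks that 200 null replicates
reject at 5% between 2% and 9% of the time.

## What the simulator emulates - and what it does not

`sim_config()` defaults define the study conditions: 2 contigs x 200 kb,
60 non-overlapping two-exon genes on both strands, 3 tissues, 20,000
100-nt reads per tissue (40% polyA-tailed, 5% internal-priming
artifacts, the rest body reads), tails uniform on 30..45 nt, per-base
substitution rate 0.002, per-(gene,tissue) abundance 10^N(1.3, 0.4) on
the FPKM scale, 1-3 cleavage sites per gene with probabilities
(0.5, 0.35, 0.15), planted PAS hexamers 80% canonical / 20%
one-permutation ending exactly 19 nt upstream of each site, usage
mixtures with exact-decimal weights - (0.75, 0.25) for stable two-site
genes, dominance flipped in one tissue for planted switches (probability
0.5 among eligible genes) - 20 planted 35-nt A-runs (half inside
transcripts, half intergenic) as internal-priming traps, the hexamer
TGATAA planted into promoter bin 5 of an exact 40% of genes, and miRNA
target labels at rate 0.5 for switching versus 0.2 for other genes.
These sizes run the full study in well under a minute on one CPU while
leaving 50+ reads on most gene/tissue pairs, enough for usage fractions
to stabilise.

Deliberate simplifications, hence limits on what passing tests show about
real libraries:

* The cleavage-site base is planted as a non-A nucleotide. In real data
  templated A's at the junction are indistinguishable from the tail, so
  every read from such a site maps its cleavage a few bases upstream;
  with the planted base the recovery checks can demand near-exactness.
* Untemplated tails are pure A (a `tail_error_rate` flag injects tail
  errors for robustness testing); base qualities are constant; there are
  no indels, no PCR duplicates, no paired ends.
* Body reads are drawn proportional to abundance x spliced length and
  always lie within one exon - there are no junction-spanning reads, so
  union-exon counting sees every fragment. PolyA reads are drawn
  proportional to abundance only, as in 3'-end counting.
* Priming traps are genomically templated A-runs (>= 30 nt), the exact
  artifact class the >= 65%-A filter targets: trap reads pass tail
  extraction and must be caught by the genomic filter, never by luck of
  the aligner.
* The genome alphabet is uppercase ACGT; N handling is an extension
  point.
* Planted promoter-motif recovery is evaluated as carriers versus
  non-carriers. With only 60 genes, a uniform random control would itself
  contain carriers and the contrast would measure dilution, not
  detection; the carrier/non-carrier split is the planted-signal analogue
  of comparing a tissue's genes against random genes in a large genome.

## Numerical and degenerate-input conventions

All internal coordinates are 1-based inclusive with explicit strand;
0-based half-open appears only at the BED boundary (handled by
rtracklayer). Strict inequalities follow the printed rules: retained iff
tail >= 30; fail iff window A >= 65%; fail iff consecutive match < 18;
filtered iff usage < 5%; filtered iff footprint A > 40%; expressed iff
FPKM >= 1; reference match iff |delta| <= 10. Empty inputs return
explicit empty markers (header-only truth tables, empty BED files,
`empty = TRUE` statistics, NULL profiles) rather than errors wherever an
empty result is meaningful; guards (unknown tissue, R < 100, background
smaller than the switch set, oversubscribed contigs) raise errors naming
the problem. A fixed seed makes every simulated artifact byte-identical
across runs; derived per-tissue seeds stay within 32-bit integer range.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` reruns the default study
from scratch - simulation, mapping, filtering, clustering, expression,
catalogs, switch calls, PAS and promoter analyses, enrichment tests - and
writes the resulting quantities (site recovery rate, artifact removal
rate, switch-call accuracy, usage error, PAS class fractions, planted
motif rank and q-value, TATAA frequency, miRNA enrichment p-values,
expression set sizes) as JSON. The vignette intentionally quotes none of
those numbers: they are computed, not asserted.
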