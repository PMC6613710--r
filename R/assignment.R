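#' Assign footprints to a single nucleotide by the 3'-end rule
#'
#' Each footprint is collapsed to the nucleotide a fixed offset from its 3'
#' terminus (by default the 15th, a proxy for the ribosomal P-site): on the
#' plus strand the 3' end is the alignment end, so the assigned position is
#' `end - (offset - 1)`; on the minus strand the 3' end is the alignment
#' start, so it is `start + (offset - 1)`. Reads shorter than `offset`
#' cannot host the assigned nucleotide and are discarded (counted in the
#' `"stats"` attribute, not an error).
#'
#' @param alignments Footprint tibble (`read_id`, `contig`, `strand`,
#'   `start`, `end`, `length`), e.g. from [read_alignments()].
#' @param offset 1-based offset from the 3' end (default 15).
#' @return Tibble `read_id`, `contig`, `strand`, `genomic_nt` for reads long
#'   enough to assign; attribute `"stats"` reports `n_input`,
#'   `n_discarded_short`, `n_assigned`.
#' @export
assign_three_prime <- function(alignments, offset = 15L) {
  stopifnot(offset >= 1)
  len <- alignments$end - alignments$start + 1L
  ok <- len >= offset
  kept <- alignments[ok, ]
  out <- tibble(
    read_id = kept$read_id,
    contig = kept$contig,
    strand = kept$strand,
    genomic_nt = if_else(kept$strand == "+",
                         kept$end - (as.integer(offset) - 1L),
                         kept$start + (as.integer(offset) - 1L))
  )
  attr(out, "stats") <- tibble(
    n_input = nrow(alignments),
    n_discarded_short = sum(!ok),
    n_assigned = nrow(out)
  )
  out
}

#' Map assigned nucleotides to gene codons
#'
#' An assigned nucleotide falls in codon `floor((pos - cds_start)/3) + 1` of a
#' plus-strand gene, or `floor((cds_end - pos)/3) + 1` of a minus-strand gene
#' (codon indices in translation order, 1-based). Only genes on the read's
#' strand are considered; positions outside every CDS are unassigned. When a
#' position lies within two or more overlapping same-strand CDSs, the default
#' policy counts it once in each (`overlap = "all"`); `overlap = "drop"`
#' discards ambiguous positions instead.
#'
#' @param assignments Tibble from [assign_three_prime()].
#' @param genes Gene-model tibble.
#' @param overlap `"all"` or `"drop"`.
#' @return Tibble `read_id`, `gene_id`, `codon` (one row per read-gene hit);
#'   attribute `"stats"` reports `n_assigned_in_cds`, `n_unassigned`,
#'   `n_ambiguous_dropped`.
#' @export
map_to_codon <- function(assignments, genes, overlap = c("all", "drop")) {
  overlap <- match.arg(overlap)
  pos_gr <- GenomicRanges::GRanges(
    seqnames = assignments$contig,
    ranges = IRanges::IRanges(start = assignments$genomic_nt, width = 1L),
    strand = assignments$strand
  )
  gene_gr <- genes_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(pos_gr, gene_gr, ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)

  n_ambiguous_dropped <- 0L
  if (overlap == "drop") {
    multi <- qi %in% qi[duplicated(qi)]
    n_ambiguous_dropped <- length(unique(qi[multi]))
    qi <- qi[!multi]
    gi <- gi[!multi]
  }

  pos <- assignments$genomic_nt[qi]
  plus <- genes$strand[gi] == "+"
  codon <- ifelse(plus,
                  (pos - genes$cds_start[gi]) %/% 3L + 1L,
                  (genes$cds_end[gi] - pos) %/% 3L + 1L)
  out <- tibble(
    read_id = assignments$read_id[qi],
    gene_id = genes$gene_id[gi],
    codon = as.integer(codon)
  )
  attr(out, "stats") <- tibble(
    n_assigned_in_cds = length(unique(qi)),
    n_unassigned = nrow(assignments) - length(unique(S4Vectors::queryHits(hits))),
    n_ambiguous_dropped = n_ambiguous_dropped
  )
  out
}

#' Accumulate per-gene per-codon counts for one sample
#'
#' Produces the dense codon count table for a sample: every codon of every
#' gene appears with its count of assigned reads (zero included). The
#' bookkeeping invariant `assigned + unassigned + discarded_short == accepted
#' reads` is reported via the `"stats"` attribute.
#'
#' @param assignments Tibble from [assign_three_prime()].
#' @param genes Gene-model tibble.
#' @param sample_id Sample label to stamp on the rows.
#' @param overlap Overlapping-gene policy passed to [map_to_codon()].
#' @return Tibble `sample_id`, `gene_id`, `codon`, `count` (dense grid);
#'   attribute `"stats"` combines assignment bookkeeping.
#' @export
count_codons <- function(assignments, genes, sample_id, overlap = "all") {
  mapped <- map_to_codon(assignments, genes, overlap = overlap)
  grid <- tibble(
    gene_id = rep(genes$gene_id, genes$n_codons),
    codon = unlist(lapply(genes$n_codons, seq_len), use.names = FALSE)
  )
  bad <- !mapped$gene_id %in% genes$gene_id
  if (any(bad)) abort("assignments refer to unknown gene_id(s).")
  counts <- mapped |>
    count(.data$gene_id, .data$codon, name = "count")
  out <- grid |>
    left_join(counts, by = c("gene_id", "codon")) |>
    mutate(count = if_else(is.na(.data$count), 0L, .data$count),
           sample_id = sample_id, .before = 1)
  map_stats <- attr(mapped, "stats")
  assign_stats <- attr(assignments, "stats")
  attr(out, "stats") <- tibble(
    sample_id = sample_id,
    n_reads = nrow(assignments),
    n_discarded_short = assign_stats$n_discarded_short %||% NA_integer_,
    n_assigned = map_stats$n_assigned_in_cds,
    n_unassigned = map_stats$n_unassigned,
    n_ambiguous_dropped = map_stats$n_ambiguous_dropped,
    total_count = sum(out$count)
  )
  out
}
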