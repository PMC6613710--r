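#' Write a simulated genome and its annotation to disk
#'
#' @param sim A `ribosim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths
#'   (`fasta`, `gff3`, `stalls`).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ribosim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "genes.gff3")
  stalls <- file.path(dir, "stalls_truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fasta)
  write_gene_gff3(sim$genes, gff3)
  readr::write_tsv(sim$stalls, stalls)
  invisible(c(fasta = fasta, gff3 = gff3, stalls = stalls))
}

#' Write gene models as GFF3 CDS features
#'
#' Coordinates are emitted 1-based inclusive with the strand column, the
#' native GFF3 convention.
#'
#' @param genes Gene-model tibble (see [simulate_genome()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$cds_start, end = genes$cds_end),
    strand = genes$strand,
    type = "CDS",
    ID = genes$gene_id,
    Name = genes$gene_id,
    phase = 0L
  )
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; keep the first token as the contig name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read CDS annotation into gene models
#'
#' Parses GFF3 CDS features (or BED12 records) and extracts each gene's
#' in-frame sense-strand sequence from the genome; minus-strand sequences are
#' reverse-complemented. Records whose CDS length is not divisible by 3, or
#' whose translation contains an internal stop, are rejected with a warning.
#' Overlapping genes are allowed but reported.
#'
#' @param path Annotation file.
#' @param genome A [Biostrings::DNAStringSet] (from [read_genome_fasta()]).
#' @param dialect `"gff3"` or `"bed12"`.
#' @return Gene-model tibble: `gene_id`, `contig`, `strand`, `cds_start`,
#'   `cds_end` (1-based inclusive), `sequence`, `n_codons`.
#' @export
read_annotation <- function(path, genome, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  gr <- if (dialect == "gff3") {
    g <- rtracklayer::import(path, format = "GFF3")
    g <- g[g$type %in% c("CDS", "gene") & !is.na(g$type)]
    if (any(g$type == "CDS")) g <- g[g$type == "CDS"]
    g
  } else {
    rtracklayer::import(path, format = "BED")
  }
  ids <- if (dialect == "gff3") {
    id <- S4Vectors::mcols(gr)$ID
    if (is.null(id)) id <- S4Vectors::mcols(gr)$Name
    if (is.null(id)) id <- sprintf("cds%04d", seq_along(gr))
    as.character(id)
  } else {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) nm <- sprintf("cds%04d", seq_along(gr))
    as.character(nm)
  }
  genes <- tibble(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = GenomicRanges::start(gr),
    cds_end = GenomicRanges::end(gr)
  )
  if (any(!genes$strand %in% c("+", "-"))) {
    warn("records without strand rejected.")
    genes <- genes |> filter(.data$strand %in% c("+", "-"))
  }

  bad_len <- (genes$cds_end - genes$cds_start + 1L) %% 3L != 0L
  if (any(bad_len)) {
    warn(sprintf("%d CDS record(s) with length not divisible by 3 rejected: %s",
                 sum(bad_len), paste(head(genes$gene_id[bad_len], 5), collapse = ", ")))
    genes <- genes[!bad_len, ]
  }
  if (nrow(genes) == 0) return(genes |> mutate(sequence = character(), n_codons = integer()))

  missing_contig <- !genes$contig %in% names(genome)
  if (any(missing_contig)) {
    abort(sprintf("contig(s) not in genome: %s",
                  paste(unique(genes$contig[missing_contig]), collapse = ", ")))
  }
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[genes$contig[i]]],
                                         genes$cds_start[i], genes$cds_end[i]))
    if (genes$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  genes <- genes |>
    mutate(sequence = seqs,
           n_codons = as.integer(nchar(seqs) %/% 3L))

  aa <- codon_to_aa_strings(genes$sequence)
  internal_stop <- grepl("\\*.", aa)  # stop anywhere but the final codon
  if (any(internal_stop)) {
    warn(sprintf("%d CDS record(s) with internal stop codons rejected: %s",
                 sum(internal_stop),
                 paste(head(genes$gene_id[internal_stop], 5), collapse = ", ")))
    genes <- genes[!internal_stop, ]
  }

  ov <- GenomicRanges::findOverlaps(genes_to_granges(genes), drop.self = TRUE,
                                    drop.redundant = TRUE)
  if (length(ov) > 0) {
    inform(sprintf("%d overlapping gene pair(s) in annotation.", length(ov)))
  }
  genes
}

# translate full CDS strings (stop rendered as "*")
codon_to_aa_strings <- function(seqs) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                     if.fuzzy.codon = "X"))
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$cds_start, end = genes$cds_end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}
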