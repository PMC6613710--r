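suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Two hand-built gene models on a 600-nt contig: one per strand, with the
# genomic sequence assembled to match (minus-strand CDS stored reverse-
# complemented in the contig). Sequences are built from a fixed codon cycle
# so translations are known without running any package code.
tiny_genes <- function() {
  codons_a <- c("ATG", rep(c("GCT", "AAA", "TCT", "CCG"), 6), "TAA")  # 26 codons
  codons_b <- c("ATG", rep(c("GAA", "CCG", "CCA", "GGT"), 5), "TGA")  # 22 codons
  seq_a <- paste(codons_a, collapse = "")
  seq_b <- paste(codons_b, collapse = "")
  genes <- tibble(
    gene_id = c("gA", "gB"),
    contig = "chr1",
    strand = c("+", "-"),
    cds_start = c(101L, 301L),
    cds_end = c(101L + 3L * 26L - 1L, 301L + 3L * 22L - 1L),
    sequence = c(seq_a, seq_b),
    n_codons = c(26L, 22L)
  )
  contig <- strrep("A", 600)
  substr(contig, 101, 178) <- seq_a
  substr(contig, 301, 366) <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq_b))
  )
  genome <- Biostrings::DNAStringSet(stats::setNames(contig, "chr1"))
  list(genes = genes, genome = genome)
}

# Small planted-stall simulation shared by several test files.
small_sim <- function(seed = 7, n_genes = 10, depth = 5000) {
  cfg <- simulation_config(
    n_genes = n_genes,
    codons_per_gene = c(60, 120),
    strand_fraction = 0.5,
    planted_stalls = list(stall_spec("SPP", condition = "efp",
                                     multiplier = 20, n_sites = 3)),
    expression = "uniform",
    depth = depth,
    n_replicates = 2,
    conditions = c("wt", "efp"),
    seed = seed
  )
  simulate_genome(cfg)
}

# Independent brute-force pause-score oracle: nested loops over reads and
# genes, no shared code with the package's counting/scoring path. Takes raw
# footprint alignments per sample and recomputes every per-codon pause score
# from first principles.
oracle_pause_scores <- function(alignments_by_sample, genes, offset = 15,
                                threshold = 0.1, edge_exclude = 6) {
  counts <- list()
  for (s in names(alignments_by_sample)) {
    aln <- alignments_by_sample[[s]]
    tab <- lapply(seq_len(nrow(genes)), function(i) numeric(genes$n_codons[i]))
    names(tab) <- genes$gene_id
    for (r in seq_len(nrow(aln))) {
      len <- aln$end[r] - aln$start[r] + 1
      if (len < offset) next
      pos <- if (aln$strand[r] == "+") aln$end[r] - (offset - 1) else aln$start[r] + (offset - 1)
      for (i in seq_len(nrow(genes))) {
        if (genes$contig[i] != aln$contig[r]) next
        if (genes$strand[i] != aln$strand[r]) next
        if (pos < genes$cds_start[i] || pos > genes$cds_end[i]) next
        codon <- if (genes$strand[i] == "+") {
          (pos - genes$cds_start[i]) %/% 3 + 1
        } else {
          (genes$cds_end[i] - pos) %/% 3 + 1
        }
        tab[[genes$gene_id[i]]][codon] <- tab[[genes$gene_id[i]]][codon] + 1
      }
    }
    counts[[s]] <- tab
  }
  # density filter: strictly > threshold in every sample
  passing <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    ok <- TRUE
    for (s in names(counts)) {
      if (sum(counts[[s]][[g]]) / genes$n_codons[i] <= threshold) ok <- FALSE
    }
    if (ok) passing <- c(passing, g)
  }
  rows <- list()
  for (s in names(counts)) {
    for (g in passing) {
      nc <- genes$n_codons[genes$gene_id == g]
      dens <- sum(counts[[s]][[g]]) / nc
      for (codon in seq_len(nc)) {
        if (codon <= edge_exclude || codon > nc - edge_exclude) next
        rows[[length(rows) + 1]] <- tibble(
          sample_id = s, gene_id = g, codon = codon,
          score = counts[[s]][[g]][codon] / dens
        )
      }
    }
  }
  bind_rows(rows)
}
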