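test_that("the 3'-end rule assigns the 15th nucleotide from the 3' terminus", {
  aln <- tibble::tibble(
    read_id = c("plus", "minus", "short"),
    contig = "chr1",
    strand = c("+", "-", "+"),
    start = c(101L, 101L, 200L),
    end = c(130L, 130L, 213L),  # the last read is 14 nt
    length = c(30L, 30L, 14L)
  )
  out <- assign_three_prime(aln, offset = 15L)
  expect_equal(out$genomic_nt[out$read_id == "plus"], 116L)   # 130 - 14
  expect_equal(out$genomic_nt[out$read_id == "minus"], 115L)  # 101 + 14
  expect_false("short" %in% out$read_id)
  st <- attr(out, "stats")
  expect_equal(st$n_discarded_short, 1)
  expect_equal(st$n_assigned + st$n_discarded_short, st$n_input)
})

test_that("nucleotide-to-codon mapping matches brute-force codon spans on both strands", {
  genes <- tibble::tibble(
    gene_id = c("plus_g", "minus_g"),
    contig = "chr1",
    strand = c("+", "-"),
    cds_start = c(101L, 501L),
    cds_end = c(400L, 800L),
    sequence = NA_character_,
    n_codons = c(100L, 100L)
  )
  # spot values forced by the definition
  spot <- tibble::tibble(read_id = c("a", "b"), contig = "chr1",
                         strand = c("+", "-"), genomic_nt = c(116L, 715L))
  got <- map_to_codon(spot, genes)
  expect_equal(got$codon[got$read_id == "a"], 6L)
  expect_equal(got$codon[got$read_id == "b"], (800L - 715L) %/% 3L + 1L)

  # independent oracle: enumerate every codon's nucleotide span explicitly
  oracle <- function(pos, start, end, strand) {
    n <- (end - start + 1) %/% 3
    for (codon in seq_len(n)) {
      span <- if (strand == "+") {
        (start + (codon - 1) * 3):(start + codon * 3 - 1)
      } else {
        (end - codon * 3 + 1):(end - (codon - 1) * 3)
      }
      if (pos %in% span) return(codon)
    }
    NA_integer_
  }
  positions <- seq(501L, 800L)
  q <- tibble::tibble(read_id = sprintf("r%d", positions), contig = "chr1",
                      strand = "-", genomic_nt = positions)
  got <- map_to_codon(q, genes) |> arrange(match(read_id, q$read_id))
  want <- vapply(positions, oracle, integer(1), start = 501L, end = 800L, strand = "-")
  expect_equal(got$codon, want)

  q_plus <- tibble::tibble(read_id = sprintf("p%d", 101:400), contig = "chr1",
                           strand = "+", genomic_nt = 101:400)
  got_plus <- map_to_codon(q_plus, genes) |> arrange(match(read_id, q_plus$read_id))
  want_plus <- vapply(101:400, oracle, integer(1), start = 101L, end = 400L, strand = "+")
  expect_equal(got_plus$codon, want_plus)
})

test_that("positions outside any CDS or on the wrong strand are unassigned", {
  genes <- tibble::tibble(gene_id = "g", contig = "chr1", strand = "+",
                          cds_start = 101L, cds_end = 400L,
                          sequence = NA_character_, n_codons = 100L)
  q <- tibble::tibble(
    read_id = c("upstream", "wrong_strand", "inside"),
    contig = "chr1",
    strand = c("+", "-", "+"),
    genomic_nt = c(100L, 200L, 200L)
  )
  got <- map_to_codon(q, genes)
  expect_equal(got$read_id, "inside")
  expect_equal(attr(got, "stats")$n_unassigned, 2)
})

test_that("counts accumulate into a dense per-gene per-codon grid", {
  genes <- tibble::tibble(gene_id = "geneA", contig = "chr1", strand = "+",
                          cds_start = 1L, cds_end = 60L,
                          sequence = NA_character_, n_codons = 20L)
  asg <- tibble::tibble(read_id = c("r1", "r2", "r3"), contig = "chr1",
                        strand = "+", genomic_nt = 28L)  # codon 10
  cc <- count_codons(asg, genes, sample_id = "s1")
  expect_equal(nrow(cc), 20)
  expect_equal(cc$count[cc$codon == 10], 3L)
  expect_equal(sum(cc$count), 3L)

  empty <- count_codons(asg[0, ], genes, sample_id = "s1")
  expect_true(all(empty$count == 0L))
  expect_equal(nrow(empty), 20)
})

test_that("overlapping same-strand genes follow the configured policy", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"),
    contig = "chr1",
    strand = "+",
    cds_start = c(1L, 31L),
    cds_end = c(90L, 120L),
    sequence = NA_character_,
    n_codons = c(30L, 30L)
  )
  q <- tibble::tibble(read_id = "r", contig = "chr1", strand = "+", genomic_nt = 50L)
  both <- map_to_codon(q, genes, overlap = "all")
  expect_setequal(both$gene_id, c("g1", "g2"))
  dropped <- map_to_codon(q, genes, overlap = "drop")
  expect_equal(nrow(dropped), 0)
  expect_equal(attr(dropped, "stats")$n_ambiguous_dropped, 1)
})

test_that("assignment reproduces simulator ground truth for every read on both strands", {
  sim <- small_sim(seed = 5, n_genes = 8, depth = 4000)
  for (cond in c("wt", "efp")) {
    fp <- simulate_footprints(sim, cond, 1, seed = 31 + (cond == "efp"))
    asg <- assign_three_prime(fp$alignments)
    cmp <- dplyr::inner_join(asg, fp$truth, by = "read_id")
    expect_equal(nrow(cmp), nrow(fp$truth))
    expect_true(all(cmp$genomic_nt == cmp$assigned_nt))
    mapped <- map_to_codon(asg, sim$genes)
    cmp2 <- dplyr::inner_join(mapped, fp$truth, by = "read_id",
                              suffix = c("", ".truth"))
    expect_true(all(cmp2$gene_id == cmp2$gene_id.truth))
    expect_true(all(cmp2$codon == cmp2$codon.truth))
  }
})
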