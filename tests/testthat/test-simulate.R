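test_that("configuration invariants are enforced", {
  expect_error(simulation_config(read_length_range = c(14, 40)), "15")
  expect_error(simulation_config(strand_fraction = 1.5), "strand_fraction")
  expect_error(stall_spec("PPPP", "efp", 10), "3-letter")
  expect_error(stall_spec("SPP", "efp", multiplier = 0.5), ">= 1")
  bad_usage <- stats::setNames(rep(1 / 61, 61), ribopause:::SENSE_CODONS)
  bad_usage[1] <- bad_usage[1] + 1e-3
  expect_error(simulation_config(codon_usage = bad_usage), "sum to 1")
  expect_error(
    simulation_config(planted_stalls = list(stall_spec("SPP", "mut", 5)),
                      conditions = c("wt", "efp")),
    "condition"
  )
})

test_that("generated genes have the configured geometry", {
  cfg <- simulation_config(n_genes = 1, codons_per_gene = 100, depth = 100, seed = 3)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$genes), 1)
  expect_equal(sim$genes$n_codons, 100)
  expect_equal(sim$genes$cds_end - sim$genes$cds_start + 1L, 300L)
  expect_equal(nchar(sim$genes$sequence), 300L)

  all_minus <- simulate_genome(
    simulation_config(n_genes = 5, codons_per_gene = 50, strand_fraction = 1,
                      depth = 100, seed = 3)
  )
  expect_true(all(all_minus$genes$strand == "-"))
})

test_that("every CDS starts ATG, ends with a stop, and has no internal stop", {
  sim <- small_sim()
  expect_true(all(substr(sim$genes$sequence, 1, 3) == "ATG"))
  aa <- ribopause:::codon_to_aa_strings(sim$genes$sequence)
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "*"))
  expect_false(any(grepl("\\*.", aa)))
})

test_that("genes are non-overlapping and minus-strand genomic slices are reverse-complemented", {
  sim <- small_sim()
  g <- sim$genes |> arrange(cds_start)
  expect_true(all(head(g$cds_end, -1) < tail(g$cds_start, -1)))
  minus <- g |> filter(strand == "-")
  for (i in seq_len(nrow(minus))) {
    slice <- as.character(Biostrings::subseq(sim$genome[[1]],
                                             minus$cds_start[i], minus$cds_end[i]))
    expect_equal(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice))),
      minus$sequence[i]
    )
  }
})

test_that("identical config and seed give byte-identical outputs", {
  f1 <- tempfile(); f2 <- tempfile()
  s1 <- simulate_genome(simulation_config(n_genes = 8, codons_per_gene = 60,
                                          depth = 500, seed = 11))
  s2 <- simulate_genome(simulation_config(n_genes = 8, codons_per_gene = 60,
                                          depth = 500, seed = 11))
  Biostrings::writeXStringSet(s1$genome, f1)
  Biostrings::writeXStringSet(s2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  fp1 <- simulate_footprints(s1, "wt", 1, seed = 5)
  fp2 <- simulate_footprints(s2, "wt", 1, seed = 5)
  expect_identical(fp1$alignments, fp2$alignments)
  fp3 <- simulate_footprints(s1, "wt", 1, seed = 6)
  expect_false(identical(fp1$alignments$start, fp3$alignments$start))
})

test_that("planted stalls sit at codons whose context matches the motif", {
  sim <- small_sim()
  aa_tab <- translate_genes(sim$genes)
  for (i in seq_len(nrow(sim$stalls))) {
    st <- sim$stalls[i, ]
    # stalled codon is the last proline of the planted motif, so for SPP the
    # window (P-1, P) reads "PP" preceded by "S"
    ctx <- aa_tab |>
      filter(gene_id == st$gene_id,
             codon %in% (st$codon - 2):(st$codon)) |>
      arrange(codon) |>
      pull(aa)
    expect_equal(paste(ctx, collapse = ""), st$motif)
  }
})

test_that("per-codon sampling matches the multinomial model", {
  # uniform occupancy: chi-square against the exact uniform expectation
  cfg <- simulation_config(n_genes = 1, codons_per_gene = 100,
                           expression = "uniform", depth = 10000, seed = 1)
  sim <- simulate_genome(cfg)
  fp <- simulate_footprints(sim, "wt", 1, seed = 1)
  obs <- tabulate(fp$truth$codon, nbins = 100)
  expect_equal(sum(obs), 10000)  # conservation: realized total equals depth
  p <- suppressWarnings(stats::chisq.test(obs, p = rep(1 / 100, 100))$p.value)
  expect_gt(p, 1e-6)
})

test_that("a planted multiplier is recovered within binomial error", {
  # one codon at multiplier 20 in a 101-codon gene: expected stalled/background
  # count ratio is 20; compare within 3 standard errors (binomial oracle)
  cfg <- simulation_config(
    n_genes = 1, codons_per_gene = 101, expression = "uniform",
    planted_stalls = list(stall_spec("APP", condition = "efp",
                                     multiplier = 20, n_sites = 1)),
    depth = 20000, seed = 2
  )
  sim <- simulate_genome(cfg)
  stall_codon <- sim$stalls$codon[1]
  fp <- simulate_footprints(sim, "efp", 1, seed = 2)
  counts <- tabulate(fp$truth$codon, nbins = 101)
  stalled <- counts[stall_codon]
  bg <- counts[-stall_codon]
  ratio <- stalled / mean(bg)
  n <- sum(counts)
  p_stall <- 20 / (100 + 20)
  e_stall <- n * p_stall
  e_bg <- n * (1 / 120)
  se_ratio <- 20 * sqrt(1 / e_stall + 1 / (length(bg) * e_bg))
  expect_lt(abs(ratio - 20), 3 * se_ratio)
})

test_that("queuing peaks appear upstream of the stall in translation order", {
  cfg <- simulation_config(
    n_genes = 1, codons_per_gene = 120, expression = "uniform",
    strand_fraction = 1,  # minus-strand gene: upstream must follow gene sense
    planted_stalls = list(stall_spec("SPP", "efp", multiplier = 20, n_sites = 1)),
    queue_offsets = tibble::tibble(offset = 10L, multiplier = 8),
    depth = 30000, seed = 4
  )
  sim <- simulate_genome(cfg)
  stall <- sim$stalls$codon[1]
  occ <- sim$occupancy |> filter(condition == "efp")
  expect_setequal(occ$codon, c(stall, stall - 10L))
  fp <- simulate_footprints(sim, "efp", 1, seed = 4)
  counts <- tabulate(fp$truth$codon, nbins = 120)
  bg <- mean(counts[-c(stall, stall - 10L)])
  expect_gt(counts[stall] / bg, 10)
  expect_gt(counts[stall - 10L] / bg, 4)
})

test_that("infeasible packing into a fixed contig length is an explicit error", {
  cfg <- simulation_config(n_genes = 10, codons_per_gene = 100,
                           contig_length = 500, depth = 100, seed = 1)
  expect_error(simulate_genome(cfg), "infeasible packing")
})
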