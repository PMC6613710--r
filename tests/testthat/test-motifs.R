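# build a gene-model tibble from amino-acid strings (one codon per residue,
# stop appended), plus a replicate-mean score table with given P-site scores
genes_from_peptides <- function(peptides) {
  aa2codon <- ribopause:::aa_codon_table()
  seqs <- vapply(peptides, function(p) {
    codons <- vapply(strsplit(p, "")[[1]], function(a) aa2codon[[a]][1], character(1))
    paste0(paste(codons, collapse = ""), "TAA")
  }, character(1))
  tibble::tibble(
    gene_id = names(peptides),
    contig = "chr1",
    strand = "+",
    cds_start = 1L,  # coordinates unused by motif operations
    cds_end = nchar(seqs),
    sequence = unname(seqs),
    n_codons = nchar(seqs) %/% 3L
  )
}

mean_scores <- function(condition, gene_id, codon, score) {
  tibble::tibble(condition = condition, gene_id = gene_id, codon = codon,
                 mean_score = score, sd_score = 0, n_reps = 3, sd_defined = TRUE)
}

test_that("differential calling applies the fold threshold with the absolute floor", {
  scores <- dplyr::bind_rows(
    mean_scores("wt", "g", 10:12, c(1.2, 2.0, 0)),
    mean_scores("efp", "g", 10:12, c(13.0, 15.0, 5.0))
  )
  out <- differential_pauses(scores, "wt", "efp", fold = 10, pseudocount = 0)
  r10 <- out[out$codon == 10, ]
  expect_equal(r10$fold, 13 / 1.2, tolerance = 1e-12)  # ~10.83
  expect_true(r10$called)
  r11 <- out[out$codon == 11, ]
  expect_equal(r11$fold, 7.5)
  expect_false(r11$called)

  # zero reference with a pseudocount: fold = 5.1/0.1 = 51 (floor relaxed to
  # isolate the pseudocount policy)
  ps <- differential_pauses(scores, "wt", "efp", fold = 10,
                            pseudocount = 0.1, min_score = 0)
  expect_equal(ps$fold[ps$codon == 12], 51, tolerance = 1e-12)
  expect_true(ps$called[ps$codon == 12])
  # with the default floor of 10, a score of 5 is not callable
  flo <- differential_pauses(scores, "wt", "efp", fold = 10, pseudocount = 0.1)
  expect_false(flo$called[flo$codon == 12])

  tally <- attr(out, "tally")
  expect_equal(tally$n_called_codons, sum(out$called))
  expect_error(differential_pauses(scores, "wt", "efp", fold = 0), "fold")
})

test_that("tripeptide tables enumerate all 8,000 tripeptides in both framings", {
  genes <- genes_from_peptides(c(g1 = "MAAAAPPAAAAAAAAAAAAA"))
  scores <- mean_scores("efp", "g1", 7:14, 1)
  for (fr in c("p_centered", "e_centered")) {
    tp <- tripeptide_scores(scores, genes, framing = fr)
    expect_equal(nrow(tp), 8000L)
    expect_equal(dplyr::n_distinct(tp$tripeptide), 8000L)
  }
})

test_that("tripeptide means average the P-site codon score per framing", {
  # APP occurs at residues 5-7 and 13-15 of g1
  genes <- genes_from_peptides(c(g1 = "MAAAAPPAAAAAAPPAAAAA"))
  aa <- ribopause:::codon_to_aa_strings(genes$sequence)
  expect_equal(unlist(gregexpr("APP", aa)), c(5L, 13L))
  # P-centered framing EPA: tripeptide APP has its P-site at the middle codon,
  # i.e. codons 6 and 14; give those P-site scores 4 and 6
  scores <- mean_scores("efp", "g1", 7:14, 0.5)
  scores$mean_score[scores$codon == 14] <- 6
  # codon 6 is edge-excluded in real tables; emulate a wider table here
  scores <- dplyr::bind_rows(scores, mean_scores("efp", "g1", 6L, 4))
  tp <- tripeptide_scores(scores, genes, framing = "p_centered")
  row <- tp[tp$tripeptide == "APP", ]
  expect_equal(row$n_occurrences, 2L)
  expect_equal(row$mean_score, 5.0)

  # E-centered framing (-2, E, P): the same codons carry tripeptide AAP
  tp_e <- tripeptide_scores(scores, genes, framing = "e_centered")
  expect_equal(tp_e$n_occurrences[tp_e$tripeptide == "AAP"], 2L)
  expect_equal(tp_e$mean_score[tp_e$tripeptide == "AAP"], 5.0)

  never <- tp[tp$tripeptide == "WWW", ]
  expect_equal(never$n_occurrences, 0L)
  expect_true(is.na(never$mean_score))
})

test_that("tripeptide occurrences conserve the number of full-context codons", {
  sim <- small_sim(seed = 17, n_genes = 6, depth = 3000)
  fp1 <- simulate_footprints(sim, "wt", 1, seed = 171)
  fp2 <- simulate_footprints(sim, "wt", 2, seed = 172)
  counts <- dplyr::bind_rows(
    count_codons(assign_three_prime(fp1$alignments), sim$genes, "wt_1"),
    count_codons(assign_three_prime(fp2$alignments), sim$genes, "wt_2")
  )
  scores <- pause_scores(counts)
  sheet <- tibble::tibble(sample_id = c("wt_1", "wt_2"), condition = "wt",
                          replicate = 1:2)
  means <- average_replicates(scores, sheet)
  for (fr in c("p_centered", "e_centered")) {
    tp <- tripeptide_scores(means, sim$genes, framing = fr)
    # every reported codon has full context here: edges are >= 6 codons away
    # from the start and the stop codon
    expect_equal(sum(tp$n_occurrences), nrow(means))
  }
})

test_that("logo windows are weighted by the P-site pause score and normalized", {
  genes <- genes_from_peptides(c(g1 = "MAASPPAAAAAAAAAA", g2 = "MAASPPCAAAAAAAAA"))
  # P-site codon 6 in both genes: the -2..+1 windows read S-P-P-A (g1) and
  # S-P-P-C (g2), differing only at the A-site
  scores <- dplyr::bind_rows(
    mean_scores("efp", "g1", 6L, 10),
    mean_scores("efp", "g2", 6L, 30)
  )
  lg <- weighted_logo(scores, genes, min_score = 10)
  expect_equal(colnames(lg), c("-2", "E", "P", "A"))
  expect_true(all(abs(colSums(lg) - 1) < 1e-9))
  expect_equal(unname(lg["S", "-2"]), 1)
  expect_equal(unname(lg["P", "P"]), 1)
  expect_equal(unname(lg["A", "A"]), 0.25)  # weight 10 of 40
  expect_equal(unname(lg["C", "A"]), 0.75)  # weight 30 of 40

  one <- weighted_logo(mean_scores("efp", "g1", 6L, 17), genes, min_score = 10)
  expect_true(all(one[cbind(c("S", "P", "P", "A"), colnames(one))] == 1))

  expect_error(weighted_logo(mean_scores("efp", "g1", 6L, 2), genes, min_score = 10),
               "qualify")

  unw <- weighted_logo(scores, genes, min_score = 10, weighted = FALSE)
  expect_equal(unname(unw["A", "A"]), 0.5)
})

test_that("gene profiles slice windows and annotate motifs", {
  genes <- genes_from_peptides(c(g1 = paste0("M", strrep("A", 10), "SPP", strrep("A", 16))))
  scores <- mean_scores("efp", "g1", 7L:24L, 1)
  prof <- gene_profile(scores, "g1", motif = "SPP", genes = genes)
  expect_s3_class(prof, "pause_profile")
  expect_true(all(prof$mean_score == 1))
  expect_equal(prof$codon[prof$motif_hit], 12:14)

  win <- gene_profile(scores, "g1", window = c(10, 20))
  expect_equal(nrow(win), 11)

  dens <- tibble::tibble(sample_id = c("s1", "s2"), gene_id = "gX",
                         n_codons = 10L, total = c(2L, 0L), density = c(0.2, 0))
  expect_error(gene_profile(scores, "gX", densities = dens), "s2")
})
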