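#' Planted-stall recovery benchmark on simulated footprints
#'
#' Simulates a two-condition experiment with stall motifs planted in the test
#' condition, runs the assignment/scoring/differential pipeline in memory,
#' and measures how well the differential-pause criterion recovers the
#' planted codons: sensitivity (planted codons called) and the false-call
#' rate among unplanted reported codons. Queuing is disabled so every
#' elevated codon is a planted stall.
#'
#' @param seed Integer seed (drives genome and all samples).
#' @param motif Stall motif to plant (default `"PPX"`; `X` is a wildcard).
#' @param n_genes,codons_per_gene Genome shape (defaults 50 genes x 200
#'   codons).
#' @param reads_per_codon Expected background depth per codon; per-sample
#'   depth is `reads_per_codon * n_genes * codons_per_gene`.
#' @param multiplier Planted occupancy multiplier (default 25).
#' @param n_sites Number of planted codons (default 30, one per gene).
#' @param n_replicates Replicates per condition (default 3).
#' @param fold,min_score Differential-calling thresholds (defaults 10, 10).
#' @return A list: `sensitivity` and `false_call_rate` (proportions),
#'   `n_planted`, `n_called`, `n_reported` (codons tested), the
#'   replicate-mean table `means`, the `differential` table, the `sim`
#'   object and the condition labels.
#' @export
benchmark_stall_recovery <- function(seed, motif = "PPX", n_genes = 50,
                                     codons_per_gene = 200, reads_per_codon = 5,
                                     multiplier = 25, n_sites = 30,
                                     n_replicates = 3, fold = 10, min_score = 10) {
  cfg <- simulation_config(
    n_genes = n_genes,
    codons_per_gene = codons_per_gene,
    strand_fraction = 0.5,
    planted_stalls = list(stall_spec(motif, condition = "efp",
                                     multiplier = multiplier, n_sites = n_sites)),
    expression = "uniform",
    depth = reads_per_codon * n_genes * codons_per_gene,
    n_replicates = n_replicates,
    conditions = c("wt", "efp"),
    seed = seed
  )
  sim <- simulate_genome(cfg)

  sheet <- expand_grid(condition = cfg$conditions,
                       replicate = seq_len(n_replicates)) |>
    mutate(sample_id = sprintf("%s_%d", .data$condition, .data$replicate))
  counts <- purrr::pmap(sheet, function(condition, replicate, sample_id) {
    fp <- simulate_footprints(
      sim, condition, replicate,
      seed = as.integer((as.numeric(seed) * 1000 +
                           match(sample_id, sheet$sample_id)) %% 2147483647)
    )
    count_codons(assign_three_prime(fp$alignments), sim$genes, sample_id)
  }) |> bind_rows()

  scores <- pause_scores(counts)
  means <- average_replicates(scores, sheet)
  differential <- differential_pauses(means, "wt", "efp",
                                      fold = fold, min_score = min_score)

  planted <- sim$stalls |> select("gene_id", "codon") |> mutate(planted = TRUE)
  eval_tab <- differential |>
    left_join(planted, by = c("gene_id", "codon")) |>
    mutate(planted = !is.na(.data$planted))

  n_planted_reported <- sum(eval_tab$planted)
  sensitivity <- sum(eval_tab$called & eval_tab$planted) / nrow(planted)
  false_calls <- sum(eval_tab$called & !eval_tab$planted)
  false_call_rate <- false_calls / sum(!eval_tab$planted)

  list(sensitivity = sensitivity,
       false_call_rate = false_call_rate,
       n_planted = nrow(planted),
       n_planted_reported = n_planted_reported,
       n_called = sum(eval_tab$called),
       n_reported = nrow(eval_tab),
       means = means,
       differential = differential,
       sim = sim,
       conditions = cfg$conditions)
}
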