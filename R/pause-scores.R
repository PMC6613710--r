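#' Per-gene average read density
#'
#' Density is the number of reads mapped to a gene divided by its codon
#' count, computed per sample over ALL codons of the gene (edges and stop
#' codon included; the edge exclusion applies only to pause-score reporting).
#'
#' @param counts Codon count tibble (`sample_id`, `gene_id`, `codon`,
#'   `count`) from [count_codons()], possibly row-bound over samples.
#' @return Tibble `sample_id`, `gene_id`, `n_codons`, `total`, `density`.
#' @export
gene_density <- function(counts) {
  counts |>
    group_by(.data$sample_id, .data$gene_id) |>
    summarise(n_codons = max(.data$codon),
              total = sum(.data$count),
              .groups = "drop") |>
    mutate(density = .data$total / .data$n_codons)
}

#' Gene density filter across all samples
#'
#' A gene is analyzed only if its average read density is strictly greater
#' than the threshold in EVERY sample of the run (a density of exactly 0.1
#' in any one sample fails the default filter).
#'
#' @param densities Tibble from [gene_density()] covering every sample.
#' @param threshold Density cutoff (default 0.1 reads/codon, strict `>`).
#' @param samples Sample ids that must all pass; defaults to every sample
#'   present in `densities`.
#' @return Character vector of passing gene ids.
#' @export
filter_genes <- function(densities, threshold = 0.1, samples = NULL) {
  samples <- samples %||% unique(densities$sample_id)
  d <- densities |> filter(.data$sample_id %in% samples)
  seen <- d |> count(.data$gene_id, name = "n_samples")
  if (any(seen$n_samples != length(samples))) {
    abort("every gene must have a density in every sample; missing sample(s) detected.")
  }
  d |>
    group_by(.data$gene_id) |>
    summarise(pass = all(.data$density > threshold), .groups = "drop") |>
    filter(.data$pass) |>
    pull("gene_id")
}

#' Per-codon pause scores for one or more samples
#'
#' The pause score of a codon is the number of reads assigned to it divided
#' by the gene's average read density in that sample, so a score of 1 means
#' average occupancy. The density denominator is computed over all codons,
#' but scores are reported only for codons `edge_exclude + 1` through
#' `n_codons - edge_exclude` (default: the first and last 6 codons are
#' excluded) of genes passing the density filter.
#'
#' @param counts Codon count tibble over all samples of the run.
#' @param threshold Density filter cutoff (strict), default 0.1.
#' @param edge_exclude Codons excluded at each gene end, default 6.
#' @param passing Optional pre-computed vector of passing gene ids; by
#'   default the filter is applied across all samples present in `counts`.
#' @return Tibble `sample_id`, `gene_id`, `codon`, `count`, `density`,
#'   `score`, restricted to reported codons of passing genes.
#' @export
pause_scores <- function(counts, threshold = 0.1, edge_exclude = 6L,
                         passing = NULL) {
  densities <- gene_density(counts)
  passing <- passing %||% filter_genes(densities, threshold = threshold)
  if (length(passing) == 0) {
    warn("no genes pass the density filter.")
  }
  scored <- counts |>
    filter(.data$gene_id %in% passing) |>
    left_join(densities |> select("sample_id", "gene_id", "n_codons", "density"),
              by = c("sample_id", "gene_id"))
  if (any(scored$density <= 0)) {
    # impossible for genes passing a strict positive filter
    abort("zero density for a passing gene; filter invariant violated.")
  }
  scored |>
    mutate(score = .data$count / .data$density) |>
    filter(.data$codon > edge_exclude,
           .data$codon <= .data$n_codons - edge_exclude) |>
    select("sample_id", "gene_id", "codon", "count", "density", "score")
}

#' Average pause scores across biological replicates
#'
#' Per codon, the replicate scores of a condition are summarized by their
#' mean and sample standard deviation (n - 1 denominator). With a single
#' replicate the mean is the value itself and the standard deviation is
#' reported as 0 with `sd_defined = FALSE`.
#'
#' @param scores Per-sample pause-score tibble from [pause_scores()].
#' @param sample_sheet Tibble `sample_id`, `condition`, `replicate`.
#' @return Tibble `condition`, `gene_id`, `codon`, `mean_score`, `sd_score`,
#'   `n_reps`, `sd_defined`.
#' @export
average_replicates <- function(scores, sample_sheet) {
  stopifnot(all(c("sample_id", "condition") %in% names(sample_sheet)))
  missing <- setdiff(unique(scores$sample_id), sample_sheet$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) absent from sample sheet: %s",
                  paste(missing, collapse = ", ")))
  }
  per_cond <- scores |>
    inner_join(sample_sheet |> select("sample_id", "condition"), by = "sample_id") |>
    group_by(.data$condition, .data$gene_id, .data$codon) |>
    summarise(mean_score = mean(.data$score),
              sd_score = if (n() > 1) sd(.data$score) else 0,
              n_reps = n(),
              .groups = "drop") |>
    mutate(sd_defined = .data$n_reps > 1)
  # identical codon sets per condition are guaranteed by the all-samples
  # filter; verify rather than assume
  sets <- per_cond |> count(.data$condition, name = "n_rows")
  if (length(unique(sets$n_rows)) > 1) {
    abort("conditions cover different codon sets; filter must span all samples.")
  }
  per_cond
}
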