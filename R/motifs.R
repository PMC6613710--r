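#' Per-codon amino-acid table for a set of genes
#'
#' Translates each gene's in-frame sense sequence; the stop codon is rendered
#' as `"*"` and is never part of a tripeptide or logo window.
#'
#' @param genes Gene-model tibble.
#' @return Tibble `gene_id`, `codon`, `aa`.
#' @export
translate_genes <- function(genes) {
  aa <- codon_to_aa_strings(genes$sequence)
  tibble(
    gene_id = rep(genes$gene_id, nchar(aa)),
    codon = unlist(lapply(nchar(aa), seq_len), use.names = FALSE),
    aa = unlist(strsplit(aa, ""), use.names = FALSE)
  )
}

#' Call differential pauses between two conditions
#'
#' Compares replicate-mean pause scores codon by codon: a codon is called as
#' a condition-B-specific pause when its fold change
#' `(score_b + pseudocount) / (score_a + pseudocount)` is at least `fold`
#' (default 10) AND its condition-B score is at least `min_score` (an
#' absolute floor that prevents infinite or unstable folds when the
#' reference score is near zero).
#'
#' @param scores Replicate-mean tibble from [average_replicates()] covering
#'   both conditions.
#' @param condition_a Reference condition (e.g. wild type).
#' @param condition_b Test condition (e.g. the mutant).
#' @param fold Fold-change threshold (> 0), default 10.
#' @param pseudocount Added to both scores before the ratio, default 0.
#' @param min_score Absolute floor on `score_b` for a call, default 10.
#' @return Tibble `gene_id`, `codon`, `score_a`, `score_b`, `fold`, `called`,
#'   sorted by decreasing fold among called codons first; attribute
#'   `"tally"`: one-row tibble `n_called_codons`, `n_called_genes`.
#' @export
differential_pauses <- function(scores, condition_a, condition_b,
                                fold = 10, pseudocount = 0, min_score = 10) {
  if (fold <= 0) abort("fold threshold must be > 0.")
  a <- scores |> filter(.data$condition == condition_a) |>
    select("gene_id", "codon", score_a = "mean_score")
  b <- scores |> filter(.data$condition == condition_b) |>
    select("gene_id", "codon", score_b = "mean_score")
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("both conditions must be present in the score table.")
  }
  out <- inner_join(a, b, by = c("gene_id", "codon")) |>
    mutate(fold = (.data$score_b + pseudocount) / (.data$score_a + pseudocount),
           called = .data$fold >= !!fold & .data$score_b >= min_score) |>
    arrange(dplyr::desc(.data$called), dplyr::desc(.data$fold))
  attr(out, "tally") <- tibble(
    n_called_codons = sum(out$called),
    n_called_genes = dplyr::n_distinct(out$gene_id[out$called])
  )
  out
}

#' Aggregate P-site pause scores over all 8,000 tripeptides
#'
#' Every analyzed codon (post edge-exclusion) whose framing window lies fully
#' inside the CDS and contains no stop contributes its P-site pause score to
#' one tripeptide. Two framings are supported, both scored by the P-site
#' codon only: `"p_centered"` frames the E-, P- and A-site residues (codons
#' P-1, P, P+1); `"e_centered"` frames the -2, E and P residues (codons P-2,
#' P-1, P). The output enumerates all 20^3 = 8,000 tripeptides; tripeptides
#' never observed carry `n_occurrences = 0` and an undefined (NA) mean.
#'
#' @param scores Pause scores for ONE condition: tibble with `gene_id`,
#'   `codon` and a score column (`mean_score` or `score`).
#' @param genes Gene-model tibble (for translations).
#' @param framing `"p_centered"` or `"e_centered"`.
#' @return Tibble of 8,000 rows: `tripeptide`, `n_occurrences`, `mean_score`,
#'   `framing`.
#' @export
tripeptide_scores <- function(scores, genes, framing = c("p_centered", "e_centered")) {
  framing <- match.arg(framing)
  score_col <- if ("mean_score" %in% names(scores)) "mean_score" else "score"
  if ("condition" %in% names(scores) && dplyr::n_distinct(scores$condition) > 1) {
    abort("scores must cover a single condition; filter before aggregating.")
  }
  offsets <- if (framing == "p_centered") c(-1L, 0L, 1L) else c(-2L, -1L, 0L)

  aa_tab <- translate_genes(genes)
  ctx <- scores |>
    select("gene_id", "codon", score = dplyr::all_of(score_col))
  for (i in seq_along(offsets)) {
    ctx <- ctx |>
      left_join(aa_tab |> rename(!!paste0("aa", i) := "aa") |>
                  mutate(codon = .data$codon - offsets[i]),
                by = c("gene_id", "codon"))
  }
  ctx <- ctx |>
    mutate(tripeptide = paste0(.data$aa1, .data$aa2, .data$aa3)) |>
    filter(!is.na(.data$aa1), !is.na(.data$aa2), !is.na(.data$aa3),
           !stringr::str_detect(.data$tripeptide, "\\*"))

  all_tri <- expand_grid(a1 = AA_ALPHABET20, a2 = AA_ALPHABET20, a3 = AA_ALPHABET20) |>
    mutate(tripeptide = paste0(.data$a1, .data$a2, .data$a3)) |>
    select("tripeptide")

  observed <- ctx |>
    group_by(.data$tripeptide) |>
    summarise(n_occurrences = n(), mean_score = mean(.data$score), .groups = "drop")

  all_tri |>
    left_join(observed, by = "tripeptide") |>
    mutate(n_occurrences = if_else(is.na(.data$n_occurrences), 0L, .data$n_occurrences),
           framing = framing)
}

#' Weighted amino-acid logo of high-pause contexts
#'
#' Collects the amino-acid window around every analyzed codon whose P-site
#' pause score meets `min_score` (default 10) and has full context inside the
#' CDS, and builds a position weight matrix in which each window contributes
#' weight equal to its P-site pause score (set `weighted = FALSE` for equal
#' weights). Columns (positions) are normalized to sum to 1.
#'
#' @param scores Pause scores for ONE condition (`gene_id`, `codon`,
#'   `mean_score` or `score`).
#' @param genes Gene-model tibble.
#' @param min_score Minimum P-site pause score for a window to qualify.
#' @param window Codon offsets relative to the P-site, `c(from, to)`;
#'   default `c(-2, 1)` spans the -2, E, P and A sites.
#' @param weighted Weight windows by their P-site score?
#' @return A matrix of class `logo_matrix` (20 amino-acid rows x window
#'   positions, columns named by site: `-2`, `E`, `P`, `A`, `+2`, ...), each
#'   column summing to 1; attribute `"n_windows"` is the number of
#'   contributing windows.
#' @export
weighted_logo <- function(scores, genes, min_score = 10, window = c(-2L, 1L),
                          weighted = TRUE) {
  stopifnot(length(window) == 2, window[1] <= 0, window[2] >= 0)
  score_col <- if ("mean_score" %in% names(scores)) "mean_score" else "score"
  offsets <- seq(window[1], window[2])
  aa_tab <- translate_genes(genes)

  qual <- scores |>
    select("gene_id", "codon", score = dplyr::all_of(score_col)) |>
    filter(.data$score >= min_score)
  ctx <- qual
  for (i in seq_along(offsets)) {
    ctx <- ctx |>
      left_join(aa_tab |> rename(!!paste0("aa", i) := "aa") |>
                  mutate(codon = .data$codon - offsets[i]),
                by = c("gene_id", "codon"))
  }
  aa_cols <- paste0("aa", seq_along(offsets))
  full <- ctx |>
    filter(dplyr::if_all(dplyr::all_of(aa_cols), ~ !is.na(.x) & .x != "*"))
  if (nrow(full) == 0) {
    abort(sprintf("no codon windows qualify at min_score = %s.", format(min_score)))
  }
  w <- if (weighted) full$score else rep(1, nrow(full))
  mat <- sapply(aa_cols, function(col) {
    v <- tapply(w, factor(full[[col]], levels = AA_ALPHABET20), sum, default = 0)
    v / sum(v)
  })
  colnames(mat) <- site_labels(offsets)
  rownames(mat) <- AA_ALPHABET20
  structure(mat, n_windows = nrow(full), class = c("logo_matrix", "matrix", "array"))
}

# ribosome-site labels for codon offsets relative to the P-site
site_labels <- function(offsets) {
  vapply(offsets, function(o) {
    switch(as.character(o), "-1" = "E", "0" = "P", "1" = "A",
           ifelse(o > 0, paste0("+", o), as.character(o)))
  }, character(1))
}

#' Per-gene pause profile
#'
#' Replicate-mean pause scores (with standard deviations) along one gene,
#' optionally sliced to a codon window and annotated with the positions of an
#' amino-acid motif found by scanning the translation (e.g. `"SPP"`).
#'
#' @param scores Replicate-mean tibble from [average_replicates()], one
#'   condition (or pass `condition` to select one).
#' @param gene One gene id.
#' @param condition Optional condition label to select from `scores`.
#' @param window Optional inclusive codon window `c(from, to)`.
#' @param motif Optional amino-acid motif to annotate.
#' @param genes Gene-model tibble; required when `motif` is given.
#' @param densities Optional [gene_density()] table used to explain a
#'   filtered-out gene by naming the failing samples.
#' @param threshold Density cutoff used for that explanation.
#' @return Tibble of class `pause_profile`: `gene_id`, `codon`, `mean_score`,
#'   `sd_score`, and `motif_hit` (logical) when a motif is scanned.
#' @export
gene_profile <- function(scores, gene, condition = NULL, window = NULL,
                         motif = NULL, genes = NULL, densities = NULL,
                         threshold = 0.1) {
  if (!is.null(condition)) scores <- scores |> filter(.data$condition == !!condition)
  prof <- scores |> filter(.data$gene_id == gene)
  if (nrow(prof) == 0) {
    if (!is.null(densities)) {
      failing <- densities |>
        filter(.data$gene_id == gene, .data$density <= threshold) |>
        pull("sample_id")
      if (length(failing) > 0) {
        abort(sprintf("gene '%s' failed the density filter in sample(s): %s",
                      gene, paste(failing, collapse = ", ")))
      }
    }
    abort(sprintf("gene '%s' has no reported pause scores (filtered out or unknown).", gene))
  }
  if (!"sd_score" %in% names(prof)) prof$sd_score <- NA_real_
  prof <- prof |>
    select("gene_id", "codon", "mean_score", "sd_score") |>
    arrange(.data$codon)
  if (!is.null(motif)) {
    if (is.null(genes)) abort("genes are required to annotate a motif.")
    aa <- codon_to_aa_strings(genes$sequence[genes$gene_id == gene])
    hit_starts <- as.integer(gregexpr(motif, aa)[[1]])
    hit_codons <- if (hit_starts[1] == -1) integer(0) else
      unlist(lapply(hit_starts, function(s) s:(s + nchar(motif) - 1L)))
    prof$motif_hit <- prof$codon %in% hit_codons
  }
  if (!is.null(window)) {
    prof <- prof |> filter(.data$codon >= window[1], .data$codon <= window[2])
  }
  class(prof) <- c("pause_profile", class(prof))
  prof
}
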