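#' Configure a pipeline run
#'
#' Collects the sample sheet and the analysis constants. Defaults are the
#' reference constants of the protocol: 3' offset 15, density threshold 0.1,
#' 6 edge codons excluded, 10-fold differential criterion with an absolute
#' floor of 10, logo threshold 10.
#'
#' @param sample_sheet Tibble with `sample_id`, `condition`, `replicate`,
#'   `path` (SAM/BAM alignment file per sample).
#' @param genome_fasta,annotation Paths to the genome FASTA and CDS
#'   annotation (GFF3).
#' @param out_dir Output directory for tables and the manifest.
#' @param contrast Length-2 character vector `c(reference, test)` of
#'   condition labels for differential calling.
#' @param offset,density_threshold,edge_exclude,fold,pseudocount,min_score
#'   Analysis constants (see the stage functions).
#' @param overlap Overlapping-gene policy for [map_to_codon()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(sample_sheet, genome_fasta, annotation, out_dir,
                       contrast = NULL, offset = 15L, density_threshold = 0.1,
                       edge_exclude = 6L, fold = 10, pseudocount = 0,
                       min_score = 10, overlap = "all") {
  sample_sheet <- as_tibble(sample_sheet)
  stopifnot(all(c("sample_id", "condition", "replicate", "path") %in% names(sample_sheet)))
  if (anyDuplicated(sample_sheet$sample_id)) abort("sample_ids must be unique.")
  conds <- unique(sample_sheet$condition)
  contrast <- contrast %||% conds[seq_len(min(2, length(conds)))]
  missing <- sample_sheet$path[!file.exists(sample_sheet$path)]
  if (length(missing) > 0) {
    abort(sprintf("alignment file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  for (f in c(genome_fasta, annotation)) {
    if (!file.exists(f)) abort(sprintf("input file not found: %s", f))
  }
  structure(list(sample_sheet = sample_sheet, genome_fasta = genome_fasta,
                 annotation = annotation, out_dir = out_dir, contrast = contrast,
                 offset = as.integer(offset), density_threshold = density_threshold,
                 edge_exclude = as.integer(edge_exclude), fold = fold,
                 pseudocount = pseudocount, min_score = min_score,
                 overlap = overlap),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level keys `genome_fasta`,
#' `annotation`, `out_dir`, optional parameter keys, and a `samples` list of
#' mappings with `sample_id`, `condition`, `replicate`, `path`. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if_else(grepl("^/", p), p, file.path(base, p))
  sheet <- purrr::map(y$samples, as_tibble) |> list_rbind() |>
    mutate(path = resolve(.data$path))
  run_config(
    sample_sheet = sheet,
    genome_fasta = resolve(y$genome_fasta),
    annotation = resolve(y$annotation),
    out_dir = y$out_dir %||% file.path(base, "results"),
    contrast = y$contrast,
    offset = y$offset %||% 15L,
    density_threshold = y$density_threshold %||% 0.1,
    edge_exclude = y$edge_exclude %||% 6L,
    fold = y$fold %||% 10,
    pseudocount = y$pseudocount %||% 0,
    min_score = y$min_score %||% 10,
    overlap = y$overlap %||% "all"
  )
}

#' Run the full pause-score pipeline
#'
#' Orchestrates assignment, density filtering, pause scoring, replicate
#' averaging, differential calling, tripeptide aggregation (both framings,
#' both contrast conditions), weighted logos and a per-gene profile of the
#' top called gene. Every table is written as TSV under `out_dir` and listed
#' in a manifest with MD5 checksums; identical inputs and configuration give
#' identical outputs.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @param quiet Suppress per-stage progress messages?
#' @return An object of class `pause_run`: a list with the key tables
#'   (`counts`, `densities`, `passing`, `scores`, `means`, `differential`,
#'   `tripeptides`, `logos`, `profile`, `assignment_stats`), the `config`,
#'   and the output `manifest` (tibble `file`, `md5`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) inform(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- stage("genome", read_genome_fasta(config$genome_fasta))
  genes <- stage("annotation", read_annotation(config$annotation, genome, "gff3"))
  say("annotation: %d genes", nrow(genes))

  counts_list <- list()
  stats_list <- list()
  for (i in seq_len(nrow(config$sample_sheet))) {
    s <- config$sample_sheet[i, ]
    aln <- stage(paste0("read_alignments:", s$sample_id),
                 read_alignments(s$path, require_unique = TRUE))
    assigned <- stage(paste0("assign:", s$sample_id),
                      assign_three_prime(aln, offset = config$offset))
    cc <- stage(paste0("count:", s$sample_id),
                count_codons(assigned, genes, s$sample_id, overlap = config$overlap))
    counts_list[[s$sample_id]] <- cc
    stats_list[[s$sample_id]] <- attr(cc, "stats")
    say("sample %s: %d reads, %d assigned in CDS",
        s$sample_id, nrow(aln), attr(cc, "stats")$n_assigned)
  }
  counts <- bind_rows(counts_list)
  assignment_stats <- bind_rows(stats_list)

  densities <- gene_density(counts)
  passing <- filter_genes(densities, threshold = config$density_threshold)
  say("density filter (> %g in all %d samples): %d/%d genes pass",
      config$density_threshold, nrow(config$sample_sheet), length(passing), nrow(genes))
  scores <- pause_scores(counts, threshold = config$density_threshold,
                         edge_exclude = config$edge_exclude, passing = passing)
  means <- average_replicates(scores, config$sample_sheet)

  cond_a <- config$contrast[1]
  cond_b <- config$contrast[2]
  differential <- differential_pauses(means, cond_a, cond_b, fold = config$fold,
                                      pseudocount = config$pseudocount,
                                      min_score = config$min_score)
  tally <- attr(differential, "tally")
  say("differential (fold >= %g, %s vs %s): %d codons in %d genes",
      config$fold, cond_b, cond_a, tally$n_called_codons, tally$n_called_genes)

  tripeptides <- list()
  logos <- list()
  for (cond in c(cond_a, cond_b)) {
    m <- means |> filter(.data$condition == cond)
    for (fr in c("p_centered", "e_centered")) {
      tripeptides[[paste(cond, fr, sep = ".")]] <-
        tripeptide_scores(m, genes, framing = fr) |> mutate(condition = cond)
    }
    logos[[cond]] <- tryCatch(
      weighted_logo(m, genes, min_score = config$min_score),
      error = function(e) {
        say("logo skipped for %s: %s", cond, conditionMessage(e))
        NULL
      }
    )
  }

  profile <- NULL
  if (tally$n_called_codons > 0) {
    top_gene <- differential$gene_id[differential$called][1]
    profile <- gene_profile(means, top_gene, condition = cond_b)
  }

  # write outputs + manifest
  paths <- c(
    assignment_stats = "assignment_stats.tsv",
    densities = "gene_densities.tsv",
    pause_scores = "pause_scores.tsv",
    condition_means = "pause_score_means.tsv",
    differential = "differential_pauses.tsv",
    tripeptides = "tripeptide_scores.tsv",
    profile = "top_gene_profile.tsv"
  )
  paths <- setNames(file.path(config$out_dir, paths), names(paths))
  readr::write_tsv(assignment_stats, paths["assignment_stats"])
  readr::write_tsv(densities, paths["densities"])
  readr::write_tsv(scores, paths["pause_scores"])
  readr::write_tsv(means, paths["condition_means"])
  readr::write_tsv(differential, paths["differential"])
  readr::write_tsv(bind_rows(tripeptides), paths["tripeptides"])
  if (!is.null(profile)) readr::write_tsv(profile, paths["profile"])
  for (cond in names(logos)) {
    if (!is.null(logos[[cond]])) {
      lp <- file.path(config$out_dir, sprintf("logo_%s.tsv", cond))
      readr::write_tsv(as_tibble(unclass(logos[[cond]]), rownames = "aa"), lp)
      paths[paste0("logo_", cond)] <- lp
    }
  }
  written <- paths[file.exists(paths)]
  manifest <- tibble(file = basename(written),
                     md5 = unname(tools::md5sum(written)))
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  structure(list(counts = counts, densities = densities, passing = passing,
                 scores = scores, means = means, differential = differential,
                 tripeptides = tripeptides, logos = logos, profile = profile,
                 assignment_stats = assignment_stats, genes = genes,
                 config = config, manifest = manifest),
            class = "pause_run")
}

#' @export
print.pause_run <- function(x, ...) {
  tally <- attr(x$differential, "tally")
  cat("<pause_run>\n")
  cat(sprintf("  samples: %d  genes: %d (passing filter: %d)\n",
              nrow(x$config$sample_sheet), nrow(x$genes), length(x$passing)))
  cat(sprintf("  reported codons per sample: %d\n",
              nrow(x$scores) / max(1, nrow(x$config$sample_sheet))))
  cat(sprintf("  differential calls (%s vs %s, fold >= %g): %d codons in %d genes\n",
              x$config$contrast[2], x$config$contrast[1], x$config$fold,
              tally$n_called_codons, tally$n_called_genes))
  invisible(x)
}

#' Tidy the replicate-mean pause-score table of a run
#'
#' @param x A `pause_run`.
#' @param ... Unused.
#' @return The replicate-mean pause-score tibble.
#' @method tidy pause_run
#' @export
tidy.pause_run <- function(x, ...) x$means

#' One-row summary of a pipeline run
#'
#' @param x A `pause_run`.
#' @param ... Unused.
#' @return One-row tibble: sample/gene tallies, reported codon count and
#'   differential-call tallies.
#' @method glance pause_run
#' @export
glance.pause_run <- function(x, ...) {
  tally <- attr(x$differential, "tally")
  tibble(
    n_samples = nrow(x$config$sample_sheet),
    n_genes = nrow(x$genes),
    n_genes_passing = length(x$passing),
    n_codons_reported = nrow(x$means) / max(1, dplyr::n_distinct(x$means$condition)),
    n_called_codons = tally$n_called_codons,
    n_called_genes = tally$n_called_genes,
    total_assigned = sum(x$assignment_stats$n_assigned)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
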