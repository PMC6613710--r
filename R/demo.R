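#' Default demo simulation configuration
#'
#' Two conditions (`wt`, `efp`) with three replicates each over 50 genes;
#' SPP and PPP stall motifs are planted with 20-fold occupancy in the `efp`
#' condition, together with queuing peaks 10 and 17 codons upstream of each
#' stall. Depth is 30,000 assigned reads per sample, a desk-scale stand-in
#' for deep footprint libraries.
#'
#' @param seed Integer seed.
#' @param n_genes,depth Overrides for the gene count and per-sample depth.
#' @return A [simulation_config()] object.
#' @export
demo_config <- function(seed = 1, n_genes = 50, depth = 30000) {
  simulation_config(
    n_genes = n_genes,
    codons_per_gene = c(80, 200),
    strand_fraction = 0.5,
    planted_stalls = list(
      stall_spec("SPP", condition = "efp", multiplier = 20, n_sites = 8),
      stall_spec("PPP", condition = "efp", multiplier = 20, n_sites = 8)
    ),
    queue_offsets = tibble(offset = c(10L, 17L), multiplier = c(4, 2)),
    expression = "lognormal",
    depth = depth,
    n_replicates = 3,
    conditions = c("wt", "efp"),
    seed = seed
  )
}

#' Write a self-contained demo dataset
#'
#' Simulates a genome with planted SPP/PPP stalls and writes everything the
#' pipeline needs into `dir`: genome FASTA, GFF3 annotation, one SAM and one
#' FASTQ per sample (2 conditions x `n_replicates`), the per-read assignment
#' ground truth, the stall ground truth, and a ready-to-run YAML pipeline
#' config. Identical seeds give byte-identical files.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param config Optional [simulation_config()]; defaults to
#'   [demo_config()] at this seed.
#' @return Invisibly, a list with the `sim` object, the sample sheet and the
#'   config path.
#' @export
make_demo <- function(dir, seed = 1, config = NULL) {
  config <- config %||% demo_config(seed = seed)
  sim <- simulate_genome(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(sim, dir)

  sheet <- expand_grid(condition = config$conditions,
                       replicate = seq_len(config$n_replicates)) |>
    mutate(sample_id = sprintf("%s_rep%d", .data$condition, .data$replicate),
           path = file.path(dir, paste0(.data$sample_id, ".sam")))
  truth_list <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    fp <- simulate_footprints(sim, condition = s$condition, replicate = s$replicate,
                              seed = as.integer((as.numeric(config$seed) * 1000 + i) %% 2147483647))
    write_sam(fp$alignments, sim$genome, s$path)
    write_fastq(fp$alignments |> select("read_id", "sequence"),
                file.path(dir, paste0(s$sample_id, ".fastq")))
    truth_list[[s$sample_id]] <- fp$truth
  }
  truth <- bind_rows(truth_list)
  readr::write_tsv(truth, file.path(dir, "read_truth.tsv"))

  cfg <- list(
    genome_fasta = "genome.fa",
    annotation = "genes.gff3",
    out_dir = file.path(dir, "results"),
    contrast = config$conditions,
    samples = purrr::pmap(sheet, function(condition, replicate, sample_id, path) {
      list(sample_id = sample_id, condition = condition,
           replicate = replicate, path = basename(path))
    })
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(sim = sim, sample_sheet = sheet, config_path = cfg_path,
                 truth = truth))
}
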