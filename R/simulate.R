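#' Configure a ribosome-footprint simulation
#'
#' Builds a validated configuration for [simulate_genome()] and
#' [simulate_footprints()]. The simulator writes a multi-gene genome on both
#' strands, plants elevated-occupancy stall sites at chosen amino-acid motifs
#' in one condition (optionally with upstream queuing peaks), and then samples
#' ribosome footprints whose 3' ends are placed so that the 15th nucleotide
#' from the 3' end falls in the sampled codon — the inverse of the assignment
#' rule applied by [assign_three_prime()].
#'
#' @param n_genes Number of genes to place on the simulated contig.
#' @param codons_per_gene Either a single codon count applied to every gene or
#'   a length-2 range `c(min, max)` sampled uniformly per gene. Counts include
#'   the start and stop codons, so a 100-codon gene has a 300-nt CDS.
#' @param codon_usage Named numeric vector of sampling probabilities over the
#'   61 sense codons (must sum to 1 within 1e-9). `NULL` means uniform usage.
#' @param strand_fraction Fraction of genes annotated on the minus strand.
#' @param planted_stalls List of stall descriptors from [stall_spec()].
#' @param queue_offsets Ribosome-queuing peaks: a data frame with columns
#'   `offset` (codons upstream of each planted stall, in translation order)
#'   and `multiplier` (extra occupancy at that codon). `NULL` disables queuing.
#' @param expression Per-gene relative abundance: `"uniform"` (equal weights),
#'   `"lognormal"` (meanlog 0, sdlog 0.75), or a numeric vector of length
#'   `n_genes`.
#' @param depth Expected number of assigned footprints per sample. The
#'   realized total is exactly `depth` (multinomial sampling).
#' @param read_length_range Footprint length range in nt, drawn uniformly.
#'   The minimum must be at least 15 so the 3' offset fits inside the read.
#' @param n_replicates Replicates per condition.
#' @param conditions Character vector of condition labels; stall descriptors
#'   refer to these labels.
#' @param contig_length Optional fixed contig length; an error is raised if
#'   the genes (plus flanks and intergenic gaps) do not fit. `NULL` sizes the
#'   contig automatically.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#'
#' @return A list of class `sim_config`.
#' @seealso [stall_spec()], [simulate_genome()], [simulate_footprints()]
#' @export
#' @examples
#' cfg <- simulation_config(
#'   n_genes = 10, codons_per_gene = 60, depth = 2000,
#'   planted_stalls = list(stall_spec("SPP", condition = "efp",
#'                                    multiplier = 20, n_sites = 4)),
#'   seed = 1
#' )
simulation_config <- function(n_genes = 50,
                              codons_per_gene = c(80, 250),
                              codon_usage = NULL,
                              strand_fraction = 0.5,
                              planted_stalls = list(),
                              queue_offsets = NULL,
                              expression = "lognormal",
                              depth = 30000,
                              read_length_range = c(25, 40),
                              n_replicates = 3,
                              conditions = c("wt", "efp"),
                              contig_length = NULL,
                              seed = 1) {
  stopifnot(n_genes >= 1, length(codons_per_gene) %in% c(1, 2),
            all(codons_per_gene >= 10), depth > 0, n_replicates >= 1,
            length(read_length_range) == 2,
            read_length_range[1] <= read_length_range[2])
  if (read_length_range[1] < 15) {
    abort("read_length_range minimum must be >= 15 nt: the 3' offset (15) must fit inside the read.")
  }
  if (strand_fraction < 0 || strand_fraction > 1) {
    abort("strand_fraction must lie in [0, 1].")
  }
  if (!is.null(codon_usage)) {
    if (is.null(names(codon_usage)) || !setequal(names(codon_usage), SENSE_CODONS)) {
      abort("codon_usage must be named by all 61 sense codons.")
    }
    if (abs(sum(codon_usage) - 1) > 1e-9) {
      abort("codon_usage probabilities must sum to 1 (within 1e-9).")
    }
    if (any(codon_usage < 0)) abort("codon_usage probabilities must be >= 0.")
    codon_usage <- codon_usage[SENSE_CODONS]
  }
  for (st in planted_stalls) {
    if (!inherits(st, "stall_spec")) abort("planted_stalls must be a list of stall_spec() objects.")
    if (!st$condition %in% conditions) {
      abort(sprintf("stall condition '%s' is not among the configured conditions.", st$condition))
    }
  }
  if (!is.null(queue_offsets)) {
    queue_offsets <- as_tibble(queue_offsets)
    stopifnot(all(c("offset", "multiplier") %in% names(queue_offsets)))
    if (any(queue_offsets$offset < 1)) abort("queue offsets must be >= 1 codon upstream.")
    if (any(queue_offsets$multiplier < 1)) abort("queue multipliers must be >= 1.")
  }
  if (is.character(expression)) {
    expression <- match.arg(expression, c("lognormal", "uniform"))
  } else {
    stopifnot(is.numeric(expression), length(expression) == n_genes, all(expression > 0))
  }
  structure(
    list(n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene),
         codon_usage = codon_usage,
         strand_fraction = strand_fraction,
         planted_stalls = planted_stalls,
         queue_offsets = queue_offsets,
         expression = expression,
         depth = as.integer(depth),
         read_length_range = as.integer(read_length_range),
         n_replicates = as.integer(n_replicates),
         conditions = conditions,
         contig_length = contig_length,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Describe a planted stall motif
#'
#' A stall descriptor plants an amino-acid motif (e.g. `"SPP"`, `"PPP"`,
#' `"PPX"`) into `n_sites` distinct genes and multiplies ribosome occupancy at
#' the stalled P-site codon in one condition. The stalled codon is the last
#' proline of the motif (the canonical polyproline geometry: the second of two
#' consecutive prolines sits in the P-site); for motifs without proline it is
#' the middle codon. The wildcard letter `X` is replaced at planting time by a
#' random amino acid other than proline.
#'
#' @param motif 3-letter amino-acid motif; `X` is a wildcard.
#' @param condition Condition label in which the stall is active.
#' @param multiplier Occupancy multiplier at the stalled codon (>= 1).
#' @param n_sites Number of genes to plant the motif into.
#' @return A list of class `stall_spec`.
#' @export
stall_spec <- function(motif, condition, multiplier, n_sites = 10) {
  motif <- toupper(motif)
  if (nchar(motif) != 3 || !all(strsplit(motif, "")[[1]] %in% c(AA_ALPHABET20, "X"))) {
    abort("motif must be a 3-letter amino-acid string (X allowed as wildcard).")
  }
  if (multiplier < 1) abort("stall multiplier must be >= 1.")
  structure(list(motif = motif, condition = condition,
                 multiplier = multiplier, n_sites = as.integer(n_sites)),
            class = "stall_spec")
}

# position of the stalled P-site codon inside a 3-letter motif
stall_psite_index <- function(motif) {
  letters3 <- strsplit(motif, "")[[1]]
  pro <- which(letters3 == "P")
  if (length(pro) > 0) max(pro) else 2L
}

#' Simulate a multi-gene genome with planted stall sites
#'
#' Generates a single contig carrying `n_genes` non-overlapping CDSs on both
#' strands, separated by random intergenic sequence and padded at both ends so
#' that no footprint can run off the contig. Every CDS starts with ATG, ends
#' with a stop codon, and contains no internal stop. Stall motifs are written
#' into the coding sequence and their codon indices recorded as ground truth.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `ribosim` with elements:
#'   \describe{
#'     \item{genome}{A [Biostrings::DNAStringSet] with the single contig.}
#'     \item{genes}{Gene-model tibble: `gene_id`, `contig`, `strand`,
#'       `cds_start`, `cds_end`, `sequence` (sense strand), `n_codons`.}
#'     \item{stalls}{Ground-truth stall tibble: `gene_id`, `codon` (stalled
#'       P-site codon index), `motif` (as planted, wildcards resolved),
#'       `condition`, `multiplier`.}
#'     \item{occupancy}{Tibble of non-baseline occupancy multipliers:
#'       `gene_id`, `codon`, `condition`, `multiplier` (stalls and queuing
#'       peaks; all other codons have multiplier 1).}
#'     \item{expression}{Named per-gene relative abundance weights.}
#'     \item{config}{The input configuration.}
#'   }
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  aa2codon <- aa_codon_table()
  n <- config$n_genes

  n_codons <- if (length(config$codons_per_gene) == 1) {
    rep(config$codons_per_gene, n)
  } else {
    sample(seq(config$codons_per_gene[1], config$codons_per_gene[2]), n, replace = TRUE)
  }

  usage <- config$codon_usage %||% setNames(rep(1 / 61, 61), SENSE_CODONS)
  body_seq <- function(k) {
    # k body codons sampled from sense-codon usage: no internal stops possible
    paste(sample(SENSE_CODONS, k, replace = TRUE, prob = usage), collapse = "")
  }
  sequences <- vapply(n_codons, function(nc) {
    paste0("ATG", body_seq(nc - 2L), sample(STOP_CODONS, 1))
  }, character(1))

  # plant stall motifs: distinct genes per descriptor, codon positions kept
  # clear of the 6-codon edges that pause reporting excludes
  stalls <- list()
  occupied <- replicate(n, integer(0), simplify = FALSE)
  for (st in config$planted_stalls) {
    eligible <- which(n_codons >= 40)
    if (st$n_sites > length(eligible)) {
      abort(sprintf("cannot plant %d '%s' sites: only %d genes are long enough.",
                    st$n_sites, st$motif, length(eligible)))
    }
    genes_idx <- sample(eligible, st$n_sites)
    for (g in genes_idx) {
      # motif occupies codons start..start+2; keep it inside codons 10..n-10
      repeat {
        start <- sample(seq(10L, n_codons[g] - 12L), 1)
        if (!any(abs(occupied[[g]] - start) < 8)) break
      }
      occupied[[g]] <- c(occupied[[g]], start)
      letters3 <- strsplit(st$motif, "")[[1]]
      letters3[letters3 == "X"] <- sample(setdiff(AA_ALPHABET20, "P"),
                                          sum(letters3 == "X"), replace = TRUE)
      motif_codons <- vapply(letters3, function(a) sample(aa2codon[[a]], 1), character(1))
      s <- sequences[g]
      substr(s, (start - 1L) * 3L + 1L, (start + 2L) * 3L) <- paste(motif_codons, collapse = "")
      sequences[g] <- s
      stalls[[length(stalls) + 1L]] <- tibble(
        gene_idx = g,
        codon = start + stall_psite_index(st$motif) - 1L,
        motif = paste(letters3, collapse = ""),
        condition = st$condition,
        multiplier = st$multiplier
      )
    }
  }
  stalls <- if (length(stalls)) bind_rows(stalls) else
    tibble(gene_idx = integer(), codon = integer(), motif = character(),
           condition = character(), multiplier = numeric())

  # layout: flank + gene + gap + gene + ... + flank; flanks and gaps exceed
  # the longest footprint so reads never run off the contig
  flank <- max(config$read_length_range) + 20L
  gaps <- sample(seq(40L, 80L), n, replace = TRUE)
  cds_len <- 3L * n_codons
  starts <- integer(n)
  pos <- flank + 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + cds_len[i] + gaps[i]
  }
  total_len <- pos - gaps[n] + flank
  if (!is.null(config$contig_length)) {
    if (config$contig_length < total_len) {
      abort(sprintf("infeasible packing: %d genes need %d nt but contig_length is %d.",
                    n, total_len, config$contig_length))
    }
    total_len <- as.integer(config$contig_length)
  }

  minus <- rep(FALSE, n)
  n_minus <- round(config$strand_fraction * n)
  if (n_minus > 0) minus[sample(n, n_minus)] <- TRUE
  strand <- if_else(minus, "-", "+")

  gene_id <- sprintf("gene%03d", seq_len(n))
  genomic_seq <- if_else(minus, reverse_complement(sequences), sequences)

  contig_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  contig <- paste(contig_chars, collapse = "")
  for (i in seq_len(n)) {
    substr(contig, starts[i], starts[i] + cds_len[i] - 1L) <- genomic_seq[i]
  }
  genome <- Biostrings::DNAStringSet(setNames(contig, "contig_1"))

  genes <- tibble(
    gene_id = gene_id,
    contig = "contig_1",
    strand = strand,
    cds_start = starts,
    cds_end = starts + cds_len - 1L,
    sequence = sequences,
    n_codons = as.integer(n_codons)
  )

  stalls <- stalls |>
    mutate(gene_id = gene_id[.data$gene_idx], .before = 1) |>
    select(-"gene_idx")

  # occupancy ground truth: stall codons, then queuing peaks upstream
  occupancy <- stalls |> select("gene_id", "codon", "condition", "multiplier")
  if (!is.null(config$queue_offsets) && nrow(stalls) > 0) {
    queue <- expand_grid(stalls |> select("gene_id", stall_codon = "codon", "condition"),
                         config$queue_offsets) |>
      mutate(codon = .data$stall_codon - .data$offset) |>
      filter(.data$codon >= 1) |>
      select("gene_id", "codon", "condition", "multiplier")
    occupancy <- bind_rows(occupancy, queue)
  }
  occupancy <- occupancy |>
    group_by(.data$gene_id, .data$codon, .data$condition) |>
    summarise(multiplier = prod(.data$multiplier), .groups = "drop")

  expr <- if (is.character(config$expression)) {
    if (config$expression == "uniform") rep(1, n) else rlnorm(n, 0, 0.75)
  } else {
    config$expression
  }
  expr <- setNames(expr / sum(expr), gene_id)

  structure(list(genome = genome, genes = genes, stalls = stalls,
                 occupancy = occupancy, expression = expr, config = config),
            class = "ribosim")
}

# per-gene-per-codon sampling weights for one condition
occupancy_weights <- function(sim, condition) {
  genes <- sim$genes
  w <- sim$genes |>
    mutate(expr = sim$expression[.data$gene_id]) |>
    select("gene_id", "n_codons", "expr") |>
    mutate(codon = map(.data$n_codons, seq_len)) |>
    tidyr::unnest("codon") |>
    mutate(multiplier = 1)
  occ <- sim$occupancy |> filter(.data$condition == !!condition)
  if (nrow(occ) > 0) {
    w <- w |>
      left_join(occ |> select("gene_id", "codon", occ_mult = "multiplier"),
                by = c("gene_id", "codon")) |>
      mutate(multiplier = if_else(is.na(.data$occ_mult), 1, .data$occ_mult)) |>
      select(-"occ_mult")
    }
  w |> mutate(weight = .data$expr * .data$multiplier)
}

#' Simulate ribosome footprints for one sample
#'
#' Samples `depth` footprints from a simulated genome. Reads are allocated to
#' genes in proportion to expression and within genes to codons in proportion
#' to the condition's occupancy multipliers (one multinomial draw over all
#' gene-codon cells, so the realized total is exactly `depth`). Within the
#' sampled codon the assigned nucleotide is chosen uniformly among its three
#' positions; the read's 3' end is then placed so that the 15th nucleotide
#' from the 3' end is that assigned position, with the read length drawn
#' uniformly from the configured range. Reads inherit the gene's strand.
#'
#' If a read would extend past the contig (impossible under the default
#' padding, which exceeds the longest footprint), it is clipped to the contig
#' bounds with a warning; clipping is only applied on the 5' side so the 3'
#' offset geometry is preserved.
#'
#' @param sim A `ribosim` object from [simulate_genome()].
#' @param condition Condition label to simulate.
#' @param replicate Replicate number (used in read ids and the truth table).
#' @param depth Number of footprints; defaults to the configured depth.
#' @param seed Integer seed for this sample's draws.
#' @return A list with `alignments` (tibble: `read_id`, `contig`, `strand`,
#'   `start`, `end`, `length`, `mapq`, `unique`, `sequence`) and `truth`
#'   (tibble: `read_id`, `gene_id`, `codon`, `assigned_nt`, `strand`,
#'   `condition`, `replicate`).
#' @export
simulate_footprints <- function(sim, condition, replicate,
                                depth = sim$config$depth, seed = sim$config$seed) {
  stopifnot(inherits(sim, "ribosim"), depth > 0)
  if (!condition %in% sim$config$conditions) {
    abort(sprintf("unknown condition '%s'.", condition))
  }
  set.seed(seed)
  w <- occupancy_weights(sim, condition)
  counts <- as.vector(rmultinom(1, size = depth, prob = w$weight))
  idx <- rep.int(seq_len(nrow(w)), counts)

  genes <- sim$genes
  gi <- match(w$gene_id[idx], genes$gene_id)
  codon <- w$codon[idx]
  strand <- genes$strand[gi]
  plus <- strand == "+"

  # assigned nucleotide: uniform among the codon's 3 positions, in the
  # gene's translation order
  k <- sample.int(3L, length(idx), replace = TRUE)
  assigned <- ifelse(plus,
                     genes$cds_start[gi] + (codon - 1L) * 3L + (k - 1L),
                     genes$cds_end[gi] - (codon - 1L) * 3L - (k - 1L))

  rng <- sim$config$read_length_range
  len <- sample(seq(rng[1], rng[2]), length(idx), replace = TRUE)

  # invert the 3'-end rule: the assigned nt is the 15th from the 3' end
  end <- ifelse(plus, assigned + 14L, assigned + len - 15L)
  start <- end - len + 1L

  contig_len <- Biostrings::width(sim$genome)[1]
  clip_lo <- start < 1L
  clip_hi <- end > contig_len
  if (any(clip_lo | clip_hi)) {
    warn(sprintf("%d reads clipped at contig bounds.", sum(clip_lo | clip_hi)))
    # clip only the 5' side of the footprint so the 3' offset stays intact
    start[clip_lo & plus] <- 1L
    end[clip_hi & !plus] <- contig_len
    len <- end - start + 1L
  }

  ord <- order(start, end)
  read_id <- sprintf("%s_rep%d_read%07d", condition, replicate, seq_along(idx))

  seqs <- as.character(Biostrings::extractAt(
    sim$genome[[1]], IRanges::IRanges(start = start[ord], end = end[ord])
  ))
  minus_ord <- !plus[ord]
  seqs[minus_ord] <- reverse_complement(seqs[minus_ord])

  alignments <- tibble(
    read_id = read_id,
    contig = "contig_1",
    strand = strand[ord],
    start = as.integer(start[ord]),
    end = as.integer(end[ord]),
    length = as.integer(len[ord]),
    mapq = 42L,
    unique = TRUE,
    sequence = seqs
  )
  truth <- tibble(
    read_id = read_id,
    gene_id = w$gene_id[idx][ord],
    codon = as.integer(codon[ord]),
    assigned_nt = as.integer(assigned[ord]),
    strand = strand[ord],
    condition = condition,
    replicate = as.integer(replicate)
  )
  list(alignments = alignments, truth = truth)
}
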