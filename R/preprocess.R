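#' Preprocess raw footprint reads
#'
#' Applies the pre-alignment cleanup used for footprint libraries, in this
#' order: (1) remove the sequencing adapter by truncating each read at the
#' first occurrence of the adapter sequence; (2) drop reads shorter than
#' `min_len` after trimming; (3) if `trim_first`, remove the first base of
#' each surviving read (ligation-bias base). The defaults are the standard
#' constants for this protocol: adapter `CTGTAGGCACCATCAAT` and a 25-bp
#' minimum length.
#'
#' @param reads Tibble with `read_id` and `sequence`, or a character vector
#'   of sequences.
#' @param adapter Adapter nucleotide string (non-empty).
#' @param min_len Minimum post-trim insert length in nt; shorter reads are
#'   dropped (applied before first-base removal).
#' @param trim_first Remove the first base of each kept read?
#' @return Tibble of kept reads (`read_id`, `sequence`, `length`), with an
#'   attribute `"stats"`: one-row tibble `n_input`, `n_adapter_trimmed`,
#'   `n_dropped_short`, `n_kept` (`n_kept + n_dropped_short == n_input`).
#' @export
#' @examples
#' preprocess_reads(c(paste0(strrep("A", 30), "CTGTAGGCACCATCAAT")))
preprocess_reads <- function(reads, adapter = "CTGTAGGCACCATCAAT",
                             min_len = 25L, trim_first = TRUE) {
  if (!nzchar(adapter)) abort("adapter must be non-empty.")
  if (min_len < 1) abort("min_len must be >= 1.")
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%d", seq_along(reads)), sequence = reads)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  seqs <- toupper(reads$sequence)

  hit <- regexpr(adapter, seqs, fixed = TRUE)
  trimmed <- hit > 0L
  insert_len <- if_else(trimmed, as.integer(hit) - 1L, nchar(seqs))
  seqs <- substr(seqs, 1L, insert_len)

  keep <- insert_len >= min_len
  out <- tibble(read_id = reads$read_id[keep], sequence = seqs[keep])
  if (trim_first) out$sequence <- substring(out$sequence, 2L)
  out$length <- nchar(out$sequence)

  attr(out, "stats") <- tibble(
    n_input = nrow(reads),
    n_adapter_trimmed = sum(trimmed),
    n_dropped_short = sum(!keep),
    n_kept = nrow(out)
  )
  out
}

#' Write reads as FASTQ
#'
#' Qualities are constant ("I", Phred 40): the simulator does not model
#' sequencing error, so qualities carry no information.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output path (uncompressed FASTQ).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence,
                           "+",
                           strrep("I", nchar(reads$sequence))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}
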