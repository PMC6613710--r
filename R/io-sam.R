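#' Write footprint alignments as SAM
#'
#' Emits a minimal valid SAM file (header with `@HD` and `@SQ` lines, one
#' record per read). Minus-strand reads carry FLAG 16 and their SEQ field is
#' the reverse complement of the genomic slice, per the SAM convention of
#' storing the sequence as aligned to the forward strand — `sequence` in the
#' input tibble is the read as sequenced (footprint sense), so it is
#' reverse-complemented back for minus-strand records. All alignments are
#' ungapped (`<length>M` CIGAR).
#'
#' @param alignments Tibble with `read_id`, `contig`, `strand`, `start`,
#'   `end`, `length`, `mapq`, and optionally `sequence` (read as sequenced)
#'   and `unique` (FALSE adds the secondary-alignment FLAG 0x100).
#' @param genome A [Biostrings::DNAStringSet] providing contig lengths for
#'   the `@SQ` header.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, genome, path) {
  stopifnot(all(c("read_id", "contig", "strand", "start", "end") %in% names(alignments)))
  len <- alignments$end - alignments$start + 1L
  flag <- if_else(alignments$strand == "-", 16L, 0L)
  if ("unique" %in% names(alignments)) {
    flag <- flag + if_else(alignments$unique, 0L, 256L)
  }
  seq_field <- if ("sequence" %in% names(alignments)) {
    s <- alignments$sequence
    minus <- alignments$strand == "-"
    s[minus] <- reverse_complement(s[minus])
    s
  } else {
    strrep("N", len)
  }
  mapq <- if ("mapq" %in% names(alignments)) alignments$mapq else 42L
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
  )
  records <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                     alignments$read_id, flag, alignments$contig,
                     alignments$start, mapq, len, seq_field, strrep("I", len))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read footprint alignments from SAM/BAM
#'
#' Loads mapped, ungapped footprint alignments. Unmapped records are always
#' excluded; with `require_unique` (the default, matching the unique-alignment
#' requirement of the analysis) multi-mapped records are excluded too.
#' "Uniquely aligned" can be operationalized either as the absence of the
#' secondary-alignment FLAG (0x100) or as MAPQ at or above a floor, since
#' aligners differ in how they report unique alignments. Gapped alignments
#' (CIGAR with anything but a single match run) are rejected with a warning:
#' bacterial footprints are short and aligned ungapped.
#'
#' @param path SAM or BAM file.
#' @param require_unique Drop multi-mapped reads?
#' @param unique_mode `"flag"` (no secondary flag) or `"mapq"` (MAPQ floor).
#' @param min_mapq MAPQ floor used when `unique_mode = "mapq"`.
#' @return Tibble of footprint alignments: `read_id`, `contig`, `strand`,
#'   `start`, `end` (1-based inclusive), `length`, `mapq`, `unique`. An
#'   attribute `"stats"` holds a one-row tibble of input/excluded/kept counts.
#' @export
read_alignments <- function(path, require_unique = TRUE,
                            unique_mode = c("flag", "mapq"), min_mapq = 10L) {
  unique_mode <- match.arg(unique_mode)
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq", "cigar")
    )
  )[[1]]
  n_input <- length(res$qname)
  aln <- tibble(
    read_id = res$qname,
    flag = res$flag,
    contig = as.character(res$rname),
    strand = as.character(res$strand),
    pos = res$pos,
    qwidth = res$qwidth,
    mapq = res$mapq,
    cigar = res$cigar
  )
  mapped <- !bitwAnd(aln$flag, 4L)
  aln <- aln[mapped, ]

  gapped <- !grepl("^[0-9]+M$", aln$cigar)
  if (any(gapped)) {
    warn(sprintf("%d gapped alignment(s) rejected (footprints must be ungapped).",
                 sum(gapped)))
    aln <- aln[!gapped, ]
  }

  is_unique <- if (unique_mode == "flag") {
    bitwAnd(aln$flag, 256L) == 0L
  } else {
    !is.na(aln$mapq) & aln$mapq >= min_mapq
  }
  n_multi <- sum(!is_unique)
  if (require_unique) {
    aln <- aln[is_unique, ]
    is_unique <- rep(TRUE, nrow(aln))
  }

  out <- aln |>
    mutate(length = .data$qwidth,
           start = .data$pos,
           end = .data$pos + .data$qwidth - 1L,
           unique = is_unique) |>
    select("read_id", "contig", "strand", "start", "end", "length", "mapq", "unique")
  attr(out, "stats") <- tibble(
    n_input = n_input,
    n_unmapped = n_input - sum(mapped),
    n_gapped = sum(gapped),
    n_multi_mapped = n_multi,
    n_kept = nrow(out)
  )
  out
}
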