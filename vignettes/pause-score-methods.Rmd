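---
title: "Codon-level pause-score analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level pause-score analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
library(dplyr)
```

## The analysis in brief

Ribosome profiling sequences the ~15–40 nt mRNA fragments protected by
translating ribosomes. In bacteria, the position of the ribosomal P-site
codon within a footprint is most reliably inferred from the footprint's 3'
end: nuclease trimming is raggedy at the 5' end but tight at the 3' end.
`ribopause` implements the codon-resolution pipeline built on that
observation:

1. **3'-end assignment.** Each uniquely aligned, ungapped footprint is
   collapsed to a single nucleotide, the 15th from its 3' terminus. On the
   plus strand that is `end − 14`; on the minus strand the 3' end is the
   alignment's left coordinate, so it is `start + 14`. Reads shorter than
   the offset are discarded and counted.
2. **Codon counting.** The assigned nucleotide is mapped to a codon index in
   translation order: `floor((pos − cds_start)/3) + 1` on the plus strand,
   `floor((cds_end − pos)/3) + 1` on the minus strand. Counts accumulate per
   gene × codon × sample.
3. **Pause scores.** For each codon of each gene,
   `score = count / density`, where `density = total gene count / n_codons`
   is the gene's average read density in that sample. A score of 1 is
   average occupancy; the per-gene mean over all codons is identically 1,
   which the tests assert to 1e-9.
4. **Filtering.** Only genes with density strictly greater than 0.1
   reads/codon in *every* sample of the run are analyzed, and the first and
   last 6 codons of each gene are excluded from reporting (initiation- and
   termination-proximal artifacts). The density denominator still includes
   those codons and the stop codon: the exclusion governs reporting only.
   The interaction between the denominator and the exclusion is a genuine
   design choice — we keep the denominator over all codons because the
   density definition is "reads mapped to the gene divided by the number of
   codons", with no carve-out.
5. **Replicate averaging.** Condition-level scores are means over biological
   replicates with the sample (n−1) standard deviation. A single replicate
   reports sd 0 with an explicit `sd_defined = FALSE` flag.
6. **Differential calling.** A codon is called as a condition-specific pause
   when its fold change between condition means is ≥ 10. Zero is a
   legitimate wild-type score, so the ratio alone can be infinite; we pair
   the fold criterion with an absolute floor (test-condition score ≥ 10) and
   expose an optional pseudocount. With the floor active the default
   pseudocount is 0.
7. **Motif aggregation.** Each analyzed codon's P-site score is added to one
   of the 20³ = 8,000 tripeptides under two framings: P-centered (residues
   at the E, P and A sites, codons P−1, P, P+1) and E-centered (−2, E, P =
   codons P−2, P−1, P). Codons whose window leaves the CDS or touches the
   stop are skipped; the table always enumerates all 8,000 rows, with
   occurrence counts and NA means for unobserved tripeptides.
8. **Weighted logos.** All windows (default −2…+1 codons: −2, E, P, A sites)
   whose P-site score is ≥ 10 are compiled into a position weight matrix in
   which each window contributes weight equal to its P-site score, and each
   position is normalized to sum to 1. "Weighted" logo tools differ in their
   exact weighting; we use the P-site pause score because it makes the
   strongest pauses dominate the picture, and an unweighted mode is
   available for comparison.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `offset` | 15 | nt from 3' end | P-site proxy position; exposed because other datasets calibrate different offsets |
| `density_threshold` | 0.1 | reads/codon | strict (`>`) gene filter, applied in **all** samples |
| `edge_exclude` | 6 | codons | reporting exclusion at each gene end |
| `fold` | 10 | — | differential-pause fold criterion on condition means |
| `min_score` | 10 | pause-score units | absolute floor for a differential call; also the logo inclusion threshold |
| `pseudocount` | 0 | pause-score units | optional ratio stabilizer |
| adapter | `CTGTAGGCACCATCAAT` | nt | 3' adapter removed before alignment |
| `min_len` | 25 | nt | post-trim length filter (reads shorter are dropped) |

Raw-read preprocessing order is: adapter removal at the first adapter
occurrence, then the ≥25 nt filter, then removal of the first base. The
first-base removal happens after the length filter, matching the order of
the original tool chain; the alternative order would shift the filter
boundary by one base.

Coordinates are 0-based half-open nowhere and 1-based inclusive everywhere
in user-facing tables, matching GFF3 and SAM conventions directly; all
arithmetic is done on 1-based inclusive coordinates so there is a single
convention in the package. "Uniquely aligned" is operationalized either as
absence of the secondary-alignment SAM flag (default) or as a MAPQ floor,
because aligners encode uniqueness differently and the original unique-mode
aligner output specifies neither completely.

## What the simulator emulates — and what it does not

`simulate_genome()` + `simulate_footprints()` generate a single contig with
non-overlapping CDSs on both strands (ATG start, stop end, no internal
stops, configurable codon usage), plant amino-acid stall motifs with an
occupancy multiplier in one condition, and sample footprints by a single
multinomial draw over gene × codon cells with weights
`expression × multiplier`. The read's 3' end is placed so that the 15th
nucleotide from the 3' end falls at the sampled position (uniform among the
codon's three nucleotides), which makes the assignment rule exactly
invertible — the round-trip tests exploit this.

Modeled: strand geometry, footprint length variation (uniform 25–40 nt; the
true length distribution of gel-excised libraries is not published beyond
its range, so uniform is a deliberate neutral choice), planted stalls at
motif-matched codons, ribosome queuing as extra multipliers at fixed codon
offsets upstream of each stall (the demo uses offsets 10 and 17 with
multipliers 4 and 2, mimicking the pattern of trailing-ribosome peaks
observed upstream of strong stalls).

Not modeled: sequencing errors and qualities, rRNA contamination, nuclease
sequence bias, multi-mapping reads, overlapping genes, codon-level
correlations beyond the planted multipliers. Passing tests on these
simulations therefore demonstrate the correctness of the bookkeeping —
assignment arithmetic, filters, score algebra, motif framing — not
robustness to alignment artifacts or biological confounders in real
libraries.

The stalled P-site codon of a planted motif is the **last proline** of the
motif (middle codon if the motif has no proline). This encodes the
polyproline-stall geometry: with prolines in the E- and P-sites the
peptidyl-transfer step slows, so for a `PPX` motif the stall sits on the
second proline and for `XPP` on the final one. The wildcard `X` is resolved
at planting time to a random non-proline amino acid so that ground-truth
contexts stay unambiguous.

## Numerical choices and degenerate inputs

* The multinomial draw fixes the per-sample total exactly at `depth`;
  conservation is asserted in tests.
* Within-codon nucleotide choice is uniform over the 3 positions in
  translation order.
* Contig flanks and intergenic gaps exceed the longest footprint, so
  simulated reads cannot leave the contig; if a read nevertheless would
  (e.g. with user-supplied extreme lengths) it is clipped on its 5' side
  only, preserving the 3'-offset geometry, with a warning.
* A gene with density exactly at the threshold fails the (strict) filter. A
  passing gene can never have zero density, and the scoring function
  asserts this rather than dividing by zero.
* Empty read streams, empty assignment streams and all-zero count matrices
  flow through with zero counts rather than errors; an empty logo (no
  window reaches `min_score`) is an explicit error because a silently empty
  matrix has no valid normalization.
* Replicate averaging requires identical codon sets per condition, which
  the all-samples filter guarantees; the function verifies it anyway.
* Sample standard deviation uses the n−1 estimator (the usual estimator for
  three biological replicates; the choice is not forced by the method).

## Problem sizes

The demo dataset (`make_demo()`) uses 50 genes of 80–200 codons, 2
conditions × 3 replicates, and 30,000 assigned reads per sample — a
deliberate scale-down from real footprint libraries (millions of uniquely
aligned reads per sample) that keeps a full pipeline run under a minute
while leaving per-codon background counts (~5 reads/codon median) in a
realistic regime. The recovery benchmark (`benchmark_stall_recovery()`)
uses 50 genes × 200 codons, 5 reads/codon background, 30 planted PPX codons
at multiplier 25, and equal per-gene expression; with these settings the
expected stall score is ≈ 22 against a background of ≈ 1, so the 10-fold
criterion has comfortable margin and observed sensitivity is at or near
100% with no false calls. Gene expression in the demo is lognormal
(sdlog 0.75), which produces the realistic situation of low-coverage genes
hovering near the density filter; the benchmark uses equal expression
because its stated depth is per-codon.

## Known limitations

* Spliced/multi-exon CDSs are unsupported: the codon arithmetic assumes a
  contiguous bacterial CDS.
* Reads are counted in every overlapping same-strand CDS by default
  (`overlap = "all"`); for heavily overlapping operons a
  drop-ambiguous policy is available but both distort scores near overlap
  boundaries.
* Differential calling is a thresholding rule, not a statistical test; no
  p-values or FDR control are provided, by design.
* The logo weighting (P-site score) and window (−2…+1) are package choices;
  published weighted logos do not always document their weighting, so
  cross-tool comparisons should use the exported matrix, not the rendering.

## Worked example

```{r example, eval = FALSE}
demo_dir <- tempfile()
make_demo(demo_dir, seed = 1)
run <- run_pipeline(file.path(demo_dir, "config.yaml"))
glance(run)
autoplot(run$logos$efp)
plot_tripeptide_comparison(run$tripeptides$wt.p_centered,
                           run$tripeptides$efp.p_centered,
                           label_a = "wt", label_b = "efp")
```
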