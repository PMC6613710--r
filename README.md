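# ribopause

Codon-resolution ribosome pause-score analysis for bacterial ribosome
profiling.

When elongation factor P (EF-P) is missing, bacterial ribosomes stall at
polyproline (XPPX) motifs. Detecting such stalls from ribosome profiling
requires collapsing each footprint to the codon in the ribosomal P-site and
quantifying local occupancy against the gene's own coverage. `ribopause`
implements that analysis end to end for anyone comparing codon-level
ribosome occupancy between strains or conditions:

* **3'-end assignment** — each uniquely aligned footprint is assigned to the
  15th nucleotide from its 3' end (plus strand: `end − 14`; minus strand:
  `start + 14`), the standard P-site proxy for bacterial footprints.
* **Pause scores** — for codon *i* of a gene,
  `score(i) = count(i) / density`, with `density = mapped reads / n_codons`.
  A score of 1 is average occupancy; the per-gene mean over all codons is
  identically 1. Genes need density > 0.1 reads/codon in **all** samples;
  the first and last 6 codons are never reported.
* **Differential pauses** — codons whose replicate-mean score is ≥ 10-fold
  higher in one condition (with an absolute floor of 10) are called as
  condition-specific pause sites.
* **Motif views** — mean P-site pause score for all 8,000 tripeptides in
  P-site-centered (E,P,A) and E-site-centered (−2,E,P) framings; weighted
  amino-acid logos of all contexts with P-site score ≥ 10; per-gene pause
  profiles with replicate standard deviations.
* **A footprint simulator** — multi-gene genomes on both strands with
  planted stall motifs, optional ribosome-queuing peaks and full ground
  truth, so the whole pipeline is testable without any downloads.

Everything is tidyverse-native: tibbles in, tibbles out, `ggplot2`
`autoplot()` methods for profiles and logos, `tidy()`/`glance()` on the
pipeline-run object.

## Worked example

```r
library(ribopause)

demo_dir <- tempfile()
make_demo(demo_dir, seed = 1)   # genome, GFF3, 6 SAM samples, ground truth
run <- run_pipeline(file.path(demo_dir, "config.yaml"))
run
```

```
annotation: 50 genes
sample wt_rep1: 30000 reads, 30000 assigned in CDS
...
density filter (> 0.1 in all 6 samples): 50/50 genes pass
differential (fold >= 10, efp vs wt): 15 codons in 14 genes
<pause_run>
  samples: 6  genes: 50 (passing filter: 50)
  reported codons per sample: 6609
  differential calls (efp vs wt, fold >= 10): 15 codons in 14 genes
```

The demo plants 16 SPP/PPP stall motifs (20× occupancy) in the `efp`
condition; all 15 called codons are planted stalls, and the one missed
stall sits just under the 10-fold ratio at this depth. The tripeptide
table shows what the
motif aggregation sees — PPX tripeptides dominate the `efp` condition:

```r
run$tripeptides$efp.p_centered |>
  dplyr::arrange(dplyr::desc(mean_score)) |>
  head(3)
#> # A tibble: 3 × 5
#>   tripeptide n_occurrences mean_score framing    condition
#> 1 PPC                    2       16.3 p_centered efp
#> 2 PPF                    1       15.8 p_centered efp
#> 3 PPK                    3       15.0 p_centered efp
```

and the weighted logo of high-pause contexts puts all P-site weight on
proline:

```r
run$logos$efp["P", ]
#>    -2     E     P     A
#> 0.559 1.000 1.000 0.000   # E and P columns: pure proline
autoplot(run$logos$efp)
```

Per-gene profiles reproduce the planted geometry — a dominant peak at the
stall plus smaller queuing peaks 10 and 17 codons upstream:

```r
top <- run$differential$gene_id[1]
autoplot(gene_profile(run$means, top, condition = "efp"))
```

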