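# pqsprofiler

Putative G-quadruplex sequence (PQS) mapping around gene boundaries, and
the exponential decay model of distance-dependent G-quadruplex induction.

## What this is for

Transcription leaves negative supercoiling behind the RNA polymerase, and
that torsional stress can fold a PQS into a G-quadruplex (G4) *upstream*
of the promoter — even kilobases away. For anyone studying that mechanism
at genome scale, the quantities of interest are distributional: how PQS
density behaves in windows around the transcription start site (TSS) and
transcription end site (TES), what fraction of genes carry at least one
PQS within a given upstream distance, and how fast transcription-induced
G4 formation decays with promoter-to-PQS separation. `pqsprofiler`
implements that analysis as a tested R package: an exact-semantics PQS
scanner, flank extraction and anchoring, windowed metaprofiles and
cumulative curves, a constrained exponential-decay fit, and a synthetic
data generator with exact ground truth so the whole pipeline is testable
without genome downloads.

## The core definitions

* **PQS grammar**: `G{3,}(.{1,7}?G{3,}){3,}` — at least four tracts of ≥3
  guanines separated by 1–7 nt loops of any base (loops may contain G).
  Matching is leftmost and non-overlapping with greedy tracts, lazy loops
  and a greedy repeat count; `scan_both_strands()` also scans the reverse
  complement and maps coordinates back. An independent `oracle_scan()`
  re-implements the same semantics from first principles for
  cross-checking.
* **Metaprofiles**: motif frequency per 100 sequences in 100-nt windows
  across the 5-kb flank on either side of the gene (20-nt windows,
  strand-split, for the first 1 kb downstream of the TES).
* **Cumulative curves**: `cum_positive_pct(d)` = percentage of genes with
  ≥1 PQS wholly inside −1…−d of the TSS, for d = 1…5000, counting both
  strands; its endpoint is `percent_positive()`.
* **Decay model**: `Y = max·exp(−k·X) + plateau`, fitted by constrained
  Levenberg–Marquardt least squares; half-decay distance
  `D1/2 = ln 2 / k`, also derived numerically from its verbal definition
  as a consistency check.

## Worked example

```r
library(pqsprofiler)

## the canonical G3(TG3)3 motif on each strand of one sequence
scan_both_strands("TTGGGTGGGTGGGTGGGTTCCCACCCACCCACCCTT")
#>   seq_id start end strand n_tracts     matched_seq
#> 1   <NA>     2  17      +        4 GGGTGGGTGGGTGGG
#> 2   <NA>    19  34      -        4 GGGTGGGTGGGTGGG

## a synthetic cohort: 5-kb flanks, 5x TSS-proximal enrichment step
cfg <- synthetic_config(n_genes = 5000, seed = 20260927)
sim <- generate_flank_set(cfg)
up  <- sim$flanks[sim$flanks$side == "upstream", ]
anchored <- scan_flanks(up)
percent_positive(anchored, up$gene_id)       # % genes with >=1 PQS in 5 kb
prof <- frequency_profile(anchored, n_sequences = nrow(up))

## the decay model at the reference parameters
d <- generate_decay_dataset(max = 59, d_half = 489, plateau = 40,
                            distances = seq(0, 2500, 250), noise_sd = 0)[[1]]
fit_decay(d$x, d$y)
#> Exponential decay fit: max = 59%, k = 0.001417 /bp, plateau = 40%
#> half-decay distance D1/2 = 489 bp (SSE 2.019e-28)
```

Interpretation: both strands of the example sequence carry the same
4-tract motif (the minus-strand match is reported in forward coordinates,
reading 5'→3' on its own strand). On the synthetic cohort the default
configuration lands ~60% of genes PQS-positive within 5 kb upstream with
a ~5-fold window-frequency peak over background, and the noiseless decay
fit returns its generating parameters exactly.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write tables under `results/` (large sequence intermediates go under
`scratch/`):

1. `01_simulate_cohort.R` — 5,000 genes, both flanks, ground truth.
2. `02_scan_and_profile.R` — TSS/TES 100-nt metaprofiles and the
   strand-split 20-nt TES inserts; reports the peak/background fold.
3. `03_cumulative_and_species.R` — cumulative curves, percent-positive,
   the G3/1-nt-loop subclass count, and a three-"species" summary across
   10-fold density differences.
4. `04_decay_fit.R` — noiseless and noisy decay fits with D1/2.

Run them in order: `Rscript analysis/01_simulate_cohort.R`, etc.

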