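---
title: "Mapping putative G-quadruplex sequences around gene boundaries"
author: "pqsprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping putative G-quadruplex sequences around gene boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqsprofiler)
```

## The problem

Guanine-rich DNA can fold into four-stranded G-quadruplex (G4) structures.
Transcription generates negative supercoiling behind a moving RNA
polymerase, and that torsional stress can induce G4 folding in a putative
G-quadruplex sequence (PQS) located *upstream* of a promoter — even
thousands of base pairs away — while the downstream side is torsionally
disfavoured. Two genome-scale signatures follow from this mechanism and are
what this package computes:

1. **Polarised PQS distribution.** PQS density, profiled in windows around
   gene boundaries, should peak just upstream of the transcription start
   site (TSS) and stay near background downstream of the transcription end
   site (TES), with a non-template-strand bias in the first ~1 kb past the
   TES.
2. **Distance-dependent induction.** The fraction of DNA molecules forming
   a G4 (%qDNA) decays with the promoter-to-PQS separation as a
   single-phase exponential, `Y = max * exp(-k * X) + plateau`, with a
   half-decay distance `D1/2 = ln(2) / k`.

## The PQS grammar and its disambiguation contract

A PQS is at least four tracts of at least three consecutive guanines,
separated by loops of 1–7 nucleotides of any base — **including G**. In
backtracking-regex form this is `G{3,}(.{1,7}?G{3,}){3,}`. Because loops
may contain G, the decomposition of a G-rich region into tracts and loops
is ambiguous, and counts depend on how that ambiguity is resolved. The
package pins the semantics down exactly:

* **greedy tracts** — a tract absorbs the maximal G-run, giving back
  characters only when nothing else completes a match;
* **lazy loops** — a loop prefers the shortest length, growing only when
  needed;
* **greedy repeat count** — a match extends over as many loop+tract units
  as possible;
* **leftmost, non-overlapping** — matches are reported leftmost-first and
  scanning resumes at each match end, so a G-rich region yields one
  maximal leftmost match.

A worked consequence of greediness: in `GGGGGGGAGGGAGGGAGGG` the first
tract commits all seven guanines and the match has four tracts, although a
6-tract decomposition of the same span exists. In `GGGGAGGGAGGGAGGGAGGG`
the greedy repeat absorbs a fifth tract rather than stopping at four.

```{r}
scan_forward("GGGGGGGAGGGAGGGAGGG")[, c("start", "end", "n_tracts")]
```

The production scanner delegates span-finding to R's PCRE engine
(`gregexpr(perl = TRUE)`), which implements exactly this backtracking
order, and derives each match's tract count from the package's own parse
of the matched substring. `oracle_scan()` is an independent
re-implementation — an exhaustive preference-ordered search over
decompositions with no shared parsing code — used throughout the tests; a
third, brute-force enumeration with an explicit comparator checks both on
short strings. The preference order is positional (longer first tract
before anything about later units), not "most tracts first": the two
differ, and only the positional order reproduces the backtracking engine.

Further fixed decisions: input is uppercased before scanning, so
soft-masked genome sequence is scanned (repeat masking is deliberately
ignored); IUPAC ambiguity codes are legal loop characters but never count
toward a tract; coordinates are 0-based half-open internally, converted
only at format boundaries (BED stays 0-based, GFF3 is converted on
reading).

## Anchored coordinates and the representative position

Flanks are always expressed 5'→3' on the gene's **sense** (non-template)
strand; a gene is the annotated transcribed region, so one TSS and one TES
per gene. Upstream flank offsets map to coordinates −L…−1 (−1 abuts the
TSS); downstream offsets map to +1…+L. A multi-base motif is represented
by the coordinate of its match start — for upstream flanks its most
anchor-distal (most negative) base. A motif therefore counts as "within
distance d" only when **wholly contained** in −1…−d, which makes the
cumulative curves stable under flank truncation. Matches on the
sense-oriented flank's plus strand are non-template-strand motifs; minus
strand matches are template-strand motifs.

One visible consequence: the window abutting the anchor is slightly
thinned, because a motif whose distal base lies closer to the anchor than
its own span cannot be wholly contained. Estimates of the TSS-proximal
peak therefore exclude the TSS-adjacent window.

## The summary statistics

* `frequency_profile()` bins each motif once by its representative
  coordinate and normalises to occurrences per 100 sequences per window
  (100 nt windows for the main profiles; 20 nt for the TES-downstream
  strand-split inserts, restricted to +1…+1000). Window counts are exact
  integers, so `frequency * n_sequences / 100` always reconstructs the
  count, and the per-strand profiles sum to the both-strand profile.
* `cumulative_distribution()` sweeps d = 1…5000 and accumulates the motif
  count and the percentage of genes with at least one wholly-contained
  motif — equivalent to walking a coordinate-sorted motif list and
  inserting gene IDs into a hash on first occurrence, implemented here as
  a vectorised per-gene minimum. `percent_positive()` is its endpoint, and
  the identity is asserted in the tests.
* `subclass_count()` identifies the compact G3-tract/1-nt-loop subclass by
  an anchored full-extent parse of each motif's matched sequence: every
  tract exactly 3 G, every loop exactly 1 nt, at least four tracts. Under
  this strict reading `GGGGTGGGTGGGTGGG` (one 4-G tract) and
  `GGGTTGGGTGGGTGGG` (one 2-nt loop) are excluded. The looser readings
  ("contains a G3/1-nt core") were rejected because they would count
  motifs whose observed extent contradicts the subclass geometry.
* `species_summary()` applies `percent_positive()` per cohort, preserving
  the caller's ordering (e.g. a species-tree order).

Genes whose flanks are truncated at a chromosome edge stay in the
denominator with their shortened flank; truncation only thins the distal
windows, which is flagged rather than silently reweighted.

## The decay model

`fit_decay()` estimates (max, k, plateau) by constrained
Levenberg–Marquardt least squares (via \pkg{minpack.lm}) with max ≥ 0 and
k ≥ 0, unweighted. Initialisation is deterministic: plateau₀ = min(y),
max₀ = max(y) − min(y), k₀ = ln 2 / (half the x-range); convergence at a
relative SSE change below 1e-10, capped at 1024 LM iterations (tens
suffice in practice). The constant model (max = 0) is nested, so the fit
is never reported worse than the best constant; a fit whose k collapses to
the boundary is flagged non-decaying with D1/2 undefined rather than
reporting an infinite half-distance. `d_half_definition_check()` solves
the verbal definition of D1/2 (the distance where the curve reaches the
min/max midpoint) by bisection on [0, 50/k] and is asserted to equal
ln 2 / k — the closed form is a theorem about the model, and the package
checks it rather than assuming it.

Raw distance/%qDNA measurements are not distributed with the package, so
the reference fit (max = 59%, plateau = 40%, D1/2 = 489 bp) is used as a
*generator* for recovery exercises — noiseless
curves must be recovered to 1e-6 relative, and with 3-percentage-point
Gaussian noise on 11 distances (0–2500 bp, evenly spaced, our choice) the
median recovered D1/2 over 100 replicates must stay within ±15% — never
as a reproduction claim about the original gel data.

## What the synthetic generator emulates — and what it does not

`generate_flank_set()` produces per-gene upstream and downstream flanks
with planted PQS instances and an exact truth table. Defaults encode the
study conditions the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| `flank_len` | 5000 bp | the profiled flank extent |
| `lambda0` | 1e-4 plants/nt/gene | ≈0.9 expected upstream plants/gene → ≈60% positive genes in 5 kb, the warm-blooded-vertebrate regime |
| `enrich_fold` | 5 | the peak-over-background ratio characteristic of the TSS-proximal PQS enrichment |
| `enrich_width` | 1000 bp | width of the TSS-proximal enriched zone (step shape by default) |
| downstream density | flat `lambda0` | "little enrichment" downstream of genes |
| `strand_probability` | 0.5 | motifs counted on both strands |
| composition | A/T 0.295, C/G 0.205 | a ~41% GC genome |

The background is made **G/C-run-free** (every run of ≥3 G or C is broken
during generation), plants are separated by an 8-nt clearance — larger
than the maximal loop, so two plants can never merge into one match — and
a single non-G/C guard base is written on each side of a plant so a
background guanine cannot extend a planted tract and shift its
coordinates. Sampled loop characters come from {A, C, T} with runs of ≥3 C
rejected, so neither strand of an instance contains a spurious tract.
Under these conditions scanning recovers exactly the truth table: 100%
recall at exact coordinates and strand classes, zero false positives.
That exactness is the point — it separates matcher correctness from
biology-like noise. Consequently, passing these tests says nothing about
repeat content, CpG islands, real base composition, overlapping genes or
isoform structure; `g_run_free = FALSE` provides a noisier background for
robustness exercises but carries no exactness guarantee.

A small bias is accepted by design: an upstream plant's distal coordinate
cannot be closer to the TSS than the motif span, so the first ~20 bp
carry no plants (see the representative-position convention above).

## Problem sizes

The bundled analyses and checks use synthetic cohorts of 400–5,000 genes
for identities and end-to-end recovery, 20,000 genes for
enrichment-shape estimation (peak/background within ±20% of the
configured fold), 5,000 random sequences (≤300 nt, 40% G) for
scanner-oracle equivalence, and 100 noisy replicates for decay recovery —
sizes at which the Monte-Carlo error of each estimate is comfortably
inside the asserted bands.

## Known limitations

* Gene-level anchors only: no transcript isoforms, no alternative-TSS
  collapsing; overlapping genes are processed independently, and flanks
  may run into neighbouring gene bodies.
* Presence/absence matching only — no thermodynamic or G4Hunter-style
  scoring, and no overlapping-match enumeration in the production
  scanner.
* No enrichment significance testing; the profiles and curves are
  descriptive statistics.
* The exhaustive oracle is a test instrument for sequences up to a few
  hundred nt, not a genome-scale scanner.
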