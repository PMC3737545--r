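Package: pqsprofiler
Title: Putative G-Quadruplex Sequence Mapping Around Gene Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans nucleotide sequences for putative G-quadruplex sequences
    (PQS) with the exact backtracking semantics of the classical pattern
    G{3,}(.{1,7}?G{3,}){3,}, on one or both strands, and summarises their
    distribution around gene boundaries: windowed frequency metaprofiles
    anchored at transcription start and end sites, strand-split profiles
    downstream of the TES, cumulative curves of PQS-positive genes as a
    function of upstream distance, per-species percent-positive summaries,
    and a count of the compact G3/1-nt-loop motif subclass. Also fits the
    single-phase exponential decay model of distance-dependent G-quadruplex
    induction, Y = max*exp(-k*X) + plateau, and derives the half-decay
    distance. A synthetic flank generator with exact ground truth makes the
    whole pipeline testable without genome downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
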