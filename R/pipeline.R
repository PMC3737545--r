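# Pipeline steps wiring the modules together. Each step is a plain R
# function (the analysis/ scripts are thin drivers over these): inputs are
# files or data frames, outputs are provenance-stamped TSV/BED tables, and
# every source of randomness is an explicit seed, so reruns are
# byte-identical.

#' Scan a FASTA file for PQS on both strands
#'
#' @param fasta Path to a (possibly gzipped) FASTA file.
#' @param pattern A [pqs_pattern()].
#' @param bed,tsv Optional output paths for BED6 / TSV exports.
#' @return Match data frame (invisibly written to `bed`/`tsv` when given),
#'   ordered by `seq_id`, `start`, `strand`.
#' @export
run_scan <- function(fasta, pattern = pqs_pattern(), bed = NULL, tsv = NULL) {
  recs <- Biostrings::readDNAStringSet(fasta)
  if (length(recs) == 0L) stop("no sequences in ", fasta)
  ids <- sub("\\s.*$", "", names(recs))
  per <- lapply(seq_along(recs), function(i) {
    scan_both_strands(as.character(recs[[i]]), pattern, seq_id = ids[i])
  })
  out <- do.call(rbind, per)
  out <- out[order(out$seq_id, out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(bed)) write_matches_bed(out, bed)
  if (!is.null(tsv)) write_matches_tsv(out, tsv, pattern)
  out
}

#' Metaprofile a flank FASTA
#'
#' Reads flank-dialect FASTA, scans both strands, anchors the matches and
#' returns the windowed frequency profile.
#'
#' @param flank_fasta Path to flank-dialect FASTA (see
#'   [read_flank_fasta()]), or a flank data frame.
#' @param window Window width, nt.
#' @param strand_scope `"both"`, `"non-template"` or `"template"`.
#' @param pattern A [pqs_pattern()].
#' @param tsv Optional output TSV path.
#' @return A [frequency_profile()] data frame.
#' @export
run_profile <- function(flank_fasta, window = 100L, strand_scope = "both",
                        pattern = pqs_pattern(), tsv = NULL) {
  flanks <- if (is.character(flank_fasta)) read_flank_fasta(flank_fasta)
            else flank_fasta
  if (nrow(flanks) == 0L) stop("zero flank sequences")
  if (length(unique(flanks$side)) > 1L) {
    stop("profile one side at a time (got both upstream and downstream)")
  }
  anchored <- scan_flanks(flanks, pattern)
  prof <- frequency_profile(anchored, n_sequences = nrow(flanks),
                            window = window, strand_scope = strand_scope,
                            flank_len = max(flanks$length),
                            side = flanks$side[1L])
  if (!is.null(tsv)) write_profile_tsv(prof, tsv)
  prof
}

#' Cumulative PQS-positive-gene curve from upstream flanks
#'
#' @inheritParams run_profile
#' @param max_distance Largest upstream distance swept, bp.
#' @return A [cumulative_distribution()] data frame.
#' @export
run_cumulative <- function(flank_fasta, pattern = pqs_pattern(),
                           max_distance = 5000L, tsv = NULL) {
  flanks <- if (is.character(flank_fasta)) read_flank_fasta(flank_fasta)
            else flank_fasta
  flanks <- flanks[flanks$side == "upstream", , drop = FALSE]
  if (nrow(flanks) == 0L) stop("zero upstream flank sequences")
  anchored <- scan_flanks(flanks, pattern)
  curve <- cumulative_distribution(anchored, flanks$gene_id, max_distance)
  if (!is.null(tsv)) write_curve_tsv(curve, tsv)
  curve
}

#' Per-species percent-positive summary from flank FASTA files
#'
#' @param flank_fastas Named character vector of flank FASTA paths (or a
#'   named list of flank data frames), one entry per species; order is
#'   preserved.
#' @inheritParams run_cumulative
#' @return A [species_summary()] data frame.
#' @export
run_species_summary <- function(flank_fastas, pattern = pqs_pattern(),
                                max_distance = 5000L, tsv = NULL) {
  sets <- lapply(flank_fastas, function(f) {
    fl <- if (is.character(f)) read_flank_fasta(f) else f
    fl[fl$side == "upstream", , drop = FALSE]
  })
  out <- species_summary(sets, pattern, max_distance)
  if (!is.null(tsv)) {
    .write_tsv(out, tsv, params = list(pattern = pqs_regex(pattern),
                                       max_distance = max_distance))
  }
  out
}

#' Generate and write a synthetic cohort
#'
#' @param config A [synthetic_config()].
#' @param fasta Output flank FASTA path.
#' @param truth_tsv Output ground-truth TSV path.
#' @param sides Flank sides to generate.
#' @return The `generate_flank_set()` result, invisibly.
#' @export
run_simulate <- function(config, fasta, truth_tsv,
                         sides = c("upstream", "downstream")) {
  sim <- generate_flank_set(config, sides)
  write_flank_fasta(sim$flanks, fasta)
  .write_tsv(sim$truth, truth_tsv,
             params = list(seed = config$seed, n_genes = config$n_genes,
                           flank_len = config$flank_len,
                           lambda0 = config$lambda0,
                           enrich_fold = config$enrich_fold,
                           enrich_width = config$enrich_width,
                           enrich_shape = config$enrich_shape))
  invisible(sim)
}

#' Fit the decay model to a %qDNA TSV
#'
#' @param decay_tsv Input TSV with columns `distance_bp`, `pct_qdna`.
#' @param tsv Optional output path for the single-row fit table.
#' @return A [fit_decay()] object.
#' @export
run_fit_decay <- function(decay_tsv, tsv = NULL) {
  d <- read_decay_tsv(decay_tsv)
  fit <- fit_decay(d$x, d$y)
  if (!is.null(tsv)) write_decay_fit_tsv(fit, tsv)
  fit
}
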