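# Tabular input/output: match exports (BED6/TSV), gene-annotation readers,
# profile/curve/decay tables. All writers stamp a provenance header
# (comment lines) naming the package version and the parameters used, so
# outputs are reproducible from their own metadata.

.provenance_header <- function(params = list()) {
  c(sprintf("# pqsprofiler %s",
            as.character(utils::packageVersion("pqsprofiler"))),
    vapply(names(params), function(k) {
      sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = " "))
    }, character(1), USE.NAMES = FALSE))
}

.write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write PQS matches as BED6
#'
#' 0-based half-open intervals; `name` is the matched motif sequence,
#' `score` the G-tract count, and the strand column records the matched
#' strand.
#'
#' @param matches Match data frame from [scan_forward()] /
#'   [scan_both_strands()] (with `seq_id` set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, path) {
  bed <- data.frame(chrom = matches$seq_id, start = matches$start,
                    end = matches$end, name = matches$matched_seq,
                    score = matches$n_tracts, strand = matches$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write PQS matches as TSV
#'
#' Columns `seq_id`, `start`, `end`, `strand`, `n_tracts`, `matched_seq`,
#' preceded by a provenance header.
#'
#' @inheritParams write_matches_bed
#' @param pattern The [pqs_pattern()] used, recorded in the header.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path, pattern = pqs_pattern()) {
  cols <- c("seq_id", "start", "end", "strand", "n_tracts", "matched_seq")
  .write_tsv(matches[, cols], path, params = list(pattern = pqs_regex(pattern)))
}

#' Read gene annotations from BED
#'
#' BED6 (or more columns; the first six are used): chrom, start, end, name,
#' score, strand. BED is already 0-based half-open, the package's internal
#' convention.
#'
#' @param path BED file.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` suitable for [extract_flanks()].
#' @export
read_gene_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(b) < 6L) stop("need BED6 (chrom, start, end, name, score, strand)")
  data.frame(gene_id = as.character(b[[4L]]), chrom = as.character(b[[1L]]),
             start = as.integer(b[[2L]]), end = as.integer(b[[3L]]),
             strand = as.character(b[[6L]]), stringsAsFactors = FALSE)
}

#' Read gene annotations from GFF3
#'
#' Keeps features of type `gene` and converts the 1-based inclusive GFF
#' coordinates to the internal 0-based half-open convention. The gene
#' identifier is taken from the `ID` attribute (a `gene:` prefix, as used
#' by Ensembl, is stripped).
#'
#' @param path GFF3 file.
#' @return Data frame as in [read_gene_bed()].
#' @export
read_gene_gff3 <- function(path) {
  g <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(g) < 9L) stop("not a GFF3 file: expected 9 columns")
  g <- g[g[[3L]] == "gene", , drop = FALSE]
  if (nrow(g) == 0L) stop("no 'gene' features in ", path)
  id <- sub("^gene:", "", sub("^.*ID=([^;]+).*$", "\\1", g[[9L]]))
  data.frame(gene_id = id, chrom = as.character(g[[1L]]),
             start = as.integer(g[[4L]]) - 1L, end = as.integer(g[[5L]]),
             strand = as.character(g[[7L]]), stringsAsFactors = FALSE)
}

#' Write a frequency profile as TSV
#'
#' @param profile A [frequency_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  .write_tsv(profile, path, params = list(
    window = attr(profile, "window"),
    n_sequences = attr(profile, "n_sequences"),
    strand_scope = attr(profile, "strand_scope")))
}

#' Write a cumulative curve as TSV
#'
#' @param curve A [cumulative_distribution()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  .write_tsv(curve, path, params = list(n_genes = attr(curve, "n_genes")))
}

#' Read a %qDNA decay dataset from TSV
#'
#' Expects columns `distance_bp` and `pct_qdna` (comment lines ignored).
#'
#' @param path TSV file.
#' @return Data frame with columns `x` (bp) and `y` (percent).
#' @export
read_decay_tsv <- function(path) {
  d <- .read_tsv(path)
  if (!all(c("distance_bp", "pct_qdna") %in% names(d))) {
    stop("expected columns distance_bp, pct_qdna")
  }
  data.frame(x = as.numeric(d$distance_bp), y = as.numeric(d$pct_qdna))
}

#' Write a decay fit as a single-row TSV
#'
#' @param fit A [fit_decay()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_fit_tsv <- function(fit, path) {
  .write_tsv(data.frame(max = fit$max, k = fit$k, plateau = fit$plateau,
                        d_half = fit$d_half, sse = fit$residual_sse),
             path, params = list(model = "Y = max*exp(-k*X) + plateau"))
}
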