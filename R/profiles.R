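# Distributional statistics over anchored matches: windowed frequency
# metaprofiles, strand-split TES-downstream profiles, cumulative curves of
# motifs and PQS-positive genes, the percent-positive summary, the compact
# G3/1-nt-loop subclass count and per-species summaries.

.check_scope <- function(strand_scope) {
  match.arg(strand_scope, c("both", "non-template", "template"))
}

.scope_filter <- function(anchored, strand_scope) {
  if (strand_scope == "both") anchored
  else anchored[anchored$strand_class == strand_scope, , drop = FALSE]
}

.check_same_anchor <- function(anchored) {
  if (nrow(anchored) == 0L) return(invisible(NULL))
  if (length(unique(anchored$anchor)) > 1L ||
      length(unique(anchored$side)) > 1L) {
    stop("anchored matches mix anchors/sides; profile them separately")
  }
  invisible(NULL)
}

#' Windowed PQS frequency profile
#'
#' Bins each motif once, by its representative coordinate (the most
#' anchor-distal base for upstream flanks, the match start for downstream
#' flanks), into consecutive windows tiling the flank, and normalises counts
#' to occurrences per 100 sequences.
#'
#' @param anchored Anchored-match data frame from [scan_flanks()] /
#'   [anchor_matches()]; all rows must share anchor and side.
#' @param n_sequences Number of flank sequences scanned (the normalisation
#'   denominator; genes without matches count here too).
#' @param window Window width, nt (100 for the main profiles, 20 for the
#'   TES-downstream inserts).
#' @param strand_scope `"both"` (default), `"non-template"` or `"template"`.
#' @param flank_len Flank length being tiled, bp.
#' @param side `"upstream"` or `"downstream"`; governs the sign of the
#'   window labels. Inferred from `anchored` when `NULL` (upstream if
#'   empty).
#' @return Data frame with columns `win_start`, `win_end` (anchor
#'   coordinates, inclusive), `count` and `frequency` (occurrences per 100
#'   sequences). Attributes record `window`, `n_sequences`, `strand_scope`
#'   and whether the last window is partial.
#' @export
frequency_profile <- function(anchored, n_sequences, window = 100L,
                              strand_scope = "both", flank_len = 5000L,
                              side = NULL) {
  strand_scope <- .check_scope(strand_scope)
  n_sequences <- as.integer(n_sequences)
  if (is.na(n_sequences) || n_sequences < 1L) {
    stop("n_sequences must be a positive integer")
  }
  .check_same_anchor(anchored)
  window <- as.integer(window)
  flank_len <- as.integer(flank_len)
  stopifnot(window >= 1L, flank_len >= 1L)
  a <- .scope_filter(anchored, strand_scope)
  n_win <- as.integer(ceiling(flank_len / window))
  dist <- abs(a$coord)                      # 1..flank_len
  if (any(dist < 1L | dist > flank_len)) {
    stop("anchored coordinate outside the flank length")
  }
  counts <- tabulate(ceiling(dist / window), nbins = n_win)
  lo <- (seq_len(n_win) - 1L) * window + 1L
  hi <- pmin(lo + window - 1L, flank_len)
  if (is.null(side)) {
    side <- if (nrow(anchored) > 0L) anchored$side[1L] else "upstream"
  }
  side_up <- side == "upstream"
  out <- data.frame(
    win_start = if (side_up) -hi else lo,
    win_end = if (side_up) -lo else hi,
    count = counts,
    frequency = counts / n_sequences * 100
  )
  if (side_up) out <- out[order(out$win_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "n_sequences") <- n_sequences
  attr(out, "strand_scope") <- strand_scope
  attr(out, "partial_last_window") <- flank_len %% window != 0L
  out
}

#' Strand-split 20-nt profiles downstream of the TES
#'
#' The 1000 nt immediately downstream of the TES, profiled at 20 nt
#' resolution separately for non-template- and template-strand motifs.
#' Motifs whose representative coordinate lies beyond +1000 are discarded.
#'
#' @inheritParams frequency_profile
#' @return A list with elements `non_template` and `template`, each a
#'   [frequency_profile()] data frame.
#' @export
tes_strand_insert_profile <- function(anchored, n_sequences) {
  if (nrow(anchored) > 0L) {
    if (any(anchored$side != "downstream")) {
      stop("TES insert profiles require TES-downstream matches")
    }
    anchored <- anchored[anchored$coord <= 1000L, , drop = FALSE]
  }
  list(
    non_template = frequency_profile(anchored, n_sequences, window = 20L,
                                     strand_scope = "non-template",
                                     flank_len = 1000L, side = "downstream"),
    template = frequency_profile(anchored, n_sequences, window = 20L,
                                 strand_scope = "template",
                                 flank_len = 1000L, side = "downstream")
  )
}

#' Cumulative PQS and PQS-positive-gene curves upstream of the TSS
#'
#' Sweeping the distance d = 1..max_distance outward from the TSS, a motif
#' contributes at distance d when it lies wholly within -1..-d, i.e. when
#' the absolute value of its (most distal) coordinate is at most d.
#' `cum_motifs` counts contributing motifs; `cum_positive_pct` is the
#' percentage of the gene universe with at least one contributing motif --
#' the first-occurrence-per-gene accumulation the original analysis did by
#' inserting gene IDs into a hash while walking the coordinate-sorted list.
#'
#' @param anchored Upstream (TSS) anchored matches, both strands.
#' @param gene_universe Character vector of all gene IDs scanned (the
#'   denominator; must cover every gene in `anchored`).
#' @param max_distance Largest distance swept, bp (default 5000).
#' @return Data frame with columns `distance` (1..max_distance),
#'   `cum_motifs`, `cum_positive_pct`; attribute `n_genes`.
#' @export
cumulative_distribution <- function(anchored, gene_universe,
                                    max_distance = 5000L) {
  max_distance <- as.integer(max_distance)
  stopifnot(max_distance >= 1L)
  gene_universe <- unique(as.character(gene_universe))
  if (length(gene_universe) == 0L) stop("gene_universe is empty")
  if (nrow(anchored) > 0L) {
    if (any(anchored$side != "upstream")) {
      stop("cumulative distribution is defined for TSS-upstream matches")
    }
    missing <- setdiff(anchored$gene_id, gene_universe)
    if (length(missing) > 0L) {
      stop("genes in matches but not in universe: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  dist <- abs(anchored$coord)
  keep <- dist <= max_distance
  cum_motifs <- cumsum(tabulate(dist[keep], nbins = max_distance))
  first_dist <- if (any(keep)) {
    vapply(split(dist[keep], anchored$gene_id[keep]), min, numeric(1))
  } else numeric(0)
  cum_pos <- cumsum(tabulate(first_dist, nbins = max_distance))
  out <- data.frame(distance = seq_len(max_distance),
                    cum_motifs = cum_motifs,
                    cum_positive_pct = 100 * cum_pos / length(gene_universe))
  attr(out, "n_genes") <- length(gene_universe)
  out
}

#' Percentage of genes with at least one upstream PQS
#'
#' The fraction of the gene universe carrying one or more motifs wholly
#' within -1..-max_distance of the TSS, on either strand. Equals the
#' endpoint of [cumulative_distribution()] on the same input.
#'
#' @inheritParams cumulative_distribution
#' @return A single percentage in `[0, 100]`.
#' @export
percent_positive <- function(anchored, gene_universe, max_distance = 5000L) {
  gene_universe <- unique(as.character(gene_universe))
  if (length(gene_universe) == 0L) stop("gene_universe is empty")
  if (nrow(anchored) > 0L && any(anchored$side != "upstream")) {
    stop("percent_positive is defined for TSS-upstream matches")
  }
  missing <- setdiff(anchored$gene_id, gene_universe)
  if (length(missing) > 0L) {
    stop("genes in matches but not in universe: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  pos <- unique(anchored$gene_id[abs(anchored$coord) <= max_distance])
  100 * length(pos) / length(gene_universe)
}

#' Count motifs of the compact exact-tract / exact-loop subclass
#'
#' Rescans the matched sequence of each motif with an anchored exact
#' grammar: a motif is counted when its full extent parses into tracts of
#' exactly `exact_tract_len` guanines separated by loops of exactly
#' `exact_loop_len` nucleotides (at least `min_tracts` tracts). With the
#' defaults this is the G3-tract / 1-nt-loop subclass.
#'
#' @param matches A data frame with a `matched_seq` column (raw scanner
#'   matches, or anchored matches from `scan_flanks(..., keep_matched_seq =
#'   TRUE)`).
#' @param exact_tract_len,exact_loop_len Subclass geometry (defaults 3, 1).
#' @param min_tracts Minimum tract count (default 4).
#' @return Integer count.
#' @examples
#' m <- scan_forward("GGGTGGGTGGGTGGG")
#' subclass_count(m)  # 1
#' @export
subclass_count <- function(matches, exact_tract_len = 3L,
                           exact_loop_len = 1L, min_tracts = 4L) {
  if (!"matched_seq" %in% names(matches)) {
    stop("matches must carry a matched_seq column")
  }
  if (nrow(matches) == 0L) return(0L)
  pat <- pqs_pattern(min_tract_len = min(3L, exact_tract_len),
                     loop_min = min(1L, exact_loop_len),
                     loop_max = max(7L, exact_loop_len),
                     min_tracts = min_tracts,
                     exact_tract_len = exact_tract_len,
                     exact_loop_len = exact_loop_len)
  sum(grepl(pqs_regex(pat, anchored = TRUE), matches$matched_seq,
            perl = TRUE))
}

#' Per-species percent-positive summary
#'
#' @param flank_sets Named list of upstream flank data frames, one per
#'   species; the input order is preserved in the output.
#' @param pattern A [pqs_pattern()].
#' @param max_distance Upstream extent, bp (default 5000).
#' @return Data frame with columns `species`, `n_genes`, `percent_positive`.
#' @export
species_summary <- function(flank_sets, pattern = pqs_pattern(),
                            max_distance = 5000L) {
  if (is.null(names(flank_sets)) || any(names(flank_sets) == "")) {
    stop("flank_sets must be a named list (one name per species)")
  }
  if (anyDuplicated(names(flank_sets))) {
    stop("duplicate species label: ",
         names(flank_sets)[duplicated(names(flank_sets))][1L])
  }
  rows <- lapply(names(flank_sets), function(sp) {
    fl <- flank_sets[[sp]]
    anchored <- scan_flanks(fl, pattern)
    data.frame(species = sp, n_genes = length(unique(fl$gene_id)),
               percent_positive = percent_positive(anchored, fl$gene_id,
                                                   max_distance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
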