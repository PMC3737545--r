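# Gene-flank handling: extraction of TSS-upstream / TES-downstream flank
# sequences from a genome, the flat flank-FASTA dialect, and conversion of
# scanner matches into anchor-relative coordinates.
#
# Flank data frames carry one row per flank with columns:
#   gene_id, anchor ("TSS"/"TES"), side ("upstream"/"downstream"),
#   length (requested bp), gene_strand ("+"/"-"), truncated (logical),
#   seq (5'->3' on the gene's sense strand).

.FLANK_COLS <- c("gene_id", "anchor", "side", "length", "gene_strand",
                 "truncated", "seq")

.side_for_anchor <- function(anchor) {
  switch(anchor, TSS = "upstream", TES = "downstream",
         stop("anchor must be 'TSS' or 'TES'"))
}

#' Extract fixed-length gene flanks from a genome
#'
#' For the TSS anchor the upstream flank is returned; for the TES anchor the
#' downstream flank. A gene is the annotated transcribed region (5' UTR,
#' exons, introns, 3' UTR); flanks are always reported 5'->3' on the gene's
#' sense (non-template) strand, so minus-strand genes yield
#' reverse-complemented genomic sequence. Flanks running off a chromosome
#' end are truncated and flagged.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open bounds of the transcribed region) and `strand`
#'   (`"+"` or `"-"`). See [read_gene_bed()] / [read_gene_gff3()].
#' @param anchor `"TSS"` (upstream flank) or `"TES"` (downstream flank).
#' @param length Flank length in bp (default 5000).
#' @return A flank data frame (see above).
#' @export
extract_flanks <- function(genome, genes, anchor = c("TSS", "TES"),
                           length = 5000L) {
  anchor <- match.arg(anchor)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  }
  side <- .side_for_anchor(anchor)

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$chrom %in% names(genome)) {
      stop("unknown chromosome '", g$chrom, "' for gene ", g$gene_id)
    }
    chrom_seq <- genome[[g$chrom]]
    clen <- nchar(chrom_seq)
    if (g$start < 0L || g$end > clen || g$start >= g$end) {
      stop("gene ", g$gene_id, " coordinates outside chromosome bounds")
    }
    # genomic interval of the flank, forward-strand coordinates: the window
    # left of gene start serves (+, TSS) and (-, TES); the window right of
    # gene end serves (+, TES) and (-, TSS)
    if ((anchor == "TSS") == (g$strand == "+")) {
      lo <- g$start - length; hi <- g$start
    } else {
      lo <- g$end; hi <- g$end + length
    }
    lo_c <- max(lo, 0L); hi_c <- min(hi, clen)
    raw <- if (hi_c > lo_c) substr(chrom_seq, lo_c + 1L, hi_c) else ""
    seq <- if (g$strand == "+") toupper(raw) else reverse_complement(raw)
    data.frame(gene_id = g$gene_id, anchor = anchor, side = side,
               length = length, gene_strand = g$strand,
               truncated = nchar(seq) < length, seq = seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read flank sequences from the flank-FASTA dialect
#'
#' Headers follow `>gene_id|anchor|side|length|gene_strand`, e.g.
#' `>G1|TSS|upstream|5000|+`. Sequences are assumed already oriented 5'->3'
#' on the gene's sense strand; a record shorter than its declared length is
#' marked truncated.
#'
#' @param path FASTA file (plain or gzipped).
#' @return A flank data frame.
#' @export
read_flank_fasta <- function(path) {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0L) stop("no sequences in ", path)
  parts <- strsplit(names(recs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad) > 0L) {
    stop("malformed flank header at record ", bad[1L], ": '",
         names(recs)[bad[1L]], "' (expected gene_id|anchor|side|length|strand)")
  }
  f <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(f) <- c("gene_id", "anchor", "side", "length", "gene_strand")
  if (!all(f$anchor %in% c("TSS", "TES"))) stop("invalid anchor in header")
  if (!all(f$side %in% c("upstream", "downstream"))) {
    stop("invalid side in header")
  }
  if (!all(f$gene_strand %in% c("+", "-"))) stop("invalid strand in header")
  f$length <- as.integer(f$length)
  if (anyNA(f$length)) stop("non-integer length in header")
  key <- paste(f$gene_id, f$anchor, f$side)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, anchor, side): ", key[duplicated(key)][1L])
  }
  f$seq <- unname(as.character(recs))
  f$truncated <- nchar(f$seq) < f$length
  f[, .FLANK_COLS]
}

#' Write flank sequences in the flank-FASTA dialect
#'
#' @param flanks A flank data frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flank_fasta <- function(flanks, path) {
  stopifnot(all(.FLANK_COLS %in% names(flanks)))
  x <- Biostrings::DNAStringSet(flanks$seq)
  names(x) <- paste(flanks$gene_id, flanks$anchor, flanks$side,
                    flanks$length, flanks$gene_strand, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Express scanner matches in anchor-relative coordinates
#'
#' For an upstream flank of realized length `L`, flank offset `i` (0-based)
#' maps to coordinate `i - L`, so the base immediately 5' of the TSS is -1.
#' For a downstream flank, offset `i` maps to `i + 1`. A match occupying
#' offsets `[s, e)` is assigned the coordinate of `s` -- for upstream flanks
#' its most anchor-distal (most negative) base -- and span `e - s`.
#' Plus-strand matches on the sense-oriented flank lie on the non-template
#' strand; minus-strand matches on the template strand.
#'
#' @param flank A single flank (one-row flank data frame or equivalent list).
#' @param matches Matches from [scan_both_strands()] (or [scan_forward()])
#'   run on `flank$seq`.
#' @return Data frame with columns `gene_id`, `anchor`, `side`, `coord`,
#'   `span`, `strand_class` (`"non-template"` / `"template"`).
#' @examples
#' fl <- list(gene_id = "G1", anchor = "TSS", side = "upstream",
#'            seq = strrep("A", 100))
#' anchor_matches(fl, scan_both_strands(fl$seq))
#' @export
anchor_matches <- function(flank, matches) {
  L <- nchar(flank$seq)
  if (nrow(matches) == 0L) {
    return(data.frame(gene_id = character(), anchor = character(),
                      side = character(), coord = integer(),
                      span = integer(), strand_class = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(matches$start < 0L) || any(matches$end > L)) {
    stop("match outside flank bounds for gene ", flank$gene_id)
  }
  coord <- if (flank$side == "upstream") matches$start - L
           else matches$start + 1L
  data.frame(gene_id = flank$gene_id, anchor = flank$anchor,
             side = flank$side, coord = as.integer(coord),
             span = matches$end - matches$start,
             strand_class = ifelse(matches$strand == "+",
                                   "non-template", "template"),
             stringsAsFactors = FALSE)
}

#' Scan a set of flanks and anchor all matches
#'
#' Runs [scan_both_strands()] on every flank and converts the matches with
#' [anchor_matches()]. The scan itself is vectorised over flanks (one PCRE
#' pass per strand).
#'
#' @param flanks A flank data frame.
#' @param pattern A [pqs_pattern()].
#' @param keep_matched_seq If `TRUE`, retain the matched sequence string of
#'   each motif (needed by [subclass_count()]).
#' @return Anchored-match data frame (`gene_id`, `anchor`, `side`, `coord`,
#'   `span`, `strand_class`, and `matched_seq` if requested), ordered by
#'   flank then coordinate.
#' @export
scan_flanks <- function(flanks, pattern = pqs_pattern(),
                        keep_matched_seq = FALSE) {
  stopifnot(nrow(flanks) >= 1L)
  seqs <- toupper(flanks$seq)
  rcs <- reverse_complement(seqs)
  rx <- pqs_regex(pattern)
  hit_p <- gregexpr(rx, seqs, perl = TRUE)
  hit_m <- gregexpr(rx, rcs, perl = TRUE)
  out <- vector("list", nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    L <- nchar(seqs[[i]])
    rows <- list()
    mp <- hit_p[[i]]
    if (mp[1L] != -1L) {
      len <- attr(mp, "match.length")
      rows[[1L]] <- data.frame(start = as.integer(mp) - 1L,
                               end = as.integer(mp) - 1L + len,
                               strand = "+",
                               matched_seq = substring(seqs[[i]],
                                                       as.integer(mp),
                                                       as.integer(mp) + len - 1L),
                               stringsAsFactors = FALSE)
    }
    mm <- hit_m[[i]]
    if (mm[1L] != -1L) {
      len <- attr(mm, "match.length")
      s_rc <- as.integer(mm) - 1L
      rows[[2L]] <- data.frame(start = L - (s_rc + len), end = L - s_rc,
                               strand = "-",
                               matched_seq = substring(rcs[[i]],
                                                       as.integer(mm),
                                                       as.integer(mm) + len - 1L),
                               stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) next
    m <- do.call(rbind, rows)
    m <- m[order(m$start, m$strand != "+"), , drop = FALSE]
    a <- anchor_matches(flanks[i, ], m)
    if (keep_matched_seq) a$matched_seq <- m$matched_seq
    out[[i]] <- a
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    a <- anchor_matches(flanks[1, ], .empty_matches())
    if (keep_matched_seq) a$matched_seq <- character()
    return(a)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
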