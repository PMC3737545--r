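#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

# IUPAC DNA codes accepted on input (after uppercasing).
.IUPAC_DNA <- "ACGTNRYSWKMBDHV"

# Uppercase and validate a single nucleotide string; returns the uppercased
# sequence or fails naming the first offending position (1-based).
.validate_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single non-NA character string")
  }
  s <- toupper(seq)
  bad <- regexpr(sprintf("[^%s]", .IUPAC_DNA), s)[1L]
  if (bad != -1L) {
    stop(sprintf("invalid nucleotide character '%s' at position %d",
                 substr(s, bad, bad), bad))
  }
  s
}

.empty_matches <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
              strand = character(), n_tracts = integer(),
              matched_seq = character(), stringsAsFactors = FALSE)
}

#' Reverse-complement nucleotide sequences
#'
#' Standard Watson-Crick complement (IUPAC ambiguity codes included, N maps
#' to N), reversed. Vectorised over its argument.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGGT")  # "ACCC"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character())
  s <- vapply(seq, .validate_seq, character(1), USE.NAMES = FALSE)
  unname(as.character(reverseComplement(DNAStringSet(s))))
}

# G-run table: gr[i] = length of the maximal run of G starting at position i.
.g_runs <- function(s) {
  isg <- utf8ToInt(s) == 71L
  n <- length(isg)
  gr <- integer(n)
  run <- 0L
  for (i in seq.int(n, 1L)) {
    run <- if (isg[i]) run + 1L else 0L
    gr[i] <- run
  }
  gr
}

# Backtracking parse of a (candidate) match starting at position 1 of `s`,
# in the exploration order of the published pattern: the first tract is
# greedy, each loop lazy, each subsequent tract greedy, and the repeat count
# greedy (extension is attempted before stopping). Returns NULL or
# list(end, n_tracts) for the first successful parse.
.parse_pqs <- function(s, pattern) {
  b <- .pattern_bounds(pattern)
  n <- nchar(s)
  if (n == 0L) return(NULL)
  gr <- .g_runs(s)

  units <- function(pos, k) {
    # try to absorb one more loop+tract unit before stopping
    for (l in seq.int(b$lmin, b$lmax)) {
      tp <- pos + l
      if (tp > n) break
      if (gr[tp] >= b$tmin) {
        for (t in seq.int(min(gr[tp], b$tmax, n - tp + 1L), b$tmin)) {
          r <- units(tp + t, k + 1L)
          if (!is.null(r)) return(r)
        }
      }
    }
    if (k >= b$min_tracts - 1L) list(end = pos - 1L, n_tracts = k + 1L)
    else NULL
  }

  if (gr[1L] < b$tmin) return(NULL)
  for (t in seq.int(min(gr[1L], b$tmax, n), b$tmin)) {
    r <- units(1L + t, 0L)
    if (!is.null(r)) return(r)
  }
  NULL
}

#' Scan the forward strand for PQS motifs
#'
#' Finds leftmost, non-overlapping PQS matches by repeated global matching:
#' after each match, scanning resumes at the match end. The disambiguation
#' semantics are those of the backtracking pattern `G{3,}(.{1,7}?G{3,}){3,}`:
#' greedy G-tracts, lazy loops, greedy repeat count. Only the literal
#' character G counts toward a tract; loop positions accept any nucleotide,
#' including G. Input is uppercased before scanning, so soft-masked bases
#' are scanned.
#'
#' @param seq A single nucleotide string (IUPAC DNA codes).
#' @param pattern A [pqs_pattern()].
#' @param seq_id Optional identifier recorded with each match.
#' @return A data frame with columns `seq_id`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`"+"`), `n_tracts` (G-tract count
#'   of the winning parse) and `matched_seq`.
#' @examples
#' scan_forward("GGGTGGGTGGGTGGG")   # one 15-nt match, 4 tracts
#' scan_forward("GCGTGGCTCCGTCGC")   # mutant control: no match
#' @export
scan_forward <- function(seq, pattern = pqs_pattern(),
                         seq_id = NA_character_) {
  s <- .validate_seq(seq)
  if (nchar(s) == 0L) return(.empty_matches())
  m <- gregexpr(pqs_regex(pattern), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(.empty_matches())
  len <- attr(m, "match.length")
  start1 <- as.integer(m)
  matched <- substring(s, start1, start1 + len - 1L)
  n_tracts <- vapply(matched, function(ms) {
    p <- .parse_pqs(ms, pattern)
    if (is.null(p)) NA_integer_ else p$n_tracts
  }, integer(1), USE.NAMES = FALSE)
  data.frame(seq_id = rep(seq_id, length(start1)), start = start1 - 1L,
             end = start1 - 1L + len, strand = "+", n_tracts = n_tracts,
             matched_seq = matched, stringsAsFactors = FALSE)
}

#' Scan both strands for PQS motifs
#'
#' Plus-strand matches come from [scan_forward()] on the sequence as given;
#' minus-strand matches from scanning its reverse complement, with
#' coordinates mapped back to forward-strand offsets (a reverse-strand match
#' at `[s, e)` on the reverse complement maps to `[L - e, L - s)`).
#' `matched_seq` always reads 5'->3' on the matched strand.
#'
#' @inheritParams scan_forward
#' @return A data frame as in [scan_forward()], sorted by forward `start`
#'   (plus before minus on ties), with `strand` in `{"+", "-"}`.
#' @examples
#' scan_both_strands("CCCACCCACCCACCC")  # one minus-strand match
#' @export
scan_both_strands <- function(seq, pattern = pqs_pattern(),
                              seq_id = NA_character_) {
  s <- .validate_seq(seq)
  plus <- scan_forward(s, pattern, seq_id)
  rc <- reverse_complement(s)
  minus <- scan_forward(rc, pattern, seq_id)
  if (nrow(minus) > 0L) {
    L <- nchar(s)
    new_start <- L - minus$end
    minus$end <- L - minus$start
    minus$start <- new_start
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
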