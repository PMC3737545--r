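# Reference scanner used to cross-check the production matcher. Implemented
# from first principles on character vectors, with no code shared with
# scan_forward()/.parse_pqs(): decompositions into tracts and loops are
# explored in an explicit lexicographic preference order and the first
# complete decomposition wins.

#' Reference PQS scanner (exhaustive preference-ordered search)
#'
#' Independent re-implementation of the PQS matching semantics, intended as
#' a test oracle at small scale (sequences up to a few hundred nt). At each
#' start offset, candidate decompositions into G-tracts and loops are
#' explored in the preference order
#' (leftmost start) > (longer first tract) > per unit: (shorter loop) >
#' (longer tract) > (more repeat units, i.e. extension before stopping),
#' applied left to right across the decomposition. This order is exactly the
#' backtracking order of a greedy-tract / lazy-loop / greedy-repeat pattern,
#' so the first complete decomposition found is the winning parse. After an
#' accepted match, scanning resumes at the match end.
#'
#' @inheritParams scan_forward
#' @return A data frame with the same columns as [scan_forward()].
#' @export
oracle_scan <- function(seq, pattern = pqs_pattern(),
                        seq_id = NA_character_) {
  s <- .validate_seq(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (is.null(pattern$exact_tract_len)) {
    t_lo <- pattern$min_tract_len; t_hi <- NA_integer_  # unbounded
  } else {
    t_lo <- t_hi <- pattern$exact_tract_len
  }
  if (is.null(pattern$exact_loop_len)) {
    l_lo <- pattern$loop_min; l_hi <- pattern$loop_max
  } else {
    l_lo <- l_hi <- pattern$exact_loop_len
  }
  need_units <- pattern$min_tracts - 1L

  run_at <- function(i) {
    k <- 0L
    while (i + k <= n && ch[i + k] == "G") k <- k + 1L
    k
  }

  # Explore loop+tract units from `at`; `done` units already accepted.
  # Returns the end (exclusive, 0-based == last consumed 1-based index) and
  # unit count of the first acceptable continuation, or NULL.
  explore_units <- function(at, done) {
    for (loop_len in l_lo:l_hi) {
      tract_start <- at + loop_len
      if (tract_start > n) break
      avail <- run_at(tract_start)
      hi <- if (is.na(t_hi)) avail else min(avail, t_hi)
      if (hi >= t_lo) {
        for (tract_len in hi:t_lo) {
          res <- explore_units(tract_start + tract_len, done + 1L)
          if (!is.null(res)) return(res)
        }
      }
    }
    if (done >= need_units) list(end = at - 1L, units = done) else NULL
  }

  hits <- list()
  i <- 1L
  while (i <= n) {
    first <- run_at(i)
    found <- NULL
    if (first >= t_lo) {
      hi1 <- if (is.na(t_hi)) first else min(first, t_hi)
      for (tract_len in hi1:t_lo) {
        found <- explore_units(i + tract_len, 0L)
        if (!is.null(found)) break
      }
    }
    if (is.null(found)) {
      i <- i + 1L
    } else {
      hits[[length(hits) + 1L]] <-
        list(start = i - 1L, end = found$end, n_tracts = found$units + 1L)
      i <- found$end + 1L
    }
  }
  if (length(hits) == 0L) return(.empty_matches())
  start0 <- vapply(hits, `[[`, integer(1), "start")
  end0 <- vapply(hits, `[[`, integer(1), "end")
  data.frame(seq_id = rep(seq_id, length(hits)), start = start0, end = end0,
             strand = "+",
             n_tracts = vapply(hits, `[[`, integer(1), "n_tracts"),
             matched_seq = substring(s, start0 + 1L, end0),
             stringsAsFactors = FALSE)
}
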