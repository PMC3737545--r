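# Full-enumeration reference matcher for short sequences: lists EVERY
# decomposition into tracts and loops at the leftmost feasible start and
# picks the winner with an explicit comparator over the decision vector
# (t1, l1, t2, l2, ...): longer tract wins, then shorter loop, compared left
# to right; with one decision vector a prefix of the other, the longer
# (more repeat units) wins. This is the backtracking preference of a
# greedy-tract / lazy-loop / greedy-repeat pattern, so it must agree with
# both scan_forward() and oracle_scan(). Exponential; keep inputs short.

enumerate_scan <- function(s, pattern = pqs_pattern()) {
  s <- toupper(s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  tmin <- pattern$min_tract_len
  tmax <- if (is.null(pattern$exact_tract_len)) Inf else pattern$exact_tract_len
  if (!is.null(pattern$exact_tract_len)) tmin <- pattern$exact_tract_len
  lmin <- if (is.null(pattern$exact_loop_len)) pattern$loop_min else pattern$exact_loop_len
  lmax <- if (is.null(pattern$exact_loop_len)) pattern$loop_max else pattern$exact_loop_len
  grun <- function(i) {
    k <- 0L
    while (i + k <= n && ch[i + k] == "G") k <- k + 1L
    k
  }
  # all decision vectors for complete parses starting at 1-based pos
  all_parses <- function(pos) {
    res <- list()
    recurse <- function(at, decisions, tracts) {
      if (tracts >= pattern$min_tracts) {
        res[[length(res) + 1L]] <<- list(dec = decisions, end = at - 1L,
                                         n_tracts = tracts)
      }
      for (l in lmin:lmax) {
        tp <- at + l
        if (tp > n) break
        avail <- min(grun(tp), tmax)
        if (avail >= tmin) {
          for (t in tmin:avail) {
            recurse(tp + t, c(decisions, l, t), tracts + 1L)
          }
        }
      }
    }
    avail1 <- min(grun(pos), tmax)
    if (avail1 >= tmin) {
      for (t1 in tmin:avail1) recurse(pos + t1, c(t1), 1L)
    }
    res
  }
  # TRUE if decision vector a beats b. Positions alternate tract (odd,
  # longer preferred) and loop (even, shorter preferred).
  beats <- function(a, b) {
    m <- min(length(a), length(b))
    for (i in seq_len(m)) {
      if (a[i] != b[i]) {
        return(if (i %% 2L == 1L) a[i] > b[i] else a[i] < b[i])
      }
    }
    length(a) > length(b)
  }
  hits <- list()
  i <- 1L
  while (i <= n) {
    parses <- all_parses(i)
    if (length(parses) == 0L) {
      i <- i + 1L
      next
    }
    best <- parses[[1L]]
    for (p in parses[-1L]) if (beats(p$dec, best$dec)) best <- p
    hits[[length(hits) + 1L]] <- data.frame(
      start = i - 1L, end = best$end, n_tracts = best$n_tracts,
      stringsAsFactors = FALSE)
    i <- best$end + 1L
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      n_tracts = integer()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
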