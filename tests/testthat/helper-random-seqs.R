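# Shared generators for property-style tests.

# Random G-enriched DNA string.
random_g_rich <- function(len, p_g = 0.4) {
  rest <- (1 - p_g) / 3
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(rest, rest, p_g, rest)), collapse = "")
}

match_key <- function(m) paste(m$start, m$end, m$n_tracts, m$strand)

anchored_key <- function(a) {
  paste(a$gene_id, a$side, a$coord, a$span, a$strand_class)
}

# Both-strand reference scan assembled from the forward-only oracle, for
# comparison against scan_both_strands().
oracle_both_strands <- function(seq, pattern = pqs_pattern()) {
  plus <- oracle_scan(seq, pattern)
  rc <- reverse_complement(seq)
  minus <- oracle_scan(rc, pattern)
  if (nrow(minus) > 0L) {
    L <- nchar(seq)
    s <- L - minus$end
    minus$end <- L - minus$start
    minus$start <- s
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
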