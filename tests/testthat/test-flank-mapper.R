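# A tiny deterministic chromosome: position i (0-based) carries a known
# base, so extraction arithmetic is directly checkable.
make_chrom <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "T"), len, replace = TRUE), collapse = "")
}

test_that("flank extraction does the stated coordinate arithmetic", {
  chrom <- make_chrom(3000)
  genome <- c(chr1 = chrom)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "+", stringsAsFactors = FALSE)
  up <- extract_flanks(genome, genes, "TSS", length = 500L)
  expect_equal(up$seq, substr(chrom, 501, 1000))
  expect_false(up$truncated)
  dn <- extract_flanks(genome, genes, "TES", length = 500L)
  expect_equal(dn$seq, substr(chrom, 2001, 2500))

  genes$strand <- "-"
  up_m <- extract_flanks(genome, genes, "TSS", length = 500L)
  expect_equal(up_m$seq, reverse_complement(substr(chrom, 2001, 2500)))
  dn_m <- extract_flanks(genome, genes, "TES", length = 500L)
  expect_equal(dn_m$seq, reverse_complement(substr(chrom, 501, 1000)))
})

test_that("flanks running off the chromosome are truncated and flagged", {
  chrom <- make_chrom(1000)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                      end = 400L, strand = "+", stringsAsFactors = FALSE)
  up <- extract_flanks(c(chr1 = chrom), genes, "TSS", length = 500L)
  expect_true(up$truncated)
  expect_equal(nchar(up$seq), 100L)
  expect_equal(up$seq, substr(chrom, 1, 100))
})

test_that("annotation problems are rejected", {
  genome <- c(chr1 = make_chrom(500))
  genes <- data.frame(gene_id = c("g1", "g1"), chrom = "chr1",
                      start = c(100L, 200L), end = c(150L, 300L),
                      strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_flanks(genome, genes, "TSS", 50), "duplicate")
  genes2 <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                       end = 600L, strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_flanks(genome, genes2, "TSS", 50), "outside")
})

test_that("flank FASTA dialect round-trips and validates headers", {
  cfg <- synthetic_config(n_genes = 5, flank_len = 300, seed = 7)
  fl <- generate_flank_set(cfg)$flanks
  path <- tempfile(fileext = ".fa")
  write_flank_fasta(fl, path)
  back <- read_flank_fasta(path)
  expect_equal(back, fl[, names(back)])

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">G1|TSS|upstream|300", strrep("A", 300)), bad)
  expect_error(read_flank_fasta(bad), "record 1")
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">G1|TSS|upstream|10|+", strrep("A", 10),
               ">G1|TSS|upstream|10|+", strrep("A", 10)), dup)
  expect_error(read_flank_fasta(dup), "duplicate")
})

test_that("anchoring maps flank offsets to the documented conventions", {
  fl <- list(gene_id = "g1", anchor = "TSS", side = "upstream",
             seq = strrep("A", 5000))
  m <- data.frame(start = c(4450L, 4985L), end = c(4465L, 5000L),
                  strand = c("+", "-"), stringsAsFactors = FALSE)
  a <- anchor_matches(fl, m)
  expect_equal(a$coord, c(-550L, -15L))
  expect_equal(a$span, c(15L, 15L))
  expect_equal(a$strand_class, c("non-template", "template"))

  fld <- list(gene_id = "g1", anchor = "TES", side = "downstream",
              seq = strrep("A", 100))
  ad <- anchor_matches(fld, data.frame(start = 0L, end = 15L, strand = "+"))
  expect_equal(ad$coord, 1L)

  expect_error(
    anchor_matches(fld, data.frame(start = 90L, end = 105L, strand = "+")),
    "bounds")
})

test_that("a genomic plant is recovered at the same anchored coordinate for all four gene configurations", {
  motif <- "GGGTGGGTGGGTGGG"
  L <- 500L
  for (gene_strand in c("+", "-")) {
    for (anchor in c("TSS", "TES")) {
      set.seed(99)  # A/T background: neither strand can carry a G-run
      chrom <- paste(sample(c("A", "T"), 3000, replace = TRUE), collapse = "")
      genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                          end = 2000L, strand = gene_strand,
                          stringsAsFactors = FALSE)
      # place the motif on the gene's sense strand at anchored coordinate
      # -120 (upstream) or +61 (downstream): flank offset -> genomic offset
      offset_in_flank <- if (anchor == "TSS") L - 120L else 60L
      if (gene_strand == "+") {
        gstart0 <- if (anchor == "TSS") 500L + offset_in_flank
                   else 2000L + offset_in_flank
        planted <- motif
      } else {
        # sense flank is the reverse complement of the genomic window
        flank_start <- if (anchor == "TSS") 2000L else 500L
        gstart0 <- flank_start + (L - offset_in_flank - nchar(motif))
        planted <- reverse_complement(motif)
      }
      substr(chrom, gstart0 + 1L, gstart0 + nchar(motif)) <- planted
      fl <- extract_flanks(c(chr1 = chrom), genes, anchor, L)
      a <- scan_flanks(fl)
      expect_equal(nrow(a), 1L)
      expect_equal(a$coord, if (anchor == "TSS") -120L else 61L)
      expect_equal(a$span, nchar(motif))
      expect_equal(a$strand_class, "non-template")
    }
  }
})

test_that("anchoring is injective over a flank's matches", {
  cfg <- synthetic_config(n_genes = 30, flank_len = 2000, lambda0 = 5e-4,
                          seed = 11)
  sim <- generate_flank_set(cfg, sides = "upstream")
  a <- scan_flanks(sim$flanks)
  expect_false(any(duplicated(a[, c("gene_id", "coord", "strand_class")])))
})
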