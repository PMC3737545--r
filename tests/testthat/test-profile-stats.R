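mk_anchored <- function(coords, side = "upstream",
                        strand_class = "non-template",
                        gene_id = sprintf("g%03d", seq_along(coords))) {
  n <- length(coords)
  data.frame(gene_id = rep_len(gene_id, n),
             anchor = rep(if (side == "upstream") "TSS" else "TES", n),
             side = rep(side, n), coord = as.integer(coords),
             span = rep(15L, n),
             strand_class = rep_len(strand_class, n),
             stringsAsFactors = FALSE)
}

test_that("window frequencies are per-100-sequence counts", {
  p <- frequency_profile(mk_anchored(-50), n_sequences = 100)
  expect_equal(p$frequency[p$win_start == -100], 1.0)
  expect_equal(sum(p$frequency), 1.0)
  expect_equal(nrow(p), 50L)
  expect_equal(p$win_end[p$win_start == -100], -1L)

  a <- mk_anchored(c(-150, -120, -199, -101, -180))
  p2 <- frequency_profile(a, n_sequences = 50)
  expect_equal(p2$frequency[p2$win_start == -200], 10.0)

  empty <- mk_anchored(integer(0))
  p0 <- frequency_profile(empty, n_sequences = 10)
  expect_true(all(p0$frequency == 0))
})

test_that("profile input is validated", {
  expect_error(frequency_profile(mk_anchored(-50), n_sequences = 0),
               "n_sequences")
  mixed <- rbind(mk_anchored(-50), mk_anchored(50, side = "downstream"))
  expect_error(frequency_profile(mixed, n_sequences = 10), "mix")
})

test_that("window counts conserve the number of anchored matches", {
  cfg <- synthetic_config(n_genes = 120, flank_len = 2000, lambda0 = 4e-4,
                          seed = 21)
  sim <- generate_flank_set(cfg, sides = "upstream")
  a <- scan_flanks(sim$flanks)
  for (scope in c("both", "non-template", "template")) {
    p <- frequency_profile(a, n_sequences = 120, window = 100,
                           strand_scope = scope, flank_len = 2000)
    in_scope <- if (scope == "both") a else a[a$strand_class == scope, ]
    expect_equal(sum(p$count), nrow(in_scope))
    expect_equal(sum(p$frequency) * 120 / 100, nrow(in_scope))
  }
})

test_that("profiles are additive across strand scopes and invariant to reordering", {
  cfg <- synthetic_config(n_genes = 80, flank_len = 1000, lambda0 = 6e-4,
                          seed = 22)
  sim <- generate_flank_set(cfg, sides = "upstream")
  a <- scan_flanks(sim$flanks)
  both <- frequency_profile(a, 80, flank_len = 1000)
  nt <- frequency_profile(a, 80, strand_scope = "non-template",
                          flank_len = 1000)
  tp <- frequency_profile(a, 80, strand_scope = "template",
                          flank_len = 1000)
  expect_equal(both$count, nt$count + tp$count)

  shuf <- a[sample(nrow(a)), ]
  shuf$gene_id <- paste0("relabel_", shuf$gene_id)
  expect_equal(frequency_profile(shuf, 80, flank_len = 1000)$frequency,
               both$frequency)
})

test_that("TES insert profiles split strands at 20 nt resolution", {
  a <- mk_anchored(30, side = "downstream")
  out <- tes_strand_insert_profile(a, n_sequences = 10)
  expect_equal(nrow(out$non_template), 50L)
  nt <- out$non_template
  expect_equal(nt$frequency[nt$win_start == 21], 10.0)
  expect_true(all(out$template$frequency == 0))

  swapped <- a
  swapped$strand_class <- "template"
  out2 <- tes_strand_insert_profile(swapped, n_sequences = 10)
  expect_equal(out2$template$frequency, out$non_template$frequency)
  expect_equal(out2$non_template$frequency, out$template$frequency)

  out0 <- tes_strand_insert_profile(mk_anchored(integer(0), side = "downstream"), 10)
  expect_true(all(out0$non_template$frequency == 0))
  expect_true(all(out0$template$frequency == 0))
  expect_error(tes_strand_insert_profile(mk_anchored(-5), 10), "downstream")
})

test_that("cumulative curves step where motifs become wholly contained", {
  a <- mk_anchored(c(-24, -300, -150), gene_id = c("A", "A", "B"))
  cc <- cumulative_distribution(a, c("A", "B"), max_distance = 400)
  expect_equal(cc$cum_positive_pct[23], 0)
  expect_equal(cc$cum_positive_pct[24], 50)
  expect_equal(cc$cum_positive_pct[149], 50)
  expect_equal(cc$cum_positive_pct[150], 100)
  expect_equal(cc$cum_positive_pct[400], 100)
  expect_equal(cc$cum_motifs[c(23, 24, 149, 150, 299, 300)],
               c(0, 1, 1, 2, 2, 3))
  expect_true(all(diff(cc$cum_motifs) >= 0))
  expect_true(all(diff(cc$cum_positive_pct) >= 0))
})

test_that("cumulative edge cases: no motifs, saturation, unknown genes", {
  cc0 <- cumulative_distribution(mk_anchored(integer(0)), c("A", "B"), 100)
  expect_true(all(cc0$cum_motifs == 0))
  expect_true(all(cc0$cum_positive_pct == 0))

  sat <- mk_anchored(rep(-15, 4), gene_id = c("A", "B", "C", "D"))
  ccs <- cumulative_distribution(sat, c("A", "B", "C", "D"), 100)
  expect_true(all(ccs$cum_positive_pct[15:100] == 100))
  expect_true(all(ccs$cum_positive_pct[1:14] == 0))

  expect_error(cumulative_distribution(sat, c("A", "B"), 100), "universe")
})

test_that("percent_positive equals the cumulative endpoint", {
  a <- mk_anchored(c(-10, -4990), gene_id = c("A", "B"))
  expect_equal(percent_positive(a, c("A", "B", "C", "D")), 50)
  cfg <- synthetic_config(n_genes = 60, flank_len = 1500, lambda0 = 3e-4,
                          seed = 23)
  sim <- generate_flank_set(cfg, sides = "upstream")
  an <- scan_flanks(sim$flanks)
  cc <- cumulative_distribution(an, sim$flanks$gene_id, 1500)
  expect_equal(percent_positive(an, sim$flanks$gene_id, 1500),
               cc$cum_positive_pct[1500])
  expect_error(percent_positive(a, character(0)), "empty")
})

test_that("the compact G3/1-nt-loop subclass is recognised by full-extent parse", {
  counted <- scan_forward("GGGTGGGTGGGTGGG")
  expect_equal(subclass_count(counted), 1L)
  long_loop <- scan_forward("GGGTTGGGTGGGTGGG")
  expect_equal(nrow(long_loop), 1L)  # still a PQS
  expect_equal(subclass_count(long_loop), 0L)
  long_tract <- scan_forward("GGGGTGGGTGGGTGGG")
  expect_equal(nrow(long_tract), 1L)
  expect_equal(subclass_count(long_tract), 0L)
  # five exact tracts still qualify
  five <- scan_forward("GGGAGGGAGGGAGGGAGGG")
  expect_equal(subclass_count(five), 1L)
  expect_equal(subclass_count(scan_forward("")), 0L)
})

test_that("species summaries preserve order and separate planting densities", {
  dense <- generate_flank_set(
    synthetic_config(n_genes = 150, flank_len = 1500, lambda0 = 1e-3,
                     seed = 31), sides = "upstream")$flanks
  sparse <- generate_flank_set(
    synthetic_config(n_genes = 150, flank_len = 1500, lambda0 = 1e-4,
                     seed = 32), sides = "upstream")$flanks
  none <- generate_flank_set(
    synthetic_config(n_genes = 30, flank_len = 1500, lambda0 = 0,
                     seed = 33), sides = "upstream")$flanks
  out <- species_summary(list(dense = dense, sparse = sparse, none = none),
                         max_distance = 1500)
  expect_equal(out$species, c("dense", "sparse", "none"))
  expect_gt(out$percent_positive[1], out$percent_positive[2])
  expect_gt(out$percent_positive[2], out$percent_positive[3])
  expect_equal(out$percent_positive[3], 0)
  expect_error(species_summary(list(a = dense, a = sparse)), "duplicate")
})
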