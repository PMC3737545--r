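# Synthetic flank cohorts with exact ground truth. Backgrounds are kept
# free of runs of three or more G or C so that every scanner hit is a
# planted motif and every planted motif is recovered at its exact
# coordinates; plants are separated by a clearance margin so matches never
# merge under the non-overlapping scan policy.

#' Configuration for a synthetic flank cohort
#'
#' The generator emulates the data regime the metaprofile analysis assumes:
#' fixed-length flanks per gene, a TSS-proximal enrichment of motif density
#' over a flat background upstream, a flat density downstream of the TES,
#' and motifs falling on either strand.
#'
#' @param n_genes Number of genes.
#' @param flank_len Flank length, bp (default 5000).
#' @param background_composition Named probabilities over A, C, G, T for
#'   background bases (default approximates a 41% GC genome).
#' @param g_run_free If `TRUE` (default), background is repaired until it
#'   contains no run of >= 3 G or >= 3 C, making ground truth exact.
#' @param lambda0 Background planting rate per nt per gene (default 1e-4;
#'   with the other defaults roughly 60% of genes acquire an upstream motif
#'   within 5 kb).
#' @param enrich_fold Fold-enrichment of the planting rate in the
#'   TSS-proximal zone (default 5).
#' @param enrich_width Width of the TSS-proximal enriched zone, bp
#'   (default 1000). For the Gaussian shape this is the standard deviation.
#' @param enrich_shape `"step"` (default) or `"gaussian"`.
#' @param strand_probability Probability a plant goes on the template
#'   strand (default 0.5).
#' @param clearance Minimum gap between plants on one flank, nt (default 8;
#'   larger than the maximal loop, so adjacent plants cannot merge into one
#'   match).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param pattern [pqs_pattern()] the plants are sampled from.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes, flank_len = 5000L,
                             background_composition = c(A = 0.295, C = 0.205,
                                                        G = 0.205, T = 0.295),
                             g_run_free = TRUE, lambda0 = 1e-4,
                             enrich_fold = 5, enrich_width = 1000L,
                             enrich_shape = c("step", "gaussian"),
                             strand_probability = 0.5, clearance = 8L,
                             seed = 1L, pattern = pqs_pattern()) {
  enrich_shape <- match.arg(enrich_shape)
  stopifnot(n_genes >= 1L, flank_len >= 50L, lambda0 >= 0,
            enrich_fold >= 0, enrich_width >= 1L,
            strand_probability >= 0, strand_probability <= 1,
            clearance >= 0L)
  comp <- background_composition[c("A", "C", "G", "T")]
  if (anyNA(comp) || any(comp < 0) || abs(sum(comp) - 1) > 1e-8) {
    stop("background_composition must be probabilities over A, C, G, T summing to 1")
  }
  structure(
    list(n_genes = as.integer(n_genes), flank_len = as.integer(flank_len),
         background_composition = comp, g_run_free = isTRUE(g_run_free),
         lambda0 = lambda0, enrich_fold = enrich_fold,
         enrich_width = as.integer(enrich_width),
         enrich_shape = enrich_shape,
         strand_probability = strand_probability,
         clearance = as.integer(clearance), seed = as.integer(seed),
         pattern = pattern),
    class = "synthetic_config"
  )
}

# Background flank as an integer code vector (1=A 2=C 3=G 4=T), with runs of
# >= 3 G or C broken by rewriting every third base of the run.
.background_codes <- function(len, comp, g_run_free) {
  x <- sample.int(4L, len, replace = TRUE, prob = comp)
  if (g_run_free) {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$lengths >= 3L & (r$values == 2L | r$values == 3L))
    for (i in bad) {
      idx <- seq.int(starts[i] + 2L, ends[i], by = 3L)
      x[idx] <- if (r$values[i] == 3L) 1L else 4L
    }
  }
  x
}

.CODE_CHARS <- c(65L, 67L, 71L, 84L)  # utf8 codes of A C G T

#' Sample one PQS instance from a motif grammar
#'
#' Draws a string guaranteed to parse under the grammar: a uniform tract
#' count in `[min_tracts, min_tracts + 2]`, tract lengths in
#' `[min_tract_len, min_tract_len + 1]`, loop lengths in
#' `[loop_min, loop_max]` (exact lengths are honoured when set) and loop
#' characters from A, C, T -- never G, and never three consecutive C, so
#' that neither strand of the instance contains a spurious G-tract.
#'
#' Uses the current RNG state (seed it, or call within a seeded generator).
#'
#' @param pattern A [pqs_pattern()].
#' @return A nucleotide string.
#' @export
sample_pqs_instance <- function(pattern = pqs_pattern()) {
  b <- .pattern_bounds(pattern)
  pick <- function(v, n) if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
  n_tracts <- pick(seq.int(b$min_tracts, b$min_tracts + 2L), 1L)
  t_hi <- if (is.finite(b$tmax)) b$tmax else b$tmin + 1L
  tract_len <- pick(seq.int(b$tmin, t_hi), n_tracts)
  loop_len <- pick(seq.int(b$lmin, b$lmax), n_tracts - 1L)
  loops <- vapply(loop_len, function(l) {
    if (l == 0L) return("")
    repeat {
      s <- paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
      if (!grepl("CCC", s, fixed = TRUE)) return(s)
    }
  }, character(1))
  paste0(paste0(strrep("G", tract_len[-n_tracts]), loops, collapse = ""),
         strrep("G", tract_len[n_tracts]))
}

# Per-distance planting rate for one side. Distances run 1..flank_len away
# from the anchor.
.lambda_profile <- function(config, side) {
  d <- seq_len(config$flank_len)
  if (side == "downstream") return(rep(config$lambda0, config$flank_len))
  if (config$enrich_shape == "step") {
    config$lambda0 * ifelse(d <= config$enrich_width, config$enrich_fold, 1)
  } else {
    config$lambda0 *
      (1 + (config$enrich_fold - 1) * exp(-d^2 / (2 * config$enrich_width^2)))
  }
}

#' Generate a synthetic flank cohort with ground truth
#'
#' For every gene, builds a background flank (G/C-run-free by default) for
#' each requested side, draws plant positions from the configured density
#' profile, and embeds freshly sampled PQS instances -- reverse-complemented
#' for template-strand plants -- with a one-base non-G/C guard on either
#' side so planted coordinates are recovered exactly by scanning. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param sides Which flanks to generate: subset of
#'   `c("upstream", "downstream")`.
#' @return A list with elements `flanks` (flank data frame; TSS/upstream
#'   and/or TES/downstream per gene) and `truth` (data frame `gene_id`,
#'   `anchor`, `side`, `coord`, `span`, `strand_class`, `motif_seq`).
#' @export
generate_flank_set <- function(config,
                               sides = c("upstream", "downstream")) {
  stopifnot(inherits(config, "synthetic_config"))
  sides <- match.arg(sides, several.ok = TRUE)
  set.seed(config$seed)
  L <- config$flank_len
  lam <- lapply(stats::setNames(sides, sides),
                function(s) .lambda_profile(config, s))
  mu <- vapply(lam, sum, numeric(1))
  flank_rows <- vector("list", config$n_genes * length(sides))
  truth_rows <- list()
  fi <- 0L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%05d", g)
    gstrand <- sample(c("+", "-"), 1L)
    for (side in sides) {
      codes <- .background_codes(L, config$background_composition,
                                 config$g_run_free)
      n_plants <- stats::rpois(1L, mu[[side]])
      occupied <- matrix(integer(0), ncol = 2L)  # 0-based [start, end)
      for (p in seq_len(n_plants)) {
        placed <- FALSE
        for (try in 1:100) {
          motif <- sample_pqs_instance(config$pattern)
          span <- nchar(motif)
          d <- sample.int(L, 1L, prob = lam[[side]])
          # flank offset (0-based) of the match start
          s0 <- if (side == "upstream") L - d else d - 1L
          if (s0 < 0L || s0 + span > L) next
          if (side == "upstream" && d < span) next
          clear_lo <- s0 - config$clearance
          clear_hi <- s0 + span + config$clearance
          if (nrow(occupied) > 0L &&
              any(occupied[, 1L] < clear_hi & occupied[, 2L] > clear_lo)) {
            next
          }
          on_template <- stats::runif(1L) < config$strand_probability
          embedded <- if (on_template) reverse_complement(motif) else motif
          codes[(s0 + 1L):(s0 + span)] <-
            match(strsplit(embedded, "")[[1L]], c("A", "C", "G", "T"))
          if (s0 >= 1L) codes[s0] <- 4L          # T guard, breaks any run
          if (s0 + span < L) codes[s0 + span + 1L] <- 4L
          occupied <- rbind(occupied, c(s0, s0 + span))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            gene_id = gid,
            anchor = if (side == "upstream") "TSS" else "TES",
            side = side,
            coord = if (side == "upstream") -d else d,
            span = span,
            strand_class = if (on_template) "template" else "non-template",
            motif_seq = motif, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place plant with required clearance after 100 ",
               "attempts; lower lambda0/enrich_fold or raise flank_len")
        }
      }
      fi <- fi + 1L
      flank_rows[[fi]] <- data.frame(
        gene_id = gid,
        anchor = if (side == "upstream") "TSS" else "TES",
        side = side, length = L, gene_strand = gstrand,
        truncated = FALSE, seq = intToUtf8(.CODE_CHARS[codes]),
        stringsAsFactors = FALSE)
    }
  }
  flanks <- do.call(rbind, flank_rows[seq_len(fi)])
  truth <- if (length(truth_rows) > 0L) {
    do.call(rbind, truth_rows)
  } else {
    data.frame(gene_id = character(), anchor = character(),
               side = character(), coord = integer(), span = integer(),
               strand_class = character(), motif_seq = character(),
               stringsAsFactors = FALSE)
  }
  rownames(flanks) <- rownames(truth) <- NULL
  list(flanks = flanks, truth = truth)
}

#' Generate synthetic %qDNA decay datasets
#'
#' Draws replicate datasets from `Y = max * exp(-k * X) + plateau` with
#' `k = ln(2) / d_half` and additive Gaussian noise, clamped to `[0, 100]`.
#'
#' @param max Amplitude, percent.
#' @param d_half Half-decay distance, bp (> 0).
#' @param plateau Plateau, percent.
#' @param distances Distances X, bp.
#' @param noise_sd Gaussian noise standard deviation, percentage points.
#' @param n_replicates Number of replicate datasets.
#' @param seed Integer seed.
#' @return A list of `n_replicates` data frames with columns `x`, `y`.
#' @export
generate_decay_dataset <- function(max = 59, d_half = 489, plateau = 40,
                                   distances = seq(0, 2500, by = 250),
                                   noise_sd = 0, n_replicates = 1L,
                                   seed = 1L) {
  if (d_half <= 0) stop("d_half must be > 0")
  set.seed(seed)
  k <- log(2) / d_half
  mu <- max * exp(-k * distances) + plateau
  lapply(seq_len(n_replicates), function(i) {
    y <- mu + stats::rnorm(length(distances), 0, noise_sd)
    data.frame(x = distances, y = pmin(pmax(y, 0), 100))
  })
}
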