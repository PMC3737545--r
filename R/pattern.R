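#' Define a PQS motif grammar
#'
#' A putative G-quadruplex sequence (PQS) is modelled as at least
#' `min_tracts` runs ("tracts") of at least `min_tract_len` consecutive
#' guanines, separated by loops of `loop_min`--`loop_max` arbitrary
#' nucleotides. Loops may themselves contain G. The defaults encode the
#' classical motif G>=3(N1-7 G>=3)>=3, i.e. the backtracking pattern
#' `G{3,}(.{1,7}?G{3,}){3,}`: four or more G-tracts of three or more
#' guanines with 1--7 nt loops.
#'
#' `exact_tract_len` / `exact_loop_len` restrict the grammar to the compact
#' subclass in which every tract has exactly that many guanines and every
#' loop exactly that many nucleotides (e.g. the G3 / 1-nt-loop subclass,
#' `exact_tract_len = 3`, `exact_loop_len = 1`).
#'
#' @param min_tract_len Minimum guanines per tract (nt, default 3).
#' @param loop_min,loop_max Loop length bounds (nt, defaults 1 and 7).
#' @param min_tracts Minimum number of G-tracts (default 4).
#' @param exact_tract_len Optional: every tract must have exactly this many
#'   guanines. Must be `>= min_tract_len` when set.
#' @param exact_loop_len Optional: every loop must have exactly this length.
#'   Must lie within `[loop_min, loop_max]` when set.
#' @return An object of class `pqs_pattern`.
#' @examples
#' pqs_pattern()                                   # G>=3(N1-7 G>=3)>=3
#' pqs_pattern(exact_tract_len = 3, exact_loop_len = 1)
#' @export
pqs_pattern <- function(min_tract_len = 3L, loop_min = 1L, loop_max = 7L,
                        min_tracts = 4L, exact_tract_len = NULL,
                        exact_loop_len = NULL) {
  min_tract_len <- as.integer(min_tract_len)
  loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max)
  min_tracts <- as.integer(min_tracts)
  if (min_tract_len < 1L) stop("min_tract_len must be >= 1")
  if (loop_min < 0L || loop_min > loop_max) {
    stop("loop bounds must satisfy 0 <= loop_min <= loop_max")
  }
  if (min_tracts < 2L) stop("min_tracts must be >= 2")
  if (!is.null(exact_tract_len)) {
    exact_tract_len <- as.integer(exact_tract_len)
    if (exact_tract_len < min_tract_len) {
      stop("exact_tract_len must be >= min_tract_len")
    }
  }
  if (!is.null(exact_loop_len)) {
    exact_loop_len <- as.integer(exact_loop_len)
    if (exact_loop_len < loop_min || exact_loop_len > loop_max) {
      stop("exact_loop_len must lie within [loop_min, loop_max]")
    }
  }
  structure(
    list(min_tract_len = min_tract_len, loop_min = loop_min,
         loop_max = loop_max, min_tracts = min_tracts,
         exact_tract_len = exact_tract_len, exact_loop_len = exact_loop_len),
    class = "pqs_pattern"
  )
}

#' @export
print.pqs_pattern <- function(x, ...) {
  cat("PQS pattern:", pqs_regex(x), "\n")
  invisible(x)
}

#' Render a PQS grammar as a PCRE regular expression
#'
#' Tract quantifiers are greedy, loop quantifiers lazy and the repeat count
#' greedy -- the standard backtracking semantics of the published pattern.
#' With exact tract/loop lengths the quantifiers become fixed counts.
#'
#' @param pattern A [pqs_pattern()].
#' @param anchored If `TRUE`, anchor with `^...$` so the regex only accepts a
#'   string whose full extent parses under the grammar (used for subclass
#'   membership tests).
#' @return A single regex string for use with `perl = TRUE`.
#' @export
pqs_regex <- function(pattern = pqs_pattern(), anchored = FALSE) {
  stopifnot(inherits(pattern, "pqs_pattern"))
  tract <- if (is.null(pattern$exact_tract_len)) {
    sprintf("G{%d,}", pattern$min_tract_len)
  } else {
    sprintf("G{%d}", pattern$exact_tract_len)
  }
  loop <- if (is.null(pattern$exact_loop_len)) {
    sprintf(".{%d,%d}?", pattern$loop_min, pattern$loop_max)
  } else {
    sprintf(".{%d}", pattern$exact_loop_len)
  }
  rx <- sprintf("%s(%s%s){%d,}", tract, loop, tract, pattern$min_tracts - 1L)
  if (anchored) paste0("^", rx, "$") else rx
}

# Effective tract/loop bounds after applying exact_* restrictions.
.pattern_bounds <- function(pattern) {
  if (is.null(pattern$exact_tract_len)) {
    tmin <- pattern$min_tract_len; tmax <- Inf
  } else {
    tmin <- tmax <- pattern$exact_tract_len
  }
  if (is.null(pattern$exact_loop_len)) {
    lmin <- pattern$loop_min; lmax <- pattern$loop_max
  } else {
    lmin <- lmax <- pattern$exact_loop_len
  }
  list(tmin = tmin, tmax = tmax, lmin = lmin, lmax = lmax,
       min_tracts = pattern$min_tracts)
}
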