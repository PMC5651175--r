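#' @keywords internal
"_PACKAGE"

## Shared helpers: argument checking, chromosome-label normalization and the
## deterministic seed substreams used by the cohort simulator and the
## permutation machinery.

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Normalize a chromosome label
#'
#' Strips a leading `"chr"` prefix (any case) so that mixed-source inputs
#' (`"chr17"` vs `"17"`) agree on one internal vocabulary.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector without the `"chr"` prefix.
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Derive a reproducible seed substream
#'
#' Maps a master seed and a stream label to an integer seed below 2^31, so
#' that independent pipeline stages (copy number, methylation, mutations,
#' expression, per-pathway permutations) consume independent, stable random
#' streams: adding one stage never perturbs another's draws.
#'
#' @param seed master integer seed.
#' @param label character stream label (e.g. a platform or pathway name).
#' @return a single integer suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps the result a valid R integer
  h <- as.double(seed) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

## checks a numeric scalar in a closed interval
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_validation("'%s' must be a number in [%g, %g]", name, lo, hi)
  invisible(x)
}

## total interval length of intersections of [s, e) rows with [a, b)
interval_overlap <- function(start, end, a, b) {
  sum(pmax(0, pmin(end, b) - pmax(start, a)))
}
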