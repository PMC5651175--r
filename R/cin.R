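## Arm-level somatic copy-number alteration calling and chromosomal-
## instability (SCNA-high / SCNA-low) classification.
##
## An arm is called altered when at least 80% of its length is covered by
## segments whose relative log2 copy ratio departs from zero by at least 0.15;
## a sample is SCNA-high when it carries at least one arm-level loss other
## than 18p, 18q, 21p or 21q, which recur in both quiet and unstable genomes
## and therefore do not discriminate.

#' Built-in chromosome-arm table (approximate GRCh37 boundaries)
#'
#' Arms for chromosomes 1-22 and X, split at approximate centromere
#' midpoints. Coordinates are 0-based half-open and intentionally coarse
#' (megabase-scale accuracy): arm-level calls integrate over tens of
#' megabases and are insensitive to the exact centromere base. The
#' acrocentric p-arms (13p, 14p, 15p, 21p, 22p) are marked non-callable.
#'
#' @return data.frame with columns `chrom, start, end, arm, callable`.
#' @export
default_arm_table <- function() {
  len <- c("1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
           "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
           "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
           "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
           "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
           "21" = 48129895, "22" = 51304566, "X" = 155270560)
  cen <- c("1" = 125e6, "2" = 93.3e6, "3" = 91e6, "4" = 50.4e6, "5" = 48.4e6,
           "6" = 61e6, "7" = 59.9e6, "8" = 45.6e6, "9" = 49e6, "10" = 40.2e6,
           "11" = 53.7e6, "12" = 35.8e6, "13" = 17.9e6, "14" = 17.6e6,
           "15" = 19e6, "16" = 36.6e6, "17" = 24e6, "18" = 17.2e6,
           "19" = 26.5e6, "20" = 27.5e6, "21" = 13.2e6, "22" = 14.7e6,
           "X" = 60.6e6)
  acro <- c("13p", "14p", "15p", "21p", "22p")
  chroms <- names(len)
  arms <- data.frame(
    chrom = rep(chroms, each = 2L),
    start = as.double(rbind(0, cen[chroms])),
    end = as.double(rbind(cen[chroms], len[chroms])),
    arm = paste0(rep(chroms, each = 2L), c("p", "q")),
    stringsAsFactors = FALSE)
  arms$callable <- !(arms$arm %in% acro)
  validate_arm_table(arms)
}

#' Fractions of an arm covered by gained / lost segments
#'
#' Intersects a sample's segments with one arm interval and returns the
#' fraction of the arm length (base-pair weighted) lying under segments at or
#' beyond the gain / loss log2 thresholds. Uncovered bases count toward
#' neither fraction; the denominator is always the full arm length.
#'
#' @param profile an [scn_profile()].
#' @param arm one row of an arm table (list or single-row data.frame with
#'   `chrom`, `start`, `end`).
#' @param gain_threshold,loss_threshold positive log2-ratio magnitudes
#'   (default 0.15): a segment counts as gained at `log2 >= gain_threshold`
#'   and lost at `log2 <= -loss_threshold` (inclusive).
#' @param probe_weighted if `TRUE`, weight by `n_probes` (prorated by
#'   overlap) instead of base pairs; requires probe counts on all segments.
#' @return named numeric vector `c(fraction_gain =, fraction_loss =)`.
#' @export
project_segments_to_arm <- function(profile, arm, gain_threshold = 0.15,
                                    loss_threshold = 0.15,
                                    probe_weighted = FALSE) {
  if (gain_threshold <= 0 || loss_threshold <= 0)
    stop_validation("log2 thresholds must be positive")
  arm_len <- arm$end - arm$start
  if (arm_len <= 0) stop_validation("arm %s has non-positive length",
                                    as.character(arm$arm %||% "?"))
  s <- profile$segments
  s <- s[normalize_chrom(s$chrom) == normalize_chrom(arm$chrom), , drop = FALSE]
  ov <- pmax(0, pmin(s$end, arm$end) - pmax(s$start, arm$start))
  if (probe_weighted) {
    if (any(is.na(s$n_probes)))
      stop_validation("probe weighting requested but n_probes missing")
    w <- s$n_probes * ov / (s$end - s$start)  # probes prorated by overlap
    denom <- sum(w)
    if (denom <= 0) return(c(fraction_gain = 0, fraction_loss = 0))
    c(fraction_gain = sum(w[s$log2_ratio >= gain_threshold]) / denom,
      fraction_loss = sum(w[s$log2_ratio <= -loss_threshold]) / denom)
  } else {
    c(fraction_gain = sum(ov[s$log2_ratio >= gain_threshold]) / arm_len,
      fraction_loss = sum(ov[s$log2_ratio <= -loss_threshold]) / arm_len)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call one arm altered, neutral or not callable
#'
#' @param fractions output of [project_segments_to_arm()].
#' @param altered_fraction_threshold minimum fraction of the arm that must be
#'   altered, inclusive (default 0.80, "at least 80%").
#' @param callable is the arm callable (acrocentric p-arms are not)?
#' @return character scalar: `"gain"`, `"loss"`, `"neutral"` or
#'   `"not_callable"`.
#' @export
call_arm <- function(fractions, altered_fraction_threshold = 0.80,
                     callable = TRUE) {
  check_fraction(altered_fraction_threshold, "altered_fraction_threshold")
  if (!callable) return("not_callable")
  g <- fractions[["fraction_gain"]] >= altered_fraction_threshold
  l <- fractions[["fraction_loss"]] >= altered_fraction_threshold
  if (g && l)
    stop_validation("both gain and loss pass the %.2f threshold (threshold <= 0.5?)",
                    altered_fraction_threshold)
  if (l) "loss" else if (g) "gain" else "neutral"
}

#' Classify one sample SCNA-high or SCNA-low
#'
#' SCNA-high (chromosomal instability) requires at least one arm-level loss
#' on an arm outside the exclusion set; gains never qualify. Losses on
#' excluded arms are recorded separately.
#'
#' @param arm_calls named character vector of per-arm calls (names = arm
#'   names, values from [call_arm()]).
#' @param excluded_arms arms whose losses do not qualify; default
#'   `c("18p","18q","21p","21q")` ("18p, 18q or 21", with bare "21" read as
#'   the whole chromosome).
#' @return list with `label` (`"SCNA_high"`/`"SCNA_low"`),
#'   `qualifying_arm_losses`, `excluded_arm_losses`.
#' @export
classify_cin <- function(arm_calls,
                         excluded_arms = c("18p", "18q", "21p", "21q")) {
  if (anyDuplicated(names(arm_calls))) stop_validation("duplicate arm names")
  losses <- names(arm_calls)[arm_calls == "loss"]
  qual <- setdiff(losses, excluded_arms)
  list(label = if (length(qual)) "SCNA_high" else "SCNA_low",
       qualifying_arm_losses = qual,
       excluded_arm_losses = intersect(losses, excluded_arms))
}

#' Arm calls and CIN classification for a cohort
#'
#' @param profiles named list of [scn_profile()] objects.
#' @param arm_table arm table (default [default_arm_table()]).
#' @param gain_threshold,loss_threshold,altered_fraction_threshold see
#'   [project_segments_to_arm()] and [call_arm()].
#' @param excluded_arms see [classify_cin()].
#' @param probe_weighted see [project_segments_to_arm()].
#' @return list with `cin_calls` (data.frame: sample, label,
#'   qualifying_losses, excluded_losses), `arm_calls` (samples x arms
#'   character matrix) and `arm_frequencies` (data.frame: arm, freq_gain,
#'   freq_loss over callable arms).
#' @export
cohort_cin <- function(profiles, arm_table = default_arm_table(),
                       gain_threshold = 0.15, loss_threshold = 0.15,
                       altered_fraction_threshold = 0.80,
                       excluded_arms = c("18p", "18q", "21p", "21q"),
                       probe_weighted = FALSE) {
  arm_table <- validate_arm_table(arm_table)
  samples <- vapply(profiles, `[[`, character(1L), "sample_id")
  calls <- matrix(NA_character_, nrow = length(profiles), ncol = nrow(arm_table),
                  dimnames = list(samples, arm_table$arm))
  for (i in seq_along(profiles)) {
    for (j in seq_len(nrow(arm_table))) {
      fr <- project_segments_to_arm(profiles[[i]], arm_table[j, ],
                                    gain_threshold, loss_threshold,
                                    probe_weighted)
      calls[i, j] <- call_arm(fr, altered_fraction_threshold,
                              callable = arm_table$callable[j])
    }
  }
  cin <- lapply(seq_along(profiles), function(i)
    classify_cin(calls[i, ], excluded_arms))
  cin_calls <- data.frame(
    sample = samples,
    label = vapply(cin, `[[`, character(1L), "label"),
    qualifying_losses = vapply(cin, function(x)
      paste(x$qualifying_arm_losses, collapse = ","), character(1L)),
    excluded_losses = vapply(cin, function(x)
      paste(x$excluded_arm_losses, collapse = ","), character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  callable <- arm_table$arm[arm_table$callable]
  freq <- data.frame(
    arm = callable,
    freq_gain = colMeans(calls[, callable, drop = FALSE] == "gain"),
    freq_loss = colMeans(calls[, callable, drop = FALSE] == "loss"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(cin_calls = cin_calls, arm_calls = calls, arm_frequencies = freq)
}
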