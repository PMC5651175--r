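## Independent brute-force oracles used to validate the implementation.
## These deliberately share no code with the package's own algorithms.

## Arm-fraction oracle: rasterize the arm at fixed resolution and count
## altered bases bin by bin.
raster_arm_fractions <- function(profile, arm, gain_threshold = 0.15,
                                 loss_threshold = 0.15, resolution = 1e4) {
  grid <- seq(arm$start, arm$end - 1, by = resolution)
  seg <- profile$segments[profile$segments$chrom == arm$chrom, , drop = FALSE]
  state <- rep(NA_real_, length(grid))
  for (i in seq_len(nrow(seg)))
    state[grid >= seg$start[i] & grid < seg$end[i]] <- seg$log2_ratio[i]
  c(fraction_gain = mean(!is.na(state) & state >= gain_threshold),
    fraction_loss = mean(!is.na(state) & state <= -loss_threshold))
}

## Single-pass per-variant re-implementation of the full filter battery,
## testing every rule independently of the package's vectorized code.
brute_filter_one <- function(v, germ, pon) {
  reasons <- character(0)
  gm <- nrow(germ) > 0 && any(germ$chrom == v$chrom & germ$pos == v$pos &
                                (is.na(germ$alt) | germ$alt == v$alt))
  if (gm) reasons <- c(reasons, "germline_1000G")
  if (v$n_ref_count < 8) reasons <- c(reasons, "normal_low_ref_coverage")
  if (v$n_alt_count > 1) reasons <- c(reasons, "normal_alt_reads")
  nd <- v$n_ref_count + v$n_alt_count
  if (nd > 0 && v$n_alt_count / nd > 0.01) reasons <- c(reasons, "normal_vaf")
  if (v$t_alt_count < 2) reasons <- c(reasons, "tumor_alt_reads")
  td <- v$t_ref_count + v$t_alt_count
  if (td == 0 || v$t_alt_count / td < 0.05) reasons <- c(reasons, "tumor_vaf")
  if (!is.na(v$alt_f1r2) && !is.na(v$alt_f2r1)) {
    tot <- v$alt_f1r2 + v$alt_f2r1
    art <- if (v$ref == "C" && v$alt == "A") v$alt_f2r1
    else if (v$ref == "G" && v$alt == "T") v$alt_f1r2 else NA
    if (!is.na(art) && tot >= 3 && art / tot >= 0.9)
      reasons <- c(reasons, "oxog_orientation")
  }
  pm <- nrow(pon) > 0 && any(pon$chrom == v$chrom & pon$pos == v$pos &
                               (is.na(pon$alt) | pon$alt == v$alt))
  if (pm) reasons <- c(reasons, "panel_of_normals")
  reasons
}

## Greedy Ward agglomeration recomputing the merge cost from cluster
## centroids at every step (the ward.D2 height is
## sqrt(2 |A||B| / (|A|+|B|)) * ||centroid_A - centroid_B|| for Euclidean
## input).
ward_oracle_heights <- function(X) {
  ## X: samples x features
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  cost <- function(A, B) {
    ca <- colMeans(X[A, , drop = FALSE])
    cb <- colMeans(X[B, , drop = FALSE])
    sqrt(2 * length(A) * length(B) / (length(A) + length(B))) *
      sqrt(sum((ca - cb)^2))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1L):length(clusters)) {
        d <- cost(clusters[[i]], clusters[[j]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## random 2x2 tables for Fisher cross-checks
random_2x2 <- function(n_total_max) {
  repeat {
    cells <- as.vector(stats::rmultinom(1L, sample.int(n_total_max, 1L),
                                        rep(0.25, 4)))
    if (sum(cells) > 0) return(cells)
  }
}

## minimal variant record builder for filter tests
variant_row <- function(sample = "S1", chrom = "1", pos = 100, ref = "C",
                        alt = "T", t_ref = 50, t_alt = 10, n_ref = 60,
                        n_alt = 0, caller = "A", context = NA_character_,
                        f1r2 = NA_integer_, f2r1 = NA_integer_) {
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref, alt = alt,
             t_ref_count = t_ref, t_alt_count = t_alt,
             n_ref_count = n_ref, n_alt_count = n_alt, caller = caller,
             context = context, alt_f1r2 = f1r2, alt_f2r1 = f2r1,
             stringsAsFactors = FALSE)
}

## random variant tables spanning all the filter decision boundaries
random_variants <- function(n, seed) {
  set.seed(seed)
  refs <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
  t_alt <- sample(0:12, n, replace = TRUE)
  has_orient <- stats::runif(n) < 0.5
  f1r2 <- ifelse(has_orient, vapply(t_alt, function(a)
    sample(0:a, 1L), integer(1L)), NA_integer_)
  data.frame(sample = sample(paste0("S", 1:5), n, replace = TRUE),
             chrom = as.character(sample(1:3, n, replace = TRUE)),
             pos = sample.int(1e6, n),  # unique keys: merge conflicts not under test here
             ref = refs, alt = alts,
             t_ref_count = sample(0:80, n, replace = TRUE),
             t_alt_count = t_alt,
             n_ref_count = sample(0:30, n, replace = TRUE),
             n_alt_count = sample(0:3, n, replace = TRUE),
             caller = NA_character_, context = NA_character_,
             alt_f1r2 = f1r2,
             alt_f2r1 = ifelse(has_orient, t_alt - f1r2, NA_integer_),
             stringsAsFactors = FALSE)
}
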