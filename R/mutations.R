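## Ensemble merging of per-caller somatic SNV call sets and the fixed filter
## battery applied to the merged set: 1000 Genomes germline-site removal,
## normal-sample coverage / alt-read / allele-fraction rules, tumour-sample
## minimum support rules, 8-oxoguanine orientation-bias removal and a
## panel-of-normals site filter. Filters accumulate reasons rather than
## short-circuit, so a rejects table explains every dropped variant.

.filter_reasons <- c("germline_1000G", "normal_low_ref_coverage",
                     "normal_alt_reads", "normal_vaf",
                     "tumor_alt_reads", "tumor_vaf",
                     "oxog_orientation", "panel_of_normals")

.variant_key <- function(v) {
  paste(v$sample, v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Merge per-caller somatic variant call sets
#'
#' Variants are keyed by (sample, chromosome, position, ref, alt). Records
#' reported by several callers collapse to one row whose read counts come
#' from the maximum-total-depth record (tumour ref+alt); the contributing
#' callers are kept as a comma-separated provenance column.
#'
#' @param call_sets list of variant data.frames in the [read_maf()] layout,
#'   one per caller (each may also carry its caller label in the `caller`
#'   column; a list name overrides a missing label).
#' @param min_callers drop variants reported by fewer than this many callers
#'   (default 1, i.e. plain union).
#' @return merged data.frame with extra columns `callers` and `n_callers`.
#' @export
merge_call_sets <- function(call_sets, min_callers = 1L) {
  stopifnot(length(call_sets) >= 1L)
  labels <- names(call_sets)
  if (is.null(labels)) labels <- rep(NA_character_, length(call_sets))
  all <- do.call(rbind, lapply(seq_along(call_sets), function(i) {
    v <- call_sets[[i]]
    if (!is.na(labels[i]) && nzchar(labels[i])) v$caller <- labels[i]
    v$caller[is.na(v$caller)] <- paste0("caller", i)
    v
  }))
  key <- paste(all$sample, all$chrom, all$pos, sep = ":")
  ref_by_key <- tapply(all$ref, key, function(r) length(unique(r)))
  if (any(ref_by_key > 1L))
    stop_validation("conflicting reference alleles at %s",
                    names(ref_by_key)[ref_by_key > 1L][1L])
  key <- .variant_key(all)
  merged <- do.call(rbind, lapply(split(all, key), function(g) {
    depth <- g$t_ref_count + g$t_alt_count
    best <- g[which.max(depth), , drop = FALSE]
    best$callers <- paste(sort(unique(g$caller)), collapse = ",")
    best$n_callers <- length(unique(g$caller))
    best
  }))
  merged <- merged[merged$n_callers >= min_callers, , drop = FALSE]
  merged <- merged[order(merged$sample, merged$chrom, merged$pos, merged$alt), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Normal- and tumour-sample read-count filters
#'
#' Applies, per variant, the removal rules: in the matched normal, fewer than
#' 8 reference-supporting reads (`normal_low_ref_coverage`), more than one
#' variant-supporting read (`normal_alt_reads`), or a variant allele fraction
#' above 1% (`normal_vaf`); in the tumour, fewer than 2 supporting reads
#' (`tumor_alt_reads`) or a variant allele fraction below 5% (`tumor_vaf`).
#' VAF denominators are ref+alt counts. A normal sample with zero total depth
#' fails coverage.
#'
#' @param variants variant data.frame ([read_maf()] layout).
#' @param min_normal_ref_coverage default 8 (strict `<` removal).
#' @param max_normal_alt_reads default 1 (strict `>` removal).
#' @param max_normal_vaf default 0.01 (strict `>` removal).
#' @param min_tumor_alt_reads default 2 (inclusive minimum).
#' @param min_tumor_vaf default 0.05 (inclusive minimum).
#' @param normal_rule `"or"` (default): a variant is removed when either the
#'   normal alt-read or the normal VAF rule trips; `"and"` requires both.
#' @return list of character vectors, one per variant, holding the reasons
#'   that fired (empty = passes).
#' @export
read_count_filter_reasons <- function(variants,
                                      min_normal_ref_coverage = 8L,
                                      max_normal_alt_reads = 1L,
                                      max_normal_vaf = 0.01,
                                      min_tumor_alt_reads = 2L,
                                      min_tumor_vaf = 0.05,
                                      normal_rule = c("or", "and")) {
  normal_rule <- match.arg(normal_rule)
  n_vaf <- with(variants, ifelse(n_ref_count + n_alt_count > 0,
                                 n_alt_count / (n_ref_count + n_alt_count), 0))
  t_vaf <- with(variants, ifelse(t_ref_count + t_alt_count > 0,
                                 t_alt_count / (t_ref_count + t_alt_count), 0))
  low_cov <- variants$n_ref_count < min_normal_ref_coverage
  n_alt <- variants$n_alt_count > max_normal_alt_reads
  n_frac <- n_vaf > max_normal_vaf
  if (normal_rule == "and") {
    both <- n_alt & n_frac
    n_alt <- both
    n_frac <- both
  }
  t_alt <- variants$t_alt_count < min_tumor_alt_reads
  t_frac <- t_vaf < min_tumor_vaf
  lapply(seq_len(nrow(variants)), function(i) c(
    if (low_cov[i]) "normal_low_ref_coverage",
    if (n_alt[i]) "normal_alt_reads",
    if (n_frac[i]) "normal_vaf",
    if (t_alt[i]) "tumor_alt_reads",
    if (t_frac[i]) "tumor_vaf"))
}

#' Read a BED-like blacklist of sites
#'
#' Columns: chromosome, start, end (0-based half-open), optional alt allele.
#' Single-base SNP sites have `end = start + 1`.
#'
#' @param path file path.
#' @return data.frame with columns `chrom, pos, alt` (one row per base; `alt`
#'   `NA` when the list does not constrain the allele).
#' @export
read_site_list <- function(path) {
  d <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop_validation("%s: site list needs >= 3 columns", path)
  starts <- as.double(d[[2L]]); ends <- as.double(d[[3L]])
  alt <- if (ncol(d) >= 4L) as.character(d[[4L]]) else
    rep(NA_character_, nrow(d))
  reps <- ends - starts
  data.frame(chrom = rep(normalize_chrom(d[[1L]]), reps),
             pos = unlist(lapply(seq_len(nrow(d)), function(i)
               seq(starts[i], ends[i] - 1))),
             alt = rep(alt, reps), stringsAsFactors = FALSE)
}

.site_match <- function(variants, sites) {
  if (is.null(sites) || nrow(sites) == 0L) return(rep(FALSE, nrow(variants)))
  constrained <- !is.na(sites$alt)
  hit <- paste(variants$chrom, variants$pos) %in%
    paste(sites$chrom[!constrained], sites$pos[!constrained])
  hit | paste(variants$chrom, variants$pos, variants$alt) %in%
    paste(sites$chrom[constrained], sites$pos[constrained],
          sites$alt[constrained])
}

#' Blacklist-site filter reasons
#'
#' Flags variants at 1000 Genomes germline SNP sites (`germline_1000G`) and
#' at panel-of-normals artifact sites (`panel_of_normals`). Matching is by
#' (chromosome, position) and additionally the alt allele where the site
#' list records one.
#'
#' @param variants variant data.frame.
#' @param germline_sites,pon_sites site data.frames from [read_site_list()]
#'   (or `NULL` to skip).
#' @return list of character reason vectors, one per variant.
#' @export
blacklist_filter_reasons <- function(variants, germline_sites = NULL,
                                     pon_sites = NULL) {
  germ <- .site_match(variants, germline_sites)
  pon <- .site_match(variants, pon_sites)
  lapply(seq_len(nrow(variants)), function(i) c(
    if (germ[i]) "germline_1000G",
    if (pon[i]) "panel_of_normals"))
}

#' 8-oxoguanine orientation-bias filter reasons
#'
#' 8-oxoG damage produces spurious C>A (equivalently G>T) calls supported
#' almost exclusively by one read-pair orientation: F2R1 for C>A, F1R2 for
#' G>T. A variant of that substitution class is flagged when the
#' artifact-consistent orientation holds at least `max_orientation_fraction`
#' of the orientation-counted alt reads and those reads number at least
#' `min_alt_reads`. Other substitution classes, and records without
#' orientation counts, are never flagged.
#'
#' @param variants variant data.frame.
#' @param max_orientation_fraction default 0.9 (inclusive).
#' @param min_alt_reads default 3.
#' @return list of character reason vectors, one per variant.
#' @export
oxog_filter_reasons <- function(variants, max_orientation_fraction = 0.9,
                                min_alt_reads = 3L) {
  f1 <- variants$alt_f1r2
  f2 <- variants$alt_f2r1
  total <- f1 + f2
  is_ca <- variants$ref == "C" & variants$alt == "A"
  is_gt <- variants$ref == "G" & variants$alt == "T"
  artifact <- ifelse(is_ca, f2, ifelse(is_gt, f1, NA_integer_))
  flag <- !is.na(artifact) & !is.na(total) & total >= min_alt_reads &
    artifact / total >= max_orientation_fraction
  lapply(flag, function(f) if (isTRUE(f)) "oxog_orientation" else character(0))
}

#' Merge call sets and apply the full somatic filter battery
#'
#' Composes [merge_call_sets()], [blacklist_filter_reasons()],
#' [read_count_filter_reasons()] and [oxog_filter_reasons()]. Reasons
#' accumulate across filters (evaluation order cannot change the outcome);
#' a variant is kept iff no reason fired.
#'
#' @param call_sets list of per-caller variant data.frames.
#' @param germline_sites,pon_sites optional site lists ([read_site_list()]).
#' @param min_callers see [merge_call_sets()].
#' @param ... threshold overrides passed to [read_count_filter_reasons()] and
#'   [oxog_filter_reasons()] (matched by name).
#' @return list with `kept` (surviving variants), `rejects` (dropped variants
#'   with a `reasons` column), and `decisions` (all merged variants with
#'   `kept` flag and `reasons`).
#' @export
filter_mutations <- function(call_sets, germline_sites = NULL,
                             pon_sites = NULL, min_callers = 1L, ...) {
  merged <- merge_call_sets(call_sets, min_callers = min_callers)
  dots <- list(...)
  take <- function(f) dots[names(dots) %in% names(formals(f))]
  r1 <- blacklist_filter_reasons(merged, germline_sites, pon_sites)
  r2 <- do.call(read_count_filter_reasons,
                c(list(merged), take(read_count_filter_reasons)))
  r3 <- do.call(oxog_filter_reasons,
                c(list(merged), take(oxog_filter_reasons)))
  reasons <- Map(function(a, b, c) intersect(.filter_reasons, c(a, b, c)),
                 r1, r2, r3)
  kept <- lengths(reasons) == 0L
  decisions <- merged
  decisions$kept <- kept
  decisions$reasons <- vapply(reasons, paste, character(1L), collapse = ",")
  list(kept = merged[kept, , drop = FALSE],
       rejects = decisions[!kept, , drop = FALSE],
       decisions = decisions)
}
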