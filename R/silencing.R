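## Per-sample epigenetic-silencing calls from paired promoter-methylation
## beta values and expression, and the exact 2x2 Fisher test used for every
## contingency comparison in the pipeline (subtype enrichment, geography,
## silencing-frequency differences).
##
## The original silencing calls were made by eye from a methylation-versus-
## expression scatterplot; the two-threshold rule implemented here (promoter
## beta at or above `beta_high` AND expression at or below a low quantile of
## the unmethylated samples) is a reproducible operationalization of that
## inverse-association read-out, with every constant exposed.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration under fixed margins, two-sided by the
#' minimum-likelihood convention: the p-value sums the probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' the observed table's (within relative tolerance 1e-7).
#'
#' @param a,b,c,d non-negative integer cell counts: rows are the condition,
#'   columns the outcome (`a` = condition 1 / outcome 1, `b` = condition 1 /
#'   outcome 2, etc.). A 2x2 matrix may be given as `a`.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(10, 31, 3, 46)  # ~0.017
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_validation("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop_validation("empty table")
  row1 <- a + b
  col1 <- a + c
  N <- sum(cells)
  support <- max(0, col1 - (N - row1)):min(row1, col1)
  probs <- stats::dhyper(support, row1, N - row1, col1)
  p_obs <- stats::dhyper(a, row1, N - row1, col1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Call per-sample silencing of one gene
#'
#' A sample is called silenced when its promoter beta value is at least
#' `beta_high` and its expression is at or below the `expr_quantile` quantile
#' of expression among the clearly unmethylated samples (beta below
#' `low_beta_ref`), which anchor the gene's expected expressed level. A gene
#' with fewer than `min_reference` unmethylated samples has no reliable
#' reference and is uncallable (`NULL`).
#'
#' @param beta named numeric vector of promoter beta values per sample.
#' @param expr named numeric vector of expression per sample, on the
#'   log2(RPKM+1) scale.
#' @param beta_high methylated threshold (default 0.3, inclusive).
#' @param low_beta_ref unmethylated reference threshold (default 0.1,
#'   exclusive).
#' @param expr_quantile expression quantile of the reference samples
#'   (default 0.25).
#' @param min_reference minimum unmethylated samples (default 5).
#' @return named logical vector over the samples present in both inputs, or
#'   `NULL` if the gene is uncallable.
#' @export
call_silencing <- function(beta, expr, beta_high = 0.3, low_beta_ref = 0.1,
                           expr_quantile = 0.25, min_reference = 5L) {
  shared <- intersect(names(beta), names(expr))
  if (length(shared) == 0L) stop_validation("no shared samples")
  beta <- beta[shared]
  expr <- expr[shared]
  reference <- which(beta < low_beta_ref)
  if (length(reference) < min_reference) return(NULL)
  expr_cut <- stats::quantile(expr[reference], expr_quantile, names = FALSE)
  setNames(beta >= beta_high & expr <= expr_cut, shared)
}

#' Silencing calls for a cohort of genes
#'
#' When several probes map to one gene's promoter, the probe with the most
#' negative methylation-expression Pearson correlation is used (the probe
#' that best expresses the inverse association).
#'
#' @param beta probes x samples beta-value matrix.
#' @param expr genes x samples expression matrix on the log2(RPKM+1) scale.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @param ... thresholds passed to [call_silencing()].
#' @return list with `calls` (genes x samples logical matrix, callable genes
#'   only), `probe_used` (named character), `uncallable` (character vector of
#'   gene names dropped for lack of an unmethylated reference).
#' @export
call_silencing_matrix <- function(beta, expr, probe_map, ...) {
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  samples <- intersect(colnames(beta), colnames(expr))
  if (length(samples) == 0L) stop_validation("no shared samples")
  genes <- intersect(unique(probe_map$gene), rownames(expr))
  calls <- list()
  probe_used <- character(0)
  uncallable <- character(0)
  for (g in genes) {
    probes <- intersect(probe_map$probe[probe_map$gene == g], rownames(beta))
    if (length(probes) == 0L) next
    if (length(probes) > 1L) {
      r <- vapply(probes, function(p)
        suppressWarnings(stats::cor(beta[p, samples], expr[g, samples])),
        numeric(1L))
      r[is.na(r)] <- 0
      probes <- probes[which.min(r)]
    }
    cl <- call_silencing(beta[probes, samples], expr[g, samples], ...)
    if (is.null(cl)) {
      uncallable <- c(uncallable, g)
      next
    }
    calls[[g]] <- cl
    probe_used[g] <- probes
  }
  if (length(uncallable))
    message(length(uncallable), " gene(s) uncallable (no unmethylated reference)")
  list(calls = if (length(calls)) do.call(rbind, calls) else
         matrix(logical(0), 0, length(samples), dimnames = list(NULL, samples)),
       probe_used = probe_used, uncallable = uncallable)
}

#' Association of per-gene silencing frequency with subtype
#'
#' For each callable gene, builds the 2x2 table of silenced / not-silenced
#' counts in the two subtypes, computes the two-sided exact Fisher p, and
#' flags genes at `p < alpha` as well as at the Bonferroni level
#' `alpha / (number of callable genes)`.
#'
#' @param calls genes x samples logical matrix (from
#'   [call_silencing_matrix()]).
#' @param subtypes per-sample labels (named, or in column order); exactly two
#'   distinct labels must be present among the call-set samples.
#' @param alpha significance level (default 0.01).
#' @return data.frame with columns `gene, n_silenced_A, n_A, n_silenced_B,
#'   n_B, fisher_p, significant, bonferroni_sig`; groups A and B are the two
#'   labels in sort order.
#' @export
silencing_subtype_association <- function(calls, subtypes, alpha = 0.01) {
  if (!is.null(names(subtypes))) subtypes <- subtypes[colnames(calls)]
  labels <- sort(unique(as.character(subtypes)))
  if (length(labels) != 2L)
    stop_validation("exactly 2 subtype labels required, got %d", length(labels))
  in_a <- subtypes == labels[1L]
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  res <- data.frame(
    gene = rownames(calls),
    n_silenced_A = rowSums(calls[, in_a, drop = FALSE]),
    n_A = n_a,
    n_silenced_B = rowSums(calls[, !in_a, drop = FALSE]),
    n_B = n_b,
    stringsAsFactors = FALSE, row.names = NULL)
  res$fisher_p <- vapply(seq_len(nrow(res)), function(i)
    fisher_exact_2x2(res$n_silenced_A[i], n_a - res$n_silenced_A[i],
                     res$n_silenced_B[i], n_b - res$n_silenced_B[i]),
    numeric(1L))
  res$significant <- res$fisher_p < alpha
  res$bonferroni_sig <- res$fisher_p < alpha / max(1L, nrow(res))
  attr(res, "groups") <- labels
  res
}
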