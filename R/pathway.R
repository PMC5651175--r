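## Pathway-level differential expression between sample groups: a gene-level
## Kruskal-Wallis p-value, a Fisher-combined composite pathway score
## S = -2 * sum(log p), and an empirical significance P_s from scoring
## size-matched random gene sets drawn from the same gene pool.

#' Kruskal-Wallis p-value for one gene
#'
#' Rank-based one-way analysis of variance across groups (mid-rank tie
#' correction, chi-square approximation with groups-1 degrees of freedom),
#' delegated to [stats::kruskal.test()]. An all-constant input, where ranks
#' carry no information, returns p = 1 by convention.
#'
#' @param values numeric vector, one value per sample.
#' @param groups group labels, same length.
#' @return two-sided p-value in (0, 1].
#' @export
kruskal_wallis_p <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop_validation("need at least 2 non-empty groups")
  if (any(table(droplevels(groups)) == 0L))
    stop_validation("empty group")
  if (length(unique(values)) == 1L) return(1)
  stats::kruskal.test(values, groups)$p.value
}

#' Gene-level p-value table for a whole expression matrix
#'
#' @param expr genes x samples numeric matrix.
#' @param groups per-sample group labels (named or in column order).
#' @return named numeric vector of p-values, one per gene.
#' @export
gene_pvalues <- function(expr, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  groups <- as.factor(groups)
  if (any(is.na(groups))) stop_validation("group label missing for some sample")
  if (any(table(groups) < 2L))
    stop_validation("every group needs >= 2 samples")
  apply(expr, 1L, kruskal_wallis_p, groups = groups)
}

#' Fisher-combined composite score
#'
#' `S = -2 * sum(log(p))`; with k independent uniform p-values S is
#' chi-square distributed with 2k degrees of freedom. Zero p-values are
#' floored at the smallest positive double with a warning.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return non-negative score S.
#' @export
fisher_combined_score <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop_validation("p-values must be in [0, 1]")
  if (any(pvals == 0)) {
    warning("p-value of 0 floored at machine minimum", call. = FALSE)
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  -2 * sum(log(pvals))
}

#' Empirical significance of a pathway score
#'
#' Draws `n_perm` random gene sets of the pathway's size (uniformly, without
#' replacement) from the gene-level p-value pool, scores each with
#' [fisher_combined_score()], and returns the add-one empirical tail
#' probability `P_s = (1 + #random scores >= S) / (1 + n_perm)`, which can
#' never be exactly 0.
#'
#' @param S observed pathway score.
#' @param gene_p named numeric vector of gene p-values (the pool).
#' @param k pathway size (genes drawn per random set).
#' @param n_perm number of random sets (default 10000).
#' @param seed integer seed for the draw.
#' @return empirical p-value in `[1/(n_perm+1), 1]`.
#' @export
empirical_pathway_p <- function(S, gene_p, k, n_perm = 10000L, seed = 1L) {
  n <- length(gene_p)
  if (k > n) stop_validation("pathway size %d exceeds gene pool %d", k, n)
  if (k < 1L) stop_validation("pathway size must be >= 1")
  neg2lp <- -2 * log(pmax(gene_p, .Machine$double.xmin))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_perm), function(i)
    sum(neg2lp[sample.int(n, k)]) >= S, logical(1L)))
  (1 + exceed) / (1 + n_perm)
}

## save/restore the global RNG state so permutation helpers are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

#' Score every pathway of a collection against two (or more) groups
#'
#' Computes one shared gene-level p-value table, then for each gene set the
#' composite score S over the genes present in the matrix (k = matched size)
#' and its empirical significance from `n_perm` size-matched random sets.
#' Per-pathway seeds are derived from the master seed and the pathway name,
#' so results do not depend on the order of sets in the collection.
#'
#' @param expr genes x samples expression matrix (any monotone scale; the
#'   test is rank-based).
#' @param groups per-sample group labels.
#' @param gene_sets named list of gene vectors (from [read_gmt()]).
#' @param n_perm permutations per pathway (default 10000).
#' @param seed master seed.
#' @return data.frame with columns `pathway, k, S, P_s, n_perm`; pathways
#'   with no matched genes get `NA` scores and a warning.
#' @export
score_all_pathways <- function(expr, groups, gene_sets, n_perm = 10000L,
                               seed = 1L) {
  gene_p <- gene_pvalues(expr, groups)
  res <- lapply(names(gene_sets), function(nm) {
    genes <- intersect(gene_sets[[nm]], names(gene_p))
    if (length(genes) == 0L) {
      warning(sprintf("pathway %s: no genes matched to the matrix", nm),
              call. = FALSE)
      return(data.frame(pathway = nm, k = 0L, S = NA_real_, P_s = NA_real_,
                        n_perm = n_perm, stringsAsFactors = FALSE))
    }
    S <- fisher_combined_score(gene_p[genes])
    P_s <- empirical_pathway_p(S, gene_p, length(genes), n_perm,
                               seed = derive_seed(seed, nm))
    data.frame(pathway = nm, k = length(genes), S = S, P_s = P_s,
               n_perm = n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
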