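## Mutational-signature machinery: 96-trinucleotide-context catalogs
## (pyrimidine-strand convention) built from merged somatic SNVs, signature
## extraction by automatic-relevance-determination Bayesian NMF on the
## generalized Kullback-Leibler objective, per-sample exposure fractions and
## rank-based group comparisons of those fractions.

.bases <- c("A", "C", "G", "T")
.sub_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context bins
#'
#' Pyrimidine-strand convention: 6 substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G) times 16 flanking-base pairs, named like `"A[C>A]A"`,
#' ordered by class, then 5' base, then 3' base.
#'
#' @return character vector of 96 bin names.
#' @export
context_bins <- function() {
  unlist(lapply(.sub_classes, function(s)
    as.vector(t(outer(.bases, .bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, NULL), function(x)
           paste(rev(x), collapse = ""), character(1L)))
}

#' Bin a set of SNVs into the 96-context catalog
#'
#' Purine-reference mutations are reverse-complemented onto the pyrimidine
#' strand (a G>T call in context TGT becomes bin `A[C>A]A`). Records that are
#' not single-base substitutions, lack a context, carry a context whose
#' middle base disagrees with the reference allele, or contain non-ACGT
#' characters are excluded and tallied.
#'
#' @param variants variant data.frame ([read_maf()] layout) with a `context`
#'   column of 3-mers centred on the reference base.
#' @return 96 x samples integer matrix (rownames = [context_bins()]) with a
#'   `"rejected"` attribute: a named count of excluded records by reason
#'   (`not_snv`, `no_context`, `bad_context`).
#' @export
build_catalog <- function(variants) {
  bins <- context_bins()
  samples <- unique(variants$sample)
  catalog <- matrix(0L, length(bins), length(samples),
                    dimnames = list(bins, samples))
  is_base <- function(x) x %in% .bases
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    is_base(variants$ref) & is_base(variants$alt)
  has_ctx <- !is.na(variants$context) & nchar(variants$context) == 3L &
    !grepl("[^ACGT]", variants$context)
  mid_ok <- substr(variants$context, 2L, 2L) == variants$ref
  ok <- snv & has_ctx & mid_ok
  rejected <- c(not_snv = sum(!snv),
                no_context = sum(snv & !has_ctx),
                bad_context = sum(snv & has_ctx & !mid_ok))
  v <- variants[ok, , drop = FALSE]
  purine <- v$ref %in% c("A", "G")
  ref <- ifelse(purine, chartr("AG", "TC", v$ref), v$ref)
  alt <- ifelse(purine, chartr("ACGT", "TGCA", v$alt), v$alt)
  ctx <- v$context
  ctx[purine] <- .revcomp(ctx[purine])
  bin <- paste0(substr(ctx, 1L, 1L), "[", ref, ">", alt, "]",
                substr(ctx, 3L, 3L))
  tab <- table(factor(bin, levels = bins), factor(v$sample, levels = samples))
  catalog[] <- as.integer(tab)
  attr(catalog, "rejected") <- rejected
  catalog
}

#' APOBEC-signature context bins
#'
#' The TpCpW bins characteristic of APOBEC cytidine-deaminase activity:
#' `T[C>T]A`, `T[C>T]T`, `T[C>G]A`, `T[C>G]T`.
#' @return character vector of 4 bin names.
#' @export
apobec_bins <- function() {
  c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")
}

#' Per-sample fraction of mutations in a set of context bins
#'
#' Simple catalog summary used, e.g., for C>A fractions (smoking-associated),
#' APOBEC TpCpW fractions, or A>C-at-ApA transversions (pyrimidine-strand
#' T>G bins with a T flank).
#'
#' @param catalog 96 x samples matrix from [build_catalog()].
#' @param bins character vector of bin names, or a substitution class like
#'   `"C>A"` (selecting all 16 of its bins).
#' @return named numeric vector: per-sample fraction of counted mutations in
#'   `bins` (`NaN` for zero-mutation samples).
#' @export
context_fraction <- function(catalog, bins) {
  if (length(bins) == 1L && bins %in% .sub_classes)
    bins <- grep(bins, rownames(catalog), fixed = TRUE, value = TRUE)
  if (!all(bins %in% rownames(catalog)))
    stop_validation("unknown context bin(s)")
  colSums(catalog[bins, , drop = FALSE]) / colSums(catalog)
}

## penalized objective: generalized KL divergence + exponential-prior terms
.ard_objective <- function(V, W, H, lambda, b, shape_total) {
  WH <- W %*% H
  WH <- pmax(WH, .Machine$double.xmin)
  kl <- sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
  kl + sum((colSums(W) + rowSums(H) + b) / lambda) +
    shape_total * sum(log(lambda))
}

#' Mutational-signature extraction by ARD Bayesian NMF
#'
#' Factorizes a 96 x samples catalog `V ~ W H` under the generalized
#' Kullback-Leibler objective with exponential priors on the columns of `W`
#' and rows of `H`. Each candidate signature `k` owns one relevance scale
#' `lambda_k` shared by its `W` column and `H` row; the maximum-a-posteriori
#' updates alternate multiplicative updates of `W` and `H` with the
#' closed-form update of `lambda`, so the penalized objective never
#' increases. Signatures whose mass collapses are pruned after convergence
#' (automatic relevance determination selects the rank); the best of
#' `n_restarts` random restarts by final objective is returned.
#'
#' @param catalog 96 x samples non-negative matrix ([build_catalog()]).
#' @param K_max maximum candidate signatures (default 20).
#' @param a shape hyperparameter of the inverse-gamma hyperprior on the
#'   relevance scales (default 10; larger drives harder pruning).
#' @param b rate hyperparameter (default 1; sets the floor a dead
#'   signature's scale collapses to).
#' @param tol relative objective-change convergence tolerance (default 1e-9).
#' @param max_iter maximum iterations per restart (default 2000).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param prune_fraction a signature is pruned when it explains less than
#'   this fraction of the reconstructed mutation mass (default 0.01).
#' @param refit_iter after pruning, the surviving factors are refit without
#'   the priors at fixed rank for up to this many plain KL multiplicative
#'   updates (default 1000; 0 disables), removing the shrinkage the
#'   exponential priors impose on profiles and exposures.
#' @return list of class `"signature_decomposition"`: `signatures` (K x 96,
#'   rows on the probability simplex), `exposures` (samples x K, counts
#'   scale), `K`, `lambda`, `objective` (final), `objective_trace` (ARD
#'   phase), `refit_trace` (KL refit phase), `converged`, `seed`.
#' @export
ard_nmf <- function(catalog, K_max = 20L, a = 10, b = 1, tol = 1e-9,
                    max_iter = 2000L, n_restarts = 10L, seed = 1L,
                    prune_fraction = 0.01, refit_iter = 1000L) {
  V <- unclass(catalog)
  attr(V, "rejected") <- NULL
  storage.mode(V) <- "double"
  if (ncol(V) < 2L) stop_validation("need at least 2 samples")
  if (sum(V) == 0) stop_validation("all-zero catalog")
  F <- nrow(V)
  N <- ncol(V)
  shape_total <- F + N + a + 1
  eps <- 1e-50

  run_once <- function(restart_seed) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(restart_seed)
    scale0 <- sqrt(mean(V) / K_max)
    W <- matrix(stats::runif(F * K_max, 0.5, 1.5) * scale0, F, K_max)
    H <- matrix(stats::runif(K_max * N, 0.5, 1.5) * scale0, K_max, N)
    lambda <- (colSums(W) + rowSums(H) + b) / shape_total
    trace <- .ard_objective(V, W, H, lambda, b, shape_total)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) /
        (matrix(rowSums(H), F, K_max, byrow = TRUE) +
           matrix(1 / lambda, F, K_max, byrow = TRUE) + eps)
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) /
        (matrix(colSums(W), K_max, N) + matrix(1 / lambda, K_max, N) + eps)
      lambda <- (colSums(W) + rowSums(H) + b) / shape_total
      obj <- .ard_objective(V, W, H, lambda, b, shape_total)
      trace <- c(trace, obj)
      prev <- trace[length(trace) - 1L]
      if (abs(prev - obj) <= tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
    list(W = W, H = H, lambda = lambda, trace = trace, converged = converged)
  }

  fits <- lapply(seq_len(n_restarts), function(r)
    run_once(derive_seed(seed, paste0("ard_nmf_restart_", r))))
  best <- fits[[which.min(vapply(fits, function(f)
    f$trace[length(f$trace)], numeric(1L)))]]
  if (!best$converged)
    warning("ARD-NMF did not converge within max_iter", call. = FALSE)

  mass <- colSums(best$W) * rowSums(best$H)  # mutation mass per signature
  keep <- which(mass / sum(mass) >= prune_fraction)
  if (length(keep) == 0L) keep <- which.max(mass)
  keep <- keep[order(mass[keep], decreasing = TRUE)]
  W <- best$W[, keep, drop = FALSE]
  H <- best$H[keep, , drop = FALSE]

  ## prune-then-refit: with the rank fixed, a short unpenalized KL refit
  ## removes the shrinkage the exponential priors imposed on W and H
  refit_trace <- numeric(0)
  if (refit_iter > 0L && length(keep) >= 1L) {
    Kk <- ncol(W)
    kl_obj <- function(W, H) {
      WH <- pmax(W %*% H, .Machine$double.xmin)
      sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
    }
    refit_trace <- kl_obj(W, H)
    for (it in seq_len(refit_iter)) {
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) /
        (matrix(rowSums(H), F, Kk, byrow = TRUE) + eps)
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / (matrix(colSums(W), Kk, N) + eps)
      obj <- kl_obj(W, H)
      refit_trace <- c(refit_trace, obj)
      prev <- refit_trace[length(refit_trace) - 1L]
      if (abs(prev - obj) <= tol * max(abs(prev), 1)) break
    }
  }
  norm <- colSums(W)
  W <- sweep(W, 2L, norm, "/")
  H <- H * norm
  K <- length(keep)
  sig_names <- paste0("S", seq_len(K))
  signatures <- t(W)
  dimnames(signatures) <- list(sig_names, rownames(catalog))
  exposures <- t(H)
  dimnames(exposures) <- list(colnames(catalog), sig_names)
  structure(list(signatures = signatures, exposures = exposures, K = K,
                 lambda = best$lambda[keep],
                 objective = best$trace[length(best$trace)],
                 objective_trace = best$trace,
                 refit_trace = refit_trace,
                 converged = best$converged, seed = seed),
            class = "signature_decomposition")
}

#' @export
print.signature_decomposition <- function(x, ...) {
  cat(sprintf("<signature_decomposition> K = %d signatures, %d samples, objective %.4g (%s)\n",
              x$K, nrow(x$exposures), x$objective,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Per-sample signature exposure fractions
#'
#' @param decomposition a [ard_nmf()] result.
#' @return samples x K matrix of fractions, rows summing to 1; samples with
#'   zero total exposure are dropped.
#' @export
signature_fractions <- function(decomposition) {
  H <- decomposition$exposures
  total <- rowSums(H)
  H[total > 0, , drop = FALSE] / total[total > 0]
}

#' Cosine-similarity matching of extracted to reference signatures
#'
#' Greedy maximum-similarity bipartite matching (largest cosine first),
#' used to compare an extracted signature set to planted or published
#' profiles.
#'
#' @param extracted,reference K x 96 matrices of signature profiles.
#' @return data.frame with columns `extracted, reference, cosine`, one row
#'   per matched pair (pairs = min of the two counts).
#' @export
match_signatures <- function(extracted, reference) {
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  sim <- outer(seq_len(nrow(extracted)), seq_len(nrow(reference)),
               Vectorize(function(i, j) cosine(extracted[i, ], reference[j, ])))
  pairs <- list()
  while (length(pairs) < min(nrow(extracted), nrow(reference))) {
    best <- which(sim == max(sim, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pairs[[length(pairs) + 1L]] <- data.frame(
      extracted = rownames(extracted)[best[1L]] %||% best[1L],
      reference = rownames(reference)[best[2L]] %||% best[2L],
      cosine = sim[best[1L], best[2L]], stringsAsFactors = FALSE)
    sim[best[1L], ] <- NA
    sim[, best[2L]] <- NA
  }
  do.call(rbind, pairs)
}

#' Rank-based comparison of signature fractions between groups
#'
#' Two groups: Wilcoxon rank-sum (normal approximation with mid-rank ties);
#' two or more groups: Kruskal-Wallis. Degenerate all-tied input returns
#' p = 1.
#'
#' @param fractions named numeric vector (per-sample fraction).
#' @param labels per-sample group labels (named or in `fractions` order).
#' @param test `"wilcoxon_rank_sum"` or `"kruskal_wallis"`.
#' @return two-sided p-value.
#' @export
group_fraction_tests <- function(fractions, labels,
                                 test = c("wilcoxon_rank_sum",
                                          "kruskal_wallis")) {
  test <- match.arg(test)
  if (!is.null(names(labels)) && !is.null(names(fractions)))
    labels <- labels[names(fractions)]
  labels <- as.factor(labels)
  if (any(table(droplevels(labels)) == 0L) || nlevels(droplevels(labels)) < 2L)
    stop_validation("need >= 2 non-empty groups")
  if (length(unique(fractions)) == 1L) return(1)
  if (test == "kruskal_wallis") return(kruskal_wallis_p(fractions, labels))
  if (nlevels(droplevels(labels)) != 2L)
    stop_validation("wilcoxon_rank_sum needs exactly 2 groups")
  groups <- split(fractions, droplevels(labels))
  stats::wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE)$p.value
}
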