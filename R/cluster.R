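## Per-platform unsupervised subtype discovery (feature selection, log
## transform, row scaling, ward.D2 agglomeration on correlation distance),
## nearest-centroid classification against external squamous subtype
## centroids, and integration of per-platform cluster assignments by COCA or
## SuperCluster weighting of the one-hot cluster-indicator matrix.

#' Select clustering features from a linear-scale expression matrix
#'
#' Features must exceed `min_mean` on the linear (RPKM/RPM) scale; the
#' qualifying features are ranked by variance or coefficient of variation and
#' the top `fraction` of the *original* feature count is retained (capped,
#' with a warning, at the number qualifying — set
#' `fraction_of = "passing"` to take the fraction of the qualifying count
#' instead). `n` overrides `fraction` with an absolute count, which is the
#' convention used for miRNA matrices ("the 303 most variable mature
#' strands").
#'
#' @param m features x samples matrix on a linear scale.
#' @param fraction fraction of features to keep (default 0.25).
#' @param min_mean minimum feature mean (default 10; strict `>`).
#' @param criterion `"variance"` (default) or `"cv"`.
#' @param n optional absolute number of features (overrides `fraction`).
#' @param fraction_of basis of the fraction: `"all"` features (default) or
#'   only those `"passing"` the mean filter.
#' @return character vector of selected feature names, best first.
#' @export
select_features <- function(m, fraction = 0.25, min_mean = 10,
                            criterion = c("variance", "cv"), n = NULL,
                            fraction_of = c("all", "passing")) {
  criterion <- match.arg(criterion)
  fraction_of <- match.arg(fraction_of)
  means <- rowMeans(m)
  passing <- which(means > min_mean)
  if (length(passing) == 0L)
    stop_validation("no feature passes the mean > %g filter", min_mean)
  stat <- switch(criterion,
                 variance = apply(m[passing, , drop = FALSE], 1L, stats::var),
                 cv = apply(m[passing, , drop = FALSE], 1L, stats::sd) /
                   means[passing])
  want <- if (!is.null(n)) n else
    ceiling(fraction * if (fraction_of == "all") nrow(m) else length(passing))
  if (want > length(passing)) {
    warning(sprintf("only %d features pass the mean filter (%d requested)",
                    length(passing), want), call. = FALSE)
    want <- length(passing)
  }
  rownames(m)[passing][order(stat, decreasing = TRUE)][seq_len(want)]
}

#' Transform a matrix for clustering
#'
#' Applies `log10(x + 1)` and, optionally, scales each row to mean 0 and unit
#' standard deviation. Constant rows scale to all-zeros rather than NaN.
#'
#' @param m features x samples matrix, non-negative.
#' @param row_scale scale rows after the log transform (default `TRUE`).
#' @return transformed matrix of the same shape.
#' @export
transform_for_clustering <- function(m, row_scale = TRUE) {
  if (min(m, na.rm = TRUE) < 0) stop_validation("negative values in matrix")
  x <- log10(m + 1)
  if (row_scale) {
    mu <- rowMeans(x)
    sd <- apply(x, 1L, stats::sd)
    x <- (x - mu) / ifelse(sd > 0, sd, 1)
    x[sd == 0, ] <- 0
  }
  x
}

#' Hierarchical clustering of samples
#'
#' Sample (column) dissimilarity is 1 - Pearson correlation (or Euclidean
#' distance); agglomeration uses Ward's minimum-variance criterion in the
#' ward.D2 convention (dissimilarities squared inside the Lance-Williams
#' update), and the tree is cut into `k` clusters. Zero-variance sample
#' columns have undefined correlations and are excluded with a warning.
#'
#' @param m features x samples matrix (already transformed).
#' @param k number of clusters.
#' @param col_distance `"correlation"` (default) or `"euclidean"`.
#' @param platform label stored with the result.
#' @return list of class `"platform_clustering"`: `platform`, `labels`
#'   (named integer vector), `k`, `method`, `tree` (the [stats::hclust()]
#'   object), `excluded` (dropped zero-variance samples).
#' @export
hierarchical_cluster <- function(m, k, col_distance = c("correlation",
                                                        "euclidean"),
                                 platform = "platform") {
  col_distance <- match.arg(col_distance)
  if (k > ncol(m)) stop_validation("k = %d exceeds %d samples", k, ncol(m))
  excluded <- character(0)
  if (col_distance == "correlation") {
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
      excluded <- colnames(m)[sds == 0]
      warning(sprintf("excluding %d zero-variance sample(s): %s",
                      length(excluded), paste(excluded, collapse = ",")),
              call. = FALSE)
      m <- m[, sds > 0, drop = FALSE]
      if (k > ncol(m)) stop_validation("k exceeds samples after exclusions")
    }
    d <- stats::as.dist(1 - stats::cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  structure(list(platform = platform, labels = labels, k = k,
                 method = list(linkage = "ward.D2", distance = col_distance),
                 tree = tree, excluded = excluded),
            class = "platform_clustering")
}

#' @export
print.platform_clustering <- function(x, ...) {
  cat(sprintf("<platform_clustering> %s: %d samples in %d clusters (%s, %s)\n",
              x$platform, length(x$labels), x$k, x$method$linkage,
              x$method$distance))
  invisible(x)
}

#' Silhouette scan over candidate cluster counts
#'
#' Diagnostic for choosing `k`: mean silhouette width of the ward.D2 cut at
#' each candidate `k`, on the same dissimilarity used for clustering.
#'
#' @param m features x samples matrix (already transformed).
#' @param ks candidate cluster counts (default 2:10).
#' @param col_distance see [hierarchical_cluster()].
#' @return data.frame with columns `k`, `mean_silhouette`.
#' @export
silhouette_scan <- function(m, ks = 2:10, col_distance = "correlation") {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop_validation("silhouette_scan needs the 'cluster' package")
  d <- if (col_distance == "correlation")
    stats::as.dist(1 - stats::cor(m)) else stats::dist(t(m))
  tree <- stats::hclust(d, method = "ward.D2")
  ks <- ks[ks <= ncol(m) - 1L]
  data.frame(k = ks, mean_silhouette = vapply(ks, function(k) {
    sil <- cluster::silhouette(stats::cutree(tree, k = k), d)
    mean(sil[, "sil_width"])
  }, numeric(1L)))
}

#' Nearest-centroid subtype classification
#'
#' Restricts the matrix and centroid set to their shared genes, transforms
#' the expression matrix by log2(x + 1) and per-gene median-centring, and
#' assigns each sample the centroid with the highest Pearson correlation.
#' Ties break lexicographically with a flag; assignments whose best
#' correlation falls below `min_correlation` are flagged low-confidence.
#'
#' @param m genes x samples expression matrix on a linear scale.
#' @param centroids genes x subtypes numeric matrix of centroid profiles.
#' @param min_shared_genes refuse to classify below this overlap (default 10).
#' @param min_correlation low-confidence threshold on the winning correlation
#'   (default 0).
#' @return data.frame with columns `sample, subtype, correlation, tie,
#'   low_confidence`; the correlation matrix is attached as attribute
#'   `"correlations"`.
#' @export
centroid_classify <- function(m, centroids, min_shared_genes = 10L,
                              min_correlation = 0) {
  shared <- intersect(rownames(m), rownames(centroids))
  if (length(shared) < min_shared_genes)
    stop_validation("only %d genes shared with the centroid set (minimum %d)",
                    length(shared), min_shared_genes)
  x <- log2(m[shared, , drop = FALSE] + 1)
  x <- x - apply(x, 1L, stats::median)
  r <- stats::cor(x, centroids[shared, , drop = FALSE])
  best <- apply(r, 1L, which.max)  # ties: first = lexicographic on columns
  tie <- apply(r, 1L, function(v) sum(abs(v - max(v)) < 1e-12) > 1L)
  out <- data.frame(sample = rownames(r),
                    subtype = colnames(r)[best],
                    correlation = r[cbind(seq_len(nrow(r)), best)],
                    tie = tie, stringsAsFactors = FALSE, row.names = NULL)
  out$low_confidence <- out$correlation < min_correlation
  attr(out, "correlations") <- r
  out
}

## normalize a platform clustering (object or named label vector) to labels
.platform_labels <- function(x, default_name) {
  if (inherits(x, "platform_clustering"))
    list(name = x$platform, labels = x$labels)
  else if (!is.null(names(x)))
    list(name = default_name, labels = x)
  else stop_validation("platform clusterings must be named label vectors or platform_clustering objects")
}

#' Integrate per-platform clusterings (COCA / SuperCluster)
#'
#' Builds the samples x cluster-indicator one-hot matrix over all platforms,
#' weights each platform's column block — SuperCluster scales a block by
#' `1/sqrt(sum of its column variances)` so every platform contributes equal
#' total variance; COCA scales by `1/sqrt(K_p)`, discounting platforms that
#' split samples more finely — and partitions the weighted indicator rows
#' into `k` clusters by k-means (25 deterministic restarts). K-means is used
#' rather than Ward agglomeration because on one-hot encodings Ward
#' preferentially isolates samples with discordant platform votes into an
#' outlier cluster instead of splitting the concordant majority; see the
#' methods vignette. Samples absent from a platform get a zero block there
#' and are flagged.
#'
#' @param platform_clusterings list of [hierarchical_cluster()] results or
#'   named per-sample label vectors (list names become platform names).
#' @param method `"COCA"` or `"SuperCluster"`.
#' @param k number of integrated clusters.
#' @return list of class `"integrative_clustering"`: `labels` (named integer
#'   vector over the union of samples), `method`, `k`, `weights` (per
#'   platform), `missing` (sample -> platforms absent), `tree`.
#' @export
integrate_clusters <- function(platform_clusterings,
                               method = c("COCA", "SuperCluster"), k) {
  method <- match.arg(method)
  if (length(platform_clusterings) < 2L)
    stop_validation("need at least 2 platforms")
  plats <- lapply(seq_along(platform_clusterings), function(i)
    .platform_labels(platform_clusterings[[i]],
                     names(platform_clusterings)[i] %||% paste0("platform", i)))
  nms <- vapply(plats, `[[`, character(1L), "name")
  nms[!nzchar(nms)] <- paste0("platform", which(!nzchar(nms)))
  samples <- Reduce(union, lapply(plats, function(p) names(p$labels)))
  if (length(samples) == 0L) stop_validation("no samples")

  blocks <- list()
  weights <- numeric(0)
  missing <- list()
  for (i in seq_along(plats)) {
    lab <- plats[[i]]$labels
    levels <- sort(unique(as.character(lab)))
    K_p <- length(levels)
    if (K_p == 1L)
      warning(sprintf("platform %s has a single cluster and contributes nothing",
                      nms[i]), call. = FALSE)
    block <- matrix(0, length(samples), K_p,
                    dimnames = list(samples, paste(nms[i], levels, sep = ":")))
    present <- intersect(samples, names(lab))
    block[cbind(present, paste(nms[i], as.character(lab[present]), sep = ":"))] <- 1
    absent <- setdiff(samples, present)
    for (s in absent) missing[[s]] <- c(missing[[s]], nms[i])
    w <- if (method == "COCA") 1 / sqrt(K_p) else {
      v <- sum(apply(block, 2L, stats::var))
      if (v > 0) 1 / sqrt(v) else 0
    }
    weights[nms[i]] <- w
    blocks[[i]] <- block * w
  }
  if (all(weights == 0) || all(vapply(plats, function(p)
    length(unique(p$labels)), integer(1L)) == 1L))
    stop_validation("every platform has a single cluster; nothing to integrate")

  indicator <- do.call(cbind, blocks)
  n_distinct <- nrow(unique(indicator))
  if (n_distinct < k)
    stop_validation("k = %d exceeds the %d distinct platform encodings",
                    k, n_distinct)
  ## fixed internal seed: the partition is a deterministic function of the
  ## inputs, like the rest of this module
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(k, paste0("integrate_", method)))
  km <- stats::kmeans(indicator, centers = k, nstart = 25L, iter.max = 100L)
  structure(list(labels = setNames(km$cluster, rownames(indicator)),
                 method = method, k = k,
                 weights = weights, missing = missing,
                 indicator = indicator),
            class = "integrative_clustering")
}

#' @export
print.integrative_clustering <- function(x, ...) {
  cat(sprintf("<integrative_clustering> %s: %d samples in %d clusters over %d platform(s)\n",
              x$method, length(x$labels), x$k, length(x$weights)))
  invisible(x)
}
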