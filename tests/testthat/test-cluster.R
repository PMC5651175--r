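test_that("feature selection composes the mean filter with the top fraction", {
  set.seed(91)
  m <- matrix(runif(100 * 10, 0, 5), 100, 10,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
  ## 30 genes pass mean > 10; top 25% of the original 100 = 25 features
  m[1:30, ] <- m[1:30, ] + 15
  sel <- select_features(m, fraction = 0.25, min_mean = 10)
  expect_length(sel, 25)
  expect_true(all(sel %in% sprintf("g%03d", 1:30)))
  ## if fewer qualify than requested, all qualifying return with a warning
  m2 <- m
  m2[11:30, ] <- 0
  expect_warning(sel2 <- select_features(m2, fraction = 0.25, min_mean = 10),
                 "pass the mean filter")
  expect_length(sel2, 10)
  expect_error(select_features(m2 * 0, min_mean = 10), "no feature")
})

test_that("constant genes rank last; planted variable genes rank first", {
  set.seed(92)
  m <- matrix(20, 1000, 12, dimnames = list(sprintf("g%04d", 1:1000),
                                            paste0("s", 1:12)))
  m <- m + matrix(rnorm(1000 * 12, 0, 1e-3), 1000, 12)
  hot <- sprintf("g%04d", 101:120)
  m[hot, ] <- 20 + matrix(rnorm(20 * 12, 0, 8), 20, 12)
  sel <- select_features(m, n = 20)
  expect_setequal(sel, hot)
  expect_setequal(select_features(m, n = 20, criterion = "cv"), hot)
})

test_that("the clustering transform is log10(x+1) with unit row scaling", {
  m <- matrix(c(0, 9, 99), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  tr <- transform_for_clustering(m)
  expect_equal(unname(tr[1, ]), c(-1, 0, 1))
  ## constant rows become zeros, not NaN
  m2 <- rbind(m, g2 = c(5, 5, 5))
  tr2 <- transform_for_clustering(m2)
  expect_equal(unname(tr2["g2", ]), c(0, 0, 0))
  ## every non-constant row is centred and unit-scaled
  set.seed(93)
  m3 <- matrix(runif(50 * 8, 0, 100), 50, 8,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  tr3 <- transform_for_clustering(m3)
  expect_lt(max(abs(rowMeans(tr3))), 1e-12)
  expect_lt(max(abs(apply(tr3, 1, sd) - 1)), 1e-12)
  expect_error(transform_for_clustering(-m), "negative")
})

test_that("identical samples merge first at zero dissimilarity", {
  set.seed(94)
  m <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("s", 1:6)))
  m[, 2] <- m[, 1]
  cl <- hierarchical_cluster(m, k = 3)
  expect_equal(cl$tree$height[1], 0, tolerance = 1e-12)
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("s1", "s2"))
  expect_equal(cl$labels[["s1"]], cl$labels[["s2"]])
})

test_that("planted expression subtypes are recovered by ward.D2/correlation", {
  cfg <- cohort_config(n_per_subtype = c(ESCC1 = 20L, ESCC2 = 20L, EAC = 20L))
  subtype <- setNames(rep(c("ESCC1", "ESCC2", "EAC"), each = 20),
                      sprintf("S%03d", 1:60))
  ex <- simulate_expression_subtypes(cfg, subtype, seed = 21)
  feats <- select_features(ex$expr_rpkm, fraction = 0.25, min_mean = 10)
  tr <- transform_for_clustering(ex$expr_rpkm[feats, ])
  cl <- hierarchical_cluster(tr, k = 3)
  expect_gte(ari(cl$labels[names(subtype)], subtype), 0.9)
  ## invariant to sample column order
  perm <- sample(ncol(tr))
  cl2 <- hierarchical_cluster(tr[, perm], k = 3)
  expect_equal(ari(cl2$labels[names(subtype)], cl$labels[names(subtype)]), 1)
})

test_that("two identical subtypes yield no stable 2-split", {
  cfg <- cohort_config(subtypes = c("A", "B"),
                       n_per_subtype = c(A = 20L, B = 20L),
                       arm_events = list(),
                       expression = list(n_genes = 300L, effect_log10 = 0,
                                         n_null_pathways = 2L))
  subtype <- setNames(rep(c("A", "B"), each = 20), sprintf("S%03d", 1:40))
  ex <- simulate_expression_subtypes(cfg, subtype, seed = 31)
  feats <- select_features(ex$expr_rpkm, fraction = 0.25, min_mean = 10)
  tr <- transform_for_clustering(ex$expr_rpkm[feats, ])
  scan <- silhouette_scan(tr, ks = 2)
  expect_lt(scan$mean_silhouette[scan$k == 2], 0.1)
})

test_that("zero-variance samples are excluded with a warning", {
  set.seed(95)
  m <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("s", 1:5)))
  m[, 5] <- 2
  expect_warning(cl <- hierarchical_cluster(m, k = 2), "zero-variance")
  expect_equal(cl$excluded, "s5")
  expect_false("s5" %in% names(cl$labels))
})

test_that("ward.D2 merge heights equal a brute-force variance agglomeration", {
  set.seed(96)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    rownames(X) <- paste0("s", seq_len(n))
    cl <- hierarchical_cluster(t(X), k = 2, col_distance = "euclidean")
    expect_equal(cl$tree$height, ward_oracle_heights(X), tolerance = 1e-9)
  }
})

test_that("centroid classification is exact on engineered profiles", {
  set.seed(97)
  genes <- paste0("g", 1:60)
  v <- rnorm(60, 0, 1.5)
  centroids <- cbind(A = v, B = -v)
  rownames(centroids) <- genes
  c0 <- abs(v) + 1  # per-gene offset keeps RPKM non-negative
  ## two samples per centroid: the per-gene median equals the offset, so the
  ## centred transforms equal +v / -v exactly
  logm <- cbind(sa1 = c0 + v, sa2 = c0 + v, sb1 = c0 - v, sb2 = c0 - v)
  m <- 2^logm - 1
  rownames(m) <- genes
  res <- centroid_classify(m, centroids)
  expect_equal(res$subtype, c("A", "A", "B", "B"))
  expect_equal(res$correlation, rep(1, 4), tolerance = 1e-9)
  expect_false(any(res$tie))
  expect_false(any(res$low_confidence))
  expect_error(centroid_classify(m[1:5, ], centroids[1:5, , drop = FALSE],
                                 min_shared_genes = 10), "shared")
})

test_that("noisy centroid profiles classify correctly at 0.5x noise", {
  set.seed(98)
  genes <- paste0("g", 1:200)
  cents <- matrix(rnorm(200 * 4, 0, 1), 200, 4,
                  dimnames = list(genes, c("atypical", "basal", "classical",
                                           "mesenchymal")))
  truth <- sample(colnames(cents), 60, replace = TRUE)
  offset <- 6
  logm <- sapply(seq_along(truth), function(i)
    offset + cents[, truth[i]] + rnorm(200, 0, 0.5))
  colnames(logm) <- paste0("s", seq_along(truth))
  rownames(logm) <- genes
  m <- pmax(2^logm - 1, 0)
  res <- centroid_classify(m, cents)
  expect_gte(mean(res$subtype == truth), 0.95)
})

test_that("integrating identical labelings reproduces the input partition", {
  labs <- setNames(rep(1:3, each = 8), sprintf("S%02d", 1:24))
  for (method in c("COCA", "SuperCluster")) {
    res <- integrate_clusters(list(a = labs, b = labs), method = method, k = 3)
    expect_equal(ari(res$labels[names(labs)], labs), 1)
  }
})

test_that("SuperCluster equalizes platform block variances", {
  set.seed(99)
  samples <- sprintf("S%02d", 1:30)
  p1 <- setNames(sample(1:3, 30, replace = TRUE), samples)
  p2 <- setNames(sample(1:5, 30, replace = TRUE), samples)
  res <- integrate_clusters(list(a = p1, b = p2), method = "SuperCluster",
                            k = 3)
  ind <- res$indicator
  va <- sum(apply(ind[, startsWith(colnames(ind), "a:")], 2, var))
  vb <- sum(apply(ind[, startsWith(colnames(ind), "b:")], 2, var))
  expect_equal(va, vb, tolerance = 1e-9)
  expect_equal(va, 1, tolerance = 1e-9)
})

test_that("duplicating a platform leaves the SuperCluster partition unchanged", {
  ## equal-weight normalization: a duplicated block carries the same unit
  ## total variance as every other block, so on concordant platforms the
  ## partition is exactly reproduced (discordant samples necessarily move
  ## toward the duplicated platform's vote; see the methods vignette)
  truth <- setNames(rep(1:3, each = 10), sprintf("S%02d", 1:30))
  p2 <- setNames(rep(c(1, 3, 2), each = 10), names(truth))  # relabelled only
  base <- integrate_clusters(list(a = truth, b = p2), "SuperCluster", k = 3)
  dup <- integrate_clusters(list(a = truth, b = p2, c = truth),
                            "SuperCluster", k = 3)
  expect_equal(ari(dup$labels[names(truth)], base$labels[names(truth)]), 1)
  ## and the duplicated block's weighted variance stays equal to the others
  ind <- dup$indicator
  v <- vapply(c("a:", "b:", "c:"), function(pr)
    sum(apply(ind[, startsWith(colnames(ind), pr)], 2, var)), numeric(1))
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-9)
})

test_that("COCA discounts fine-grained platforms by 1/sqrt(K)", {
  samples <- sprintf("S%02d", 1:12)
  p1 <- setNames(rep(1:2, 6), samples)
  p2 <- setNames(rep(1:4, 3), samples)
  res <- integrate_clusters(list(coarse = p1, fine = p2), "COCA", k = 2)
  expect_equal(unname(res$weights["coarse"]), 1 / sqrt(2))
  expect_equal(unname(res$weights["fine"]), 1 / sqrt(4))
})

test_that("samples missing from one platform are zero-filled and flagged", {
  p1 <- setNames(rep(1:2, each = 5), sprintf("S%02d", 1:10))
  p2 <- setNames(rep(1:2, each = 4), sprintf("S%02d", 1:8))
  res <- integrate_clusters(list(a = p1, b = p2), "COCA", k = 2)
  expect_setequal(names(res$labels), names(p1))
  expect_equal(res$missing[["S09"]], "b")
  expect_warning(
    integrate_clusters(list(a = p1,
                            b = setNames(rep(1, 10), names(p1))), "COCA",
                       k = 2),
    "single cluster")
})
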