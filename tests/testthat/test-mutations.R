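test_that("merging unions variants and records caller provenance", {
  a <- variant_row(caller = "A")
  b <- variant_row(caller = "B", t_ref = 60, t_alt = 12)  # deeper record
  m <- merge_call_sets(list(A = a, B = b))
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "A,B")
  expect_equal(m$n_callers, 2)
  expect_equal(m$t_ref_count, 60)  # max-depth record wins

  only_a <- merge_call_sets(list(A = a, B = variant_row(pos = 999)),
                            min_callers = 2)
  expect_equal(nrow(only_a), 0)

  expect_error(merge_call_sets(list(variant_row(ref = "C"),
                                    variant_row(ref = "G", alt = "T"))),
               "conflicting reference")
})

test_that("a 3-caller fixture with planned overlaps unions to 7 variants", {
  v <- function(pos) variant_row(pos = pos)
  setA <- do.call(rbind, lapply(c(1, 2, 3, 4), v))
  setB <- do.call(rbind, lapply(c(3, 4, 5, 6), v))
  setC <- do.call(rbind, lapply(c(1, 4, 6, 7), v))
  m <- merge_call_sets(list(A = setA, B = setB, C = setC))
  expect_equal(nrow(m), 7)  # union of {1..7}
  expect_equal(m$n_callers[m$pos == 4], 3)
})

test_that("read-count filters implement the stated removal rules", {
  ## passes every rule: clean normal, 5 alt reads at VAF 8.3%
  ok <- variant_row(n_ref = 50, n_alt = 0, t_alt = 5, t_ref = 55)
  expect_length(read_count_filter_reasons(ok)[[1]], 0)

  low_cov <- variant_row(n_ref = 7, n_alt = 0)
  expect_equal(read_count_filter_reasons(low_cov)[[1]],
               "normal_low_ref_coverage")

  low_vaf <- variant_row(t_alt = 2, t_ref = 48)  # 4% < the 5% minimum
  expect_equal(read_count_filter_reasons(low_vaf)[[1]], "tumor_vaf")

  ## boundaries: >1 normal alt read, >1% normal VAF, >=2 tumour reads, >=5% VAF
  expect_length(read_count_filter_reasons(
    variant_row(n_ref = 99, n_alt = 1, t_alt = 5, t_ref = 95))[[1]], 0)
  expect_equal(read_count_filter_reasons(
    variant_row(n_ref = 99, n_alt = 2))[[1]],
    c("normal_alt_reads", "normal_vaf"))
  expect_equal(read_count_filter_reasons(
    variant_row(n_ref = 98, n_alt = 1))[[1]], "normal_vaf")
  expect_length(read_count_filter_reasons(
    variant_row(t_alt = 2, t_ref = 38))[[1]], 0)  # exactly 5%, kept
  ## zero normal depth fails coverage
  expect_true("normal_low_ref_coverage" %in%
                read_count_filter_reasons(variant_row(n_ref = 0, n_alt = 0))[[1]])
})

test_that("blacklist matching flags exactly the listed sites", {
  set.seed(31)
  v <- random_variants(20, seed = 31)
  listed <- v[sample.int(20, 5), c("chrom", "pos")]
  listed$alt <- NA_character_
  r <- blacklist_filter_reasons(v, germline_sites = listed)
  expect_equal(sum(vapply(r, length, 1L) > 0), 5)
  expect_true(all(unlist(r) == "germline_1000G"))

  none <- blacklist_filter_reasons(v, NULL, NULL)
  expect_true(all(lengths(none) == 0))

  ## allele-constrained sites only match the same alt
  con <- data.frame(chrom = v$chrom[1], pos = v$pos[1],
                    alt = setdiff(c("A", "C", "G", "T"),
                                  c(v$ref[1], v$alt[1]))[1])
  expect_length(blacklist_filter_reasons(v[1, ], con)[[1]], 0)
})

test_that("oxoG filter flags only orientation-biased C>A / G>T calls", {
  ca_biased <- variant_row(ref = "C", alt = "A", f1r2 = 1L, f2r1 = 9L)
  expect_equal(oxog_filter_reasons(ca_biased)[[1]], "oxog_orientation")

  ca_balanced <- variant_row(ref = "C", alt = "A", f1r2 = 5L, f2r1 = 5L)
  expect_length(oxog_filter_reasons(ca_balanced)[[1]], 0)

  tg <- variant_row(ref = "T", alt = "G", f1r2 = 0L, f2r1 = 10L)
  expect_length(oxog_filter_reasons(tg)[[1]], 0)  # wrong substitution class

  gt_biased <- variant_row(ref = "G", alt = "T", f1r2 = 9L, f2r1 = 1L)
  expect_equal(oxog_filter_reasons(gt_biased)[[1]], "oxog_orientation")

  no_counts <- variant_row(ref = "C", alt = "A")
  expect_length(oxog_filter_reasons(no_counts)[[1]], 0)
  ## below the minimum alt reads the evidence is too thin to flag
  few <- variant_row(ref = "C", alt = "A", f1r2 = 0L, f2r1 = 2L)
  expect_length(oxog_filter_reasons(few)[[1]], 0)
})

test_that("the composed pipeline equals an independent single-pass filter", {
  v <- random_variants(1000, seed = 77)
  germ <- data.frame(chrom = v$chrom[1:40], pos = v$pos[1:40],
                     alt = NA_character_)
  pon <- data.frame(chrom = v$chrom[41:60], pos = v$pos[41:60],
                    alt = NA_character_)
  res <- filter_mutations(list(A = v), germline_sites = germ, pon_sites = pon)
  expect_equal(nrow(res$decisions), 1000)
  key_dec <- paste(res$decisions$sample, res$decisions$chrom,
                   res$decisions$pos)
  for (i in seq_len(nrow(v))) {
    expected <- sort(brute_filter_one(v[i, ], germ, pon))
    j <- match(paste(v$sample[i], v$chrom[i], v$pos[i]), key_dec)
    got <- res$decisions$reasons[j]
    got <- if (nzchar(got)) sort(strsplit(got, ",")[[1]]) else character(0)
    expect_equal(got, expected)
  }
  expect_equal(res$decisions$kept, res$decisions$reasons == "")
})

test_that("survivor count is monotone in threshold strictness", {
  v <- random_variants(400, seed = 78)
  n_kept <- function(...) nrow(filter_mutations(list(A = v), ...)$kept)
  base <- n_kept()
  expect_lte(n_kept(min_tumor_vaf = 0.10), base)
  expect_lte(n_kept(min_tumor_alt_reads = 4), base)
  expect_lte(n_kept(min_normal_ref_coverage = 15), base)
  expect_gte(n_kept(max_normal_alt_reads = 5), base)
  ## the AND reading of the normal rule is strictly laxer than OR
  expect_gte(n_kept(normal_rule = "and"), base)
})

test_that("filter reasons do not depend on evaluation order", {
  v <- random_variants(200, seed = 79)
  germ <- data.frame(chrom = v$chrom[1:10], pos = v$pos[1:10],
                     alt = NA_character_)
  r1 <- blacklist_filter_reasons(v, germ)
  r2 <- read_count_filter_reasons(v)
  r3 <- oxog_filter_reasons(v)
  ab <- Map(c, r1, r2)
  ba <- Map(c, r2, r1)
  expect_equal(lapply(Map(c, ab, r3), sort), lapply(Map(c, r3, ba), sort))
})
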