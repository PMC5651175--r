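small_cfg <- function(...) {
  base <- list(n_per_subtype = c(ESCC1 = 6L, ESCC2 = 6L, EAC = 6L),
               mutations = list(per_sample = 25L),
               expression = list(n_genes = 150L, n_null_pathways = 3L),
               methylation = list(n_genes = 15L))
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
                      !is.data.frame(over[[nm]]))
      utils::modifyList(base[[nm]], over[[nm]]) else over[[nm]]
  }
  do.call(cohort_config, base)
}

test_that("the same seed reproduces the cohort byte-for-byte", {
  c1 <- simulate_cohort(small_cfg(), seed = 42)
  c2 <- simulate_cohort(small_cfg(), seed = 42)
  expect_equal(c1, c2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  ## a different seed changes the data
  c3 <- simulate_cohort(small_cfg(), seed = 43)
  expect_false(identical(c1$expr_rpkm, c3$expr_rpkm))
})

test_that("platform substreams are independent of one another", {
  cfg <- small_cfg()
  subtype <- setNames(rep(c("ESCC1", "ESCC2", "EAC"), each = 6),
                      sprintf("S%03d", 1:18))
  me1 <- simulate_methylation_expression(cfg, subtype, seed = 42)
  ## generating another platform first must not perturb this one
  invisible(simulate_expression_subtypes(cfg, subtype, seed = 42))
  me2 <- simulate_methylation_expression(cfg, subtype, seed = 42)
  expect_equal(me1, me2)
})

test_that("all outputs respect their declared scales", {
  co <- simulate_cohort(small_cfg(), seed = 7)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_true(all(co$expr_rpkm >= 0))
  expect_true(all(co$meth_expr_rpkm >= 0))
  counts <- do.call(rbind, co$call_sets)
  expect_true(all(counts$t_ref_count >= 0 & counts$t_alt_count >= 0 &
                    counts$n_ref_count >= 0 & counts$n_alt_count >= 0))
  expect_true(all(abs(rowSums(co$truth$exposures) - 1) < 1e-9))
})

test_that("with no dropout and no false positives callers reproduce truth", {
  cfg <- small_cfg(mutations = list(per_sample = 25L, dropout = 0,
                                    fp_rate = 0, fp_blacklist_rate = 0))
  co <- simulate_cohort(cfg, seed = 9)
  tkey <- with(co$truth$variants, paste(sample, chrom, pos, ref, alt))
  for (cs in co$call_sets) {
    ckey <- with(cs, paste(sample, chrom, pos, ref, alt))
    expect_setequal(ckey, tkey)
  }
  ## and with dropout, every truth variant still appears in >= 1 caller
  ## only when dropout = 0 (the guarantee under test)
  merged <- merge_call_sets(co$call_sets)
  expect_setequal(with(merged, paste(sample, chrom, pos, ref, alt)), tkey)
})

test_that("planted false positives fall to the read-count filters", {
  cfg <- small_cfg(mutations = list(per_sample = 25L, dropout = 0,
                                    fp_rate = 0.3, fp_blacklist_rate = 0))
  co <- simulate_cohort(cfg, seed = 10)
  res <- filter_mutations(co$call_sets, germline_sites = co$germline_sites)
  tkey <- with(co$truth$variants, paste(sample, chrom, pos))
  kkey <- with(res$kept, paste(sample, chrom, pos))
  ## every planted FP has 1-2 alt reads at ~100x depth: none survives
  expect_true(all(kkey %in% tkey))
})

test_that("silencing rate zero yields no silencing calls at defaults", {
  cfg <- small_cfg(methylation = list(n_genes = 15L, silencing_rate = 0,
                                      n_subtype_genes = 0L,
                                      differential_gene_rates =
                                        c(ESCC1 = 0, ESCC2 = 0, EAC = 0)))
  subtype <- setNames(rep(c("ESCC1", "ESCC2", "EAC"), each = 10),
                      sprintf("S%03d", 1:30))
  me <- simulate_methylation_expression(cfg, subtype, seed = 11)
  expect_false(any(me$silenced))
  res <- call_silencing_matrix(me$beta, log2(me$expr_rpkm + 1), me$probe_map)
  expect_equal(sum(res$calls), 0)
})

test_that("a certain loss with zero noise forces a uniform downstream call", {
  cfg <- small_cfg(
    arm_events = list(ESCC1 = data.frame(arm = "17p", p_gain = 0, p_loss = 1),
                      ESCC2 = data.frame(arm = "17p", p_gain = 0, p_loss = 1),
                      EAC = data.frame(arm = "17p", p_gain = 0, p_loss = 1)),
    cn = list(noise_sd = 0, min_covered_fraction = 1 - 1e-9))
  subtype <- setNames(rep(c("ESCC1", "ESCC2", "EAC"), each = 4),
                      sprintf("S%03d", 1:12))
  cn <- simulate_copy_number(cfg, subtype, seed = 12)
  expect_true(all(cn$arm_truth[, "17p"] == "loss"))
  res <- cohort_cin(cn$profiles)
  expect_true(all(res$arm_calls[, "17p"] == "loss"))
  expect_true(all(res$cin_calls$label == "SCNA_high"))
})

test_that("arm events stay away from the calling boundaries by construction", {
  cfg <- small_cfg()
  subtype <- setNames(rep(c("ESCC1", "ESCC2", "EAC"), each = 15),
                      sprintf("S%03d", 1:45))
  cn <- simulate_copy_number(cfg, subtype, seed = 13)
  res <- cohort_cin(cn$profiles)
  agree <- mean(res$arm_calls[, colnames(cn$arm_truth)] == cn$arm_truth)
  expect_gte(agree, 0.99)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(arm_events = list(
    ESCC1 = data.frame(arm = "17p", p_gain = 0.8, p_loss = 0.8))),
    "out of range")
  expect_error(cohort_config(arm_events = list(
    ESCC1 = data.frame(arm = "99z", p_gain = 0, p_loss = 1))), "unknown arm")
  expect_error(cohort_config(arm_events = list(
    ESCC1 = data.frame(arm = "13p", p_gain = 0, p_loss = 1))),
    "non-callable")
  expect_error(cohort_config(mutations = list(tumor_depth = 0)), "depth")
  expect_error(cohort_config(mutations = list(dropout = 2)), "dropout")
})
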