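make_profile <- function(segs, sample = "S1") {
  scn_profile(sample, data.frame(chrom = segs$chrom %||% "1", segs))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
arm1 <- list(chrom = "1", start = 0, end = 100e6, arm = "1p")

test_that("arm fractions are overlap sums at the stated log2 thresholds", {
  p <- make_profile(data.frame(start = 0, end = 85e6, log2_ratio = -0.20))
  fr <- project_segments_to_arm(p, arm1)
  expect_equal(fr[["fraction_loss"]], 0.85)
  expect_equal(fr[["fraction_gain"]], 0)

  ## below the 0.15 magnitude threshold nothing counts
  p2 <- make_profile(data.frame(start = 0, end = 85e6, log2_ratio = -0.14))
  expect_equal(project_segments_to_arm(p2, arm1)[["fraction_loss"]], 0)
  ## the threshold itself is inclusive ("at least 0.15")
  p3 <- make_profile(data.frame(start = 0, end = 85e6, log2_ratio = -0.15))
  expect_equal(project_segments_to_arm(p3, arm1)[["fraction_loss"]], 0.85)
})

test_that("mixed multi-segment fractions match hand-computed overlaps", {
  ## arm [0, 100Mb); segments partially overlapping, mixed signs
  p <- make_profile(data.frame(
    start = c(-10e6, 10e6, 40e6, 60e6, 95e6),
    end = c(5e6, 30e6, 55e6, 90e6, 120e6),
    log2_ratio = c(-0.3, 0.2, -0.5, 0.1, 0.16)))
  fr <- project_segments_to_arm(p, arm1)
  ## loss: [0,5M) + [40M,55M) = 20M; gain: [10M,30M) + [95M,100M) = 25M
  expect_equal(fr[["fraction_loss"]], 20e6 / 100e6)
  expect_equal(fr[["fraction_gain"]], 25e6 / 100e6)
})

test_that("the 80% arm-alteration boundary is inclusive", {
  expect_equal(call_arm(c(fraction_gain = 0, fraction_loss = 0.85)), "loss")
  expect_equal(call_arm(c(fraction_gain = 0, fraction_loss = 0.80)), "loss")
  expect_equal(call_arm(c(fraction_gain = 0.10, fraction_loss = 0.79)),
               "neutral")
  expect_equal(call_arm(c(fraction_gain = 0.80, fraction_loss = 0)), "gain")
  expect_equal(call_arm(c(fraction_gain = 0, fraction_loss = 1),
                        callable = FALSE), "not_callable")
  expect_error(call_arm(c(fraction_gain = 0.5, fraction_loss = 0.5),
                        altered_fraction_threshold = 0.4), "both")
})

test_that("SCNA-high requires a loss outside the 18p/18q/21 exclusion", {
  calls <- c("18q" = "loss", "17p" = "neutral", "1p" = "gain")
  r <- classify_cin(calls)
  expect_equal(r$label, "SCNA_low")
  expect_equal(r$excluded_arm_losses, "18q")

  calls["17p"] <- "loss"
  r2 <- classify_cin(calls)
  expect_equal(r2$label, "SCNA_high")
  expect_equal(r2$qualifying_arm_losses, "17p")

  expect_equal(classify_cin(c("1p" = "neutral", "1q" = "neutral"))$label,
               "SCNA_low")
  expect_error(classify_cin(c("1p" = "loss", "1p" = "loss")), "duplicate")
})

test_that("interval arithmetic matches a 10-kb rasterization oracle", {
  set.seed(401)
  arm <- list(chrom = "1", start = 0, end = 20e6, arm = "1p")
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    starts <- sort(sample(seq(-2e6, 22e6, by = 1e4), n))
    lens <- sample(seq(1e5, 8e6, by = 1e4), n, replace = TRUE)
    ## rasterization cannot represent overlap; keep segments disjoint
    segs <- data.frame(chrom = "1", start = starts, end = starts + lens,
                       log2_ratio = round(runif(n, -0.5, 0.5), 2))
    segs$end <- pmin(segs$end, c(segs$start[-1], Inf))
    segs <- segs[segs$start < segs$end, ]
    p <- scn_profile("S1", segs)
    fr <- project_segments_to_arm(p, arm)
    or <- raster_arm_fractions(p, arm)
    unit <- 1e4 / (arm$end - arm$start)
    expect_lt(abs(fr[["fraction_gain"]] - or[["fraction_gain"]]), unit + 1e-12)
    expect_lt(abs(fr[["fraction_loss"]] - or[["fraction_loss"]]), unit + 1e-12)
    ## agreement of the derived arm call
    expect_equal(call_arm(fr), call_arm(or))
  }
})

test_that("loss calls are monotone in loss magnitude and translation-invariant", {
  set.seed(402)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    starts <- sort(sample.int(90e6, n))
    segs <- data.frame(start = starts,
                       end = starts + sample(1e6:30e6, n, replace = TRUE),
                       log2_ratio = runif(n, -0.6, 0.2))
    segs$end <- pmin(segs$end, c(segs$start[-1], Inf))
    p <- make_profile(segs)
    fr <- project_segments_to_arm(p, arm1)
    ## deepen every loss: the loss fraction can only grow
    segs2 <- segs
    segs2$log2_ratio <- ifelse(segs2$log2_ratio < 0,
                               segs2$log2_ratio - 0.3, segs2$log2_ratio)
    fr2 <- project_segments_to_arm(make_profile(segs2), arm1)
    expect_gte(fr2[["fraction_loss"]], fr[["fraction_loss"]])
    if (call_arm(fr) == "loss") expect_equal(call_arm(fr2), "loss")
    ## translate all coordinates: calls unchanged
    shift <- 7.3e6
    segs3 <- segs
    segs3$start <- segs3$start + shift
    segs3$end <- segs3$end + shift
    arm_s <- list(chrom = "1", start = arm1$start + shift,
                  end = arm1$end + shift, arm = "1p")
    fr3 <- project_segments_to_arm(make_profile(segs3), arm_s)
    expect_equal(fr3, fr)
  }
})

test_that("cohort calls are per-sample and order-invariant", {
  cohort <- simulate_copy_number(
    cohort_config(n_per_subtype = c(ESCC1 = 3L, ESCC2 = 3L, EAC = 3L)),
    setNames(rep(c("ESCC1", "ESCC2", "EAC"), each = 3), sprintf("S%02d", 1:9)),
    seed = 7)
  res <- cohort_cin(cohort$profiles)
  expect_equal(nrow(res$cin_calls), 9)
  res_rev <- cohort_cin(rev(cohort$profiles))
  reord <- res_rev$cin_calls[match(res$cin_calls$sample,
                                   res_rev$cin_calls$sample), ]
  expect_equal(reord$label, res$cin_calls$label)

  one <- cohort_cin(cohort$profiles[1])
  expect_equal(nrow(one$cin_calls), 1)
})

test_that("probe weighting is available and agrees on uniform probe density", {
  segs <- data.frame(start = c(0, 50e6), end = c(50e6, 100e6),
                     log2_ratio = c(-0.3, 0), n_probes = c(500L, 500L))
  p <- make_profile(segs)
  bp <- project_segments_to_arm(p, arm1)
  pw <- project_segments_to_arm(p, arm1, probe_weighted = TRUE)
  expect_equal(bp[["fraction_loss"]], 0.5)
  expect_equal(pw[["fraction_loss"]], 0.5)
})
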