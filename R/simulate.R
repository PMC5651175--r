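## Synthetic multi-platform cohort generator with recorded ground truth.
##
## The generator emulates the structure the analysis stages are built to
## detect: subtype-patterned arm-level gains/losses in segmented copy-number
## profiles, inverse methylation-expression coupling for silenced genes,
## multi-caller somatic variant sets with planted false positives and
## read-count noise, trinucleotide-context mutation catalogs drawn from
## signature mixtures, and subtype-differential expression organized into
## pathways. One master seed drives independent, labelled substreams per
## platform, so regenerating one platform never perturbs another.

#' Default simulated signature profiles
#'
#' Three caricature signatures on the 96-context simplex: an ageing-like
#' C>T-at-CpG profile, an APOBEC-like TpCpW C>T/C>G profile, and a
#' smoking-like profile spread over the C>A bins. Each row sums to 1 and the
#' three are mutually near-orthogonal, which makes factorization recovery
#' unambiguous.
#'
#' @return 3 x 96 matrix with rownames `aging`, `apobec`, `smoking`.
#' @export
default_signatures <- function() {
  bins <- context_bins()
  base <- 0.1 / 96
  aging <- rep(base, 96)
  names(aging) <- bins
  cpg <- grepl("\\[C>T\\]G$", bins)
  aging[cpg] <- aging[cpg] + 0.9 / sum(cpg)
  apobec <- rep(base, 96)
  names(apobec) <- bins
  apobec[apobec_bins()] <- apobec[apobec_bins()] + 0.9 / 4
  smoking <- rep(base, 96)
  names(smoking) <- bins
  ca <- grepl("\\[C>A\\]", bins)
  smoking[ca] <- smoking[ca] + 0.9 / sum(ca)
  m <- rbind(aging = aging, apobec = apobec, smoking = smoking)
  m / rowSums(m)
}

#' Default simulation configuration
#'
#' The study conditions of the synthetic cohort. Per-subtype arm-event
#' probabilities give each subtype a recognizable copy-number fingerprint
#' (including losses of the CIN-excluded arms 18q/21q in the EAC-like
#' subtype, so the exclusion rule is exercised); altered arms sit at
#' log2 +/- 0.3 with segment noise sd 0.05 and cover at least 90% of the
#' arm, keeping planted events well clear of the 80% / 0.15 decision
#' boundaries, whose exact behaviour is tested with deterministic fixtures
#' instead. All values can be overridden by name.
#'
#' @param ... named overrides of top-level config entries.
#' @return config list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    subtypes = c("ESCC1", "ESCC2", "EAC"),
    n_per_subtype = c(ESCC1 = 40L, ESCC2 = 40L, EAC = 40L),
    arm_table = default_arm_table(),
    ## per-subtype arm event probabilities: list(subtype -> data.frame)
    arm_events = list(
      ESCC1 = data.frame(arm = c("3p", "3q", "9p", "5p"),
                         p_gain = c(0, 0.9, 0, 0.7),
                         p_loss = c(0.9, 0, 0.5, 0)),
      ESCC2 = data.frame(arm = c("8q", "13q", "11q", "9p"),
                         p_gain = c(0.8, 0, 0.7, 0),
                         p_loss = c(0, 0.8, 0, 0.4)),
      EAC = data.frame(arm = c("17p", "4q", "20q", "18q", "21q"),
                       p_gain = c(0, 0, 0.8, 0, 0),
                       p_loss = c(0.9, 0.7, 0, 0.6, 0.3))),
    cn = list(altered_log2 = 0.3, noise_sd = 0.05,
              min_covered_fraction = 0.9, breakpoints_per_arm = 2),
    methylation = list(
      n_genes = 60L, silencing_rate = 0.05,
      differential_gene_rates = c(ESCC1 = 0.40, ESCC2 = 0.05, EAC = 0.05),
      n_subtype_genes = 4L, subtype_rate_in = 0.8, subtype_rate_out = 0.02,
      beta_low = c(2, 30), beta_high = c(10, 4),
      suppression_factor = 0.05,
      baseline_log10_mean = 1, baseline_log10_sd = 0.3,
      sample_log10_sd = 0.2),
    expression = list(
      n_genes = 1000L, baseline_log10_mean = 1, baseline_log10_sd = 0.4,
      sample_log10_sd = 0.3, pathway_size = 30L, effect_log10 = 1.0,
      n_null_pathways = 20L),
    mutations = list(
      n_callers = 3L, per_sample = 100L,
      tumor_depth = 100, normal_depth = 140, normal_error = 0.001,
      vaf_beta = c(2, 5), dropout = 0.05, fp_rate = 0.05,
      fp_blacklist_rate = 0.02, n_blacklist_sites = 200L),
    signatures = list(
      profiles = default_signatures(),
      mixture = rbind(ESCC1 = c(aging = 0.15, apobec = 0.10, smoking = 0.75),
                      ESCC2 = c(aging = 0.15, apobec = 0.70, smoking = 0.15),
                      EAC = c(aging = 0.80, apobec = 0.05, smoking = 0.15)),
      concentration = 50))
  over <- list(...)
  ## parameter sub-lists merge entry-by-entry (shallow, so data.frames and
  ## matrices inside them are replaced wholesale); everything else replaces
  mergeable <- c("cn", "methylation", "expression", "mutations", "signatures")
  for (nm in names(over)) {
    if (nm %in% mergeable && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  for (st in names(cfg$arm_events)) {
    ev <- cfg$arm_events[[st]]
    if (any(ev$p_gain < 0 | ev$p_gain > 1 | ev$p_loss < 0 | ev$p_loss > 1 |
            ev$p_gain + ev$p_loss > 1))
      stop_validation("arm event probabilities for %s out of range", st)
    unknown <- setdiff(ev$arm, cfg$arm_table$arm)
    if (length(unknown))
      stop_validation("unknown arm(s) in config: %s",
                      paste(unknown, collapse = ","))
    uncallable <- ev$arm[!cfg$arm_table$callable[match(ev$arm, cfg$arm_table$arm)]]
    if (length(uncallable))
      stop_validation("events configured on non-callable arm(s): %s",
                      paste(uncallable, collapse = ","))
  }
  check_fraction(cfg$mutations$dropout, "dropout")
  check_fraction(cfg$methylation$silencing_rate, "silencing_rate")
  if (cfg$mutations$tumor_depth <= 0 || cfg$mutations$normal_depth <= 0)
    stop_validation("sequencing depth must be positive")
  invisible(cfg)
}

## sample ids + subtype labels, fixed by seed
.simulate_subtypes <- function(config, seed) {
  n <- config$n_per_subtype[config$subtypes]
  ids <- sprintf("S%03d", seq_len(sum(n)))
  subtype <- rep(config$subtypes, times = n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "subtype_order"))
  o <- sample(length(ids))
  setNames(subtype[o], ids)
}

## tile [a, b) into segments at sorted internal breakpoints
.tile <- function(a, b, breaks) {
  cuts <- sort(unique(c(a, breaks[breaks > a & breaks < b], b)))
  data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
}

#' Simulate segmented copy-number profiles with arm-event truth
#'
#' For each sample and callable arm, plants a gain, loss or no event
#' according to the subtype's configured probabilities. An altered arm
#' carries contiguous segments at log2 `+/- altered_log2` (plus
#' `N(0, noise_sd)` per segment) covering a uniformly drawn fraction of the
#' arm between `min_covered_fraction` and 1, anchored at a random arm end;
#' the remainder, and all neutral arms, carry noise-only segments centred at
#' 0. Segments tile each arm without overlap.
#'
#' @param config from [cohort_config()].
#' @param subtype named per-sample subtype labels.
#' @param seed master seed (the `"copy_number"` substream is used).
#' @return list with `profiles` (named list of [scn_profile()]),
#'   `arm_truth` (samples x callable arms character matrix of
#'   gain/loss/neutral), `cin_truth` (named SCNA_high/SCNA_low vector,
#'   derived from the planted losses with the standard exclusion set).
#' @export
simulate_copy_number <- function(config, subtype, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "copy_number"))
  arms <- config$arm_table[config$arm_table$callable, , drop = FALSE]
  cn <- config$cn
  if (any(arms$end - arms$start < 10 * (cn$breakpoints_per_arm + 1)))
    stop_validation("arm shorter than minimum segment length")
  samples <- names(subtype)
  arm_truth <- matrix("neutral", length(samples), nrow(arms),
                      dimnames = list(samples, arms$arm))
  profiles <- vector("list", length(samples))
  names(profiles) <- samples
  for (s in samples) {
    ev_cfg <- config$arm_events[[subtype[[s]]]]
    seg_rows <- vector("list", nrow(arms))
    for (j in seq_len(nrow(arms))) {
      arm <- arms[j, ]
      p <- c(0, 0)
      if (!is.null(ev_cfg) && arm$arm %in% ev_cfg$arm) {
        row <- ev_cfg[ev_cfg$arm == arm$arm, ]
        p <- c(row$p_gain, row$p_loss)
      }
      event <- sample(c("gain", "loss", "neutral"), 1L,
                      prob = c(p, 1 - sum(p)))
      arm_truth[s, arm$arm] <- event
      len <- arm$end - arm$start
      n_break <- stats::rpois(1L, cn$breakpoints_per_arm)
      breaks <- round(arm$start + stats::runif(n_break) * len)
      if (event == "neutral") {
        segs <- .tile(arm$start, arm$end, breaks)
        segs$log2_ratio <- stats::rnorm(nrow(segs), 0, cn$noise_sd)
      } else {
        f <- stats::runif(1L, cn$min_covered_fraction, 1)
        sign <- if (event == "gain") 1 else -1
        from_p <- stats::runif(1L) < 0.5
        cut <- round(if (from_p) arm$start + f * len else arm$end - f * len)
        alt_iv <- if (from_p) c(arm$start, cut) else c(cut, arm$end)
        neu_iv <- if (from_p) c(cut, arm$end) else c(arm$start, cut)
        segs <- .tile(alt_iv[1L], alt_iv[2L], breaks)
        segs$log2_ratio <- sign * cn$altered_log2 +
          stats::rnorm(nrow(segs), 0, cn$noise_sd)
        if (neu_iv[2L] > neu_iv[1L]) {
          neu <- .tile(neu_iv[1L], neu_iv[2L], breaks)
          neu$log2_ratio <- stats::rnorm(nrow(neu), 0, cn$noise_sd)
          segs <- rbind(segs, neu)
        }
      }
      segs$chrom <- arm$chrom
      segs$n_probes <- pmax(1L, as.integer((segs$end - segs$start) / 1e5))
      seg_rows[[j]] <- segs
    }
    profiles[[s]] <- scn_profile(s, do.call(rbind, seg_rows))
  }
  excluded <- c("18p", "18q", "21p", "21q")
  qual <- arm_truth == "loss" &
    matrix(!colnames(arm_truth) %in% excluded, length(samples),
           ncol(arm_truth), byrow = TRUE)
  cin_truth <- setNames(ifelse(rowSums(qual) > 0, "SCNA_high", "SCNA_low"),
                        samples)
  list(profiles = profiles, arm_truth = arm_truth, cin_truth = cin_truth)
}

#' Simulate coupled promoter methylation and expression with planted silencing
#'
#' Every (gene, sample) pair is silenced independently at the configured
#' baseline rate; one designated gene (the first, an immunomodulatory
#' BST2-like marker) is silenced at subtype-specific rates to plant a
#' subtype-differential silencing signal. Silenced pairs draw promoter beta
#' from the high component and have expression multiplied by the suppression
#' factor; unsilenced pairs draw beta from the low component around their
#' log-normal gene baseline.
#'
#' @param config from [cohort_config()].
#' @param subtype named per-sample subtype labels.
#' @param seed master seed (the `"methylation"` substream is used).
#' @return list with `beta` (probes x samples), `expr_rpkm`
#'   (genes x samples), `probe_map` (data.frame probe, gene), `silenced`
#'   (genes x samples logical truth matrix).
#' @export
simulate_methylation_expression <- function(config, subtype, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "methylation"))
  me <- config$methylation
  samples <- names(subtype)
  genes <- sprintf("MG%03d", seq_len(me$n_genes))
  probes <- sprintf("cg%06d", seq_len(me$n_genes))
  probe_map <- data.frame(probe = probes, gene = genes,
                          stringsAsFactors = FALSE)
  rate <- matrix(me$silencing_rate, me$n_genes, length(samples),
                 dimnames = list(genes, samples))
  rate[1L, ] <- me$differential_gene_rates[subtype[samples]]
  ## subtype-marker genes: hypermethylated-and-silenced predominantly in one
  ## subtype (mirrors subtype-patterned hypermethylation such as the
  ## ESCC3-like hypermethylated class), making the platform informative for
  ## integrative clustering
  ns <- me$n_subtype_genes %||% 0L
  if (ns > 0L) {
    if (me$n_genes < 1L + ns * length(config$subtypes))
      stop_validation("n_genes too small for the subtype-marker genes")
    for (i in seq_along(config$subtypes)) {
      rows <- 1L + ((i - 1L) * ns + 1L):(i * ns)
      rate[rows, ] <- me$subtype_rate_out
      rate[rows, subtype[samples] == config$subtypes[i]] <- me$subtype_rate_in
    }
  }
  silenced <- matrix(stats::runif(length(rate)) < rate, me$n_genes,
                     length(samples), dimnames = dimnames(rate))
  beta <- matrix(NA_real_, me$n_genes, length(samples),
                 dimnames = list(probes, samples))
  beta[!silenced] <- stats::rbeta(sum(!silenced), me$beta_low[1L], me$beta_low[2L])
  beta[silenced] <- stats::rbeta(sum(silenced), me$beta_high[1L], me$beta_high[2L])
  baseline <- 10^stats::rnorm(me$n_genes, me$baseline_log10_mean,
                              me$baseline_log10_sd)
  expr <- baseline * 10^matrix(stats::rnorm(length(rate), 0, me$sample_log10_sd),
                               me$n_genes, length(samples))
  expr[silenced] <- expr[silenced] * me$suppression_factor
  dimnames(expr) <- list(genes, samples)
  list(beta = omics_matrix(beta, "beta"),
       expr_rpkm = omics_matrix(expr, "RPKM"),
       probe_map = probe_map, silenced = silenced)
}

#' Simulate a subtype-structured expression matrix with planted pathways
#'
#' Genes have log-normal baselines; every gene adds sample-level log-normal
#' noise. One planted pathway per subtype shares a common upward shift
#' (default 1.0 on the log10 scale) in that subtype's samples; the remaining
#' genes are exchangeable between subtypes. Null pathways (random gene sets
#' of the same size) are generated alongside for calibration work.
#'
#' @param config from [cohort_config()].
#' @param subtype named per-sample subtype labels.
#' @param seed master seed (the `"expression"` substream is used).
#' @return list with `expr_rpkm` (genes x samples), `gene_sets` (planted
#'   differential pathways first, then null sets), `differential_pathways`
#'   (named character: pathway -> subtype shifted up).
#' @export
simulate_expression_subtypes <- function(config, subtype, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "expression"))
  ex <- config$expression
  samples <- names(subtype)
  genes <- sprintf("G%04d", seq_len(ex$n_genes))
  k <- ex$pathway_size
  subtypes <- config$subtypes
  if (ex$n_genes < k * length(subtypes))
    stop_validation("too few genes for the planted pathways")
  logx <- matrix(stats::rnorm(ex$n_genes, ex$baseline_log10_mean,
                              ex$baseline_log10_sd),
                 ex$n_genes, length(samples)) +
    matrix(stats::rnorm(ex$n_genes * length(samples), 0, ex$sample_log10_sd),
           ex$n_genes, length(samples))
  dimnames(logx) <- list(genes, samples)
  gene_sets <- list()
  differential <- character(0)
  for (i in seq_along(subtypes)) {
    members <- genes[((i - 1L) * k + 1L):(i * k)]
    nm <- sprintf("PLANTED_%s", subtypes[i])
    gene_sets[[nm]] <- members
    differential[nm] <- subtypes[i]
    logx[members, subtype[samples] == subtypes[i]] <-
      logx[members, subtype[samples] == subtypes[i]] + ex$effect_log10
  }
  pool <- genes
  for (j in seq_len(ex$n_null_pathways))
    gene_sets[[sprintf("NULL_%03d", j)]] <- sample(pool, k)
  attr(gene_sets, "descriptions") <-
    setNames(c(paste("planted differential pathway, up in",
                     subtypes),
               rep("random null pathway", ex$n_null_pathways)),
             names(gene_sets))
  list(expr_rpkm = omics_matrix(10^logx, "RPKM"),
       gene_sets = gene_sets, differential_pathways = differential)
}

## draw one trinucleotide bin index per mutation from a 96-probability vector
.draw_contexts <- function(n, probs) {
  sample.int(96L, n, replace = TRUE, prob = probs)
}

.bin_parts <- function(bin_idx) {
  bins <- context_bins()[bin_idx]
  data.frame(ref = substr(bins, 3L, 3L), alt = substr(bins, 5L, 5L),
             context = paste0(substr(bins, 1L, 1L), substr(bins, 3L, 3L),
                              substr(bins, 7L, 7L)),
             stringsAsFactors = FALSE)
}

#' Simulate multi-caller somatic variant call sets
#'
#' True variants per sample draw their trinucleotide context from the
#' sample's signature mixture (a Dirichlet perturbation of the subtype
#' mixture), their allele fraction from Beta(2, 5), tumour alt counts from
#' Binomial(depth, VAF) and normal alt counts from Binomial(depth, error
#' rate). Each caller reports each true variant with probability
#' 1 - dropout and adds false positives: low-support records (1-2 alt
#' reads) and records at 1000 Genomes blacklist sites. Half of the true
#' records are emitted in the purine-strand representation to exercise the
#' catalog's strand collapse. Orientation counts split alt reads
#' binomially, as real (artifact-free) variants do.
#'
#' @param config from [cohort_config()].
#' @param subtype named per-sample subtype labels.
#' @param seed master seed (the `"mutations"` substream is used).
#' @return list with `call_sets` (named list of per-caller variant
#'   data.frames), `truth` (data.frame of true variants incl. context and
#'   exposure-drawn bins), `exposures` (samples x signatures fractions),
#'   `germline_sites` (blacklist data.frame chrom/pos/alt).
#' @export
simulate_mutation_callsets <- function(config, subtype, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "mutations"))
  mu <- config$mutations
  sg <- config$signatures
  if (mu$n_callers < 2L) stop_validation("need >= 2 callers")
  samples <- names(subtype)
  profiles <- sg$profiles

  ## per-sample signature exposures: Dirichlet around the subtype mixture
  rdirichlet1 <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    x / sum(x)
  }
  exposures <- t(vapply(samples, function(s)
    rdirichlet1(sg$mixture[subtype[[s]], ] * sg$concentration),
    numeric(nrow(profiles))))
  dimnames(exposures) <- list(samples, rownames(profiles))

  ## each blacklist site carries fixed alleles/context, as a real germline
  ## SNP would, so independent callers hitting one site agree on the record
  site_parts <- .bin_parts(.draw_contexts(mu$n_blacklist_sites,
                                          rep(1 / 96, 96)))
  germline_sites <- data.frame(
    chrom = as.character(sample(1:22, mu$n_blacklist_sites, replace = TRUE)),
    pos = sample.int(1e8, mu$n_blacklist_sites),
    alt = NA_character_, ref = site_parts$ref, site_alt = site_parts$alt,
    context = site_parts$context, stringsAsFactors = FALSE)

  truth <- list()
  per_caller <- replicate(mu$n_callers, list(), simplify = FALSE)
  caller_names <- sprintf("caller%d", seq_len(mu$n_callers))
  for (s in samples) {
    n <- mu$per_sample
    probs <- as.vector(t(profiles) %*% exposures[s, ])
    parts <- .bin_parts(.draw_contexts(n, probs))
    vaf <- stats::rbeta(n, mu$vaf_beta[1L], mu$vaf_beta[2L])
    t_depth <- stats::rpois(n, mu$tumor_depth)
    t_alt <- stats::rbinom(n, t_depth, vaf)
    n_depth <- stats::rpois(n, mu$normal_depth)
    n_alt <- stats::rbinom(n, n_depth, mu$normal_error)
    ## emit half on the purine strand
    flip <- stats::runif(n) < 0.5
    ref <- ifelse(flip, chartr("ACGT", "TGCA", parts$ref), parts$ref)
    alt <- ifelse(flip, chartr("ACGT", "TGCA", parts$alt), parts$alt)
    ctx <- parts$context
    ctx[flip] <- .revcomp(ctx[flip])
    f1r2 <- stats::rbinom(n, t_alt, 0.5)
    v <- data.frame(
      sample = s,
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n), ref = ref, alt = alt,
      t_ref_count = t_depth - t_alt, t_alt_count = t_alt,
      n_ref_count = n_depth - n_alt, n_alt_count = n_alt,
      caller = NA_character_, context = ctx,
      alt_f1r2 = f1r2, alt_f2r1 = t_alt - f1r2,
      true_vaf = vaf, stringsAsFactors = FALSE)
    truth[[s]] <- v
    for (ci in seq_len(mu$n_callers)) {
      seen <- stats::runif(n) >= mu$dropout
      calls <- v[seen, setdiff(names(v), "true_vaf"), drop = FALSE]
      calls$caller <- caller_names[ci]
      n_fp <- stats::rbinom(1L, n, mu$fp_rate)
      n_bl <- stats::rbinom(1L, n, mu$fp_blacklist_rate)
      if (n_fp > 0) {
        fp_parts <- .bin_parts(.draw_contexts(n_fp, rep(1 / 96, 96)))
        fp_depth <- stats::rpois(n_fp, mu$tumor_depth)
        fp_alt <- sample(1:2, n_fp, replace = TRUE)
        fpn_depth <- stats::rpois(n_fp, mu$normal_depth)
        fp <- data.frame(
          sample = s, chrom = as.character(sample(1:22, n_fp, replace = TRUE)),
          pos = sample.int(2e8, n_fp), ref = fp_parts$ref, alt = fp_parts$alt,
          t_ref_count = pmax(fp_depth - fp_alt, 0L), t_alt_count = fp_alt,
          n_ref_count = fpn_depth, n_alt_count = 0L,
          caller = caller_names[ci], context = fp_parts$context,
          alt_f1r2 = fp_alt, alt_f2r1 = 0L, stringsAsFactors = FALSE)
        calls <- rbind(calls, fp)
      }
      if (n_bl > 0) {
        idx <- sample.int(nrow(germline_sites), n_bl)
        bl_parts <- germline_sites[idx, c("ref", "site_alt", "context")]
        names(bl_parts)[2L] <- "alt"
        bl_depth <- stats::rpois(n_bl, mu$tumor_depth)
        bl_alt <- stats::rbinom(n_bl, bl_depth, 0.5)
        bln_depth <- stats::rpois(n_bl, mu$normal_depth)
        bl_f1 <- stats::rbinom(n_bl, bl_alt, 0.5)
        bl <- data.frame(
          sample = s, chrom = germline_sites$chrom[idx],
          pos = germline_sites$pos[idx],
          ref = bl_parts$ref, alt = bl_parts$alt,
          t_ref_count = bl_depth - bl_alt, t_alt_count = bl_alt,
          n_ref_count = bln_depth, n_alt_count = 0L,
          caller = caller_names[ci], context = bl_parts$context,
          alt_f1r2 = bl_f1, alt_f2r1 = bl_alt - bl_f1,
          stringsAsFactors = FALSE)
        calls <- rbind(calls, bl)
      }
      per_caller[[ci]][[s]] <- calls
    }
  }
  call_sets <- lapply(per_caller, function(x) {
    d <- do.call(rbind, x)
    rownames(d) <- NULL
    d
  })
  names(call_sets) <- caller_names
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(call_sets = call_sets, truth = truth, exposures = exposures,
       germline_sites = germline_sites)
}

#' Simulate a complete multi-platform cohort with ground truth
#'
#' Runs every platform generator off independent substreams of one master
#' seed and bundles the outputs with a truth object recording subtype
#' labels, planted arm events and derived CIN labels, silenced (gene,
#' sample) pairs, true somatic variants, per-sample signature exposures and
#' the planted differential pathways.
#'
#' @param config from [cohort_config()].
#' @param seed master seed.
#' @return list of class `"synthetic_cohort"` with elements `truth`,
#'   `profiles`, `beta`, `meth_expr_rpkm`, `probe_map`, `expr_rpkm`,
#'   `gene_sets`, `call_sets`, `germline_sites`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  subtype <- .simulate_subtypes(config, seed)
  cn <- simulate_copy_number(config, subtype, seed)
  me <- simulate_methylation_expression(config, subtype, seed)
  ex <- simulate_expression_subtypes(config, subtype, seed)
  muts <- simulate_mutation_callsets(config, subtype, seed)
  truth <- list(sample_ids = names(subtype), subtype = subtype,
                arm_events = cn$arm_truth, cin_label = cn$cin_truth,
                silenced = me$silenced, variants = muts$truth,
                exposures = muts$exposures,
                differential_pathways = ex$differential_pathways,
                seed = seed)
  stopifnot(all(abs(rowSums(truth$exposures) - 1) < 1e-9))
  structure(list(truth = truth, profiles = cn$profiles, beta = me$beta,
                 meth_expr_rpkm = me$expr_rpkm, probe_map = me$probe_map,
                 expr_rpkm = ex$expr_rpkm, gene_sets = ex$gene_sets,
                 call_sets = muts$call_sets,
                 germline_sites = muts$germline_sites,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%s), seed %d\n",
              length(x$truth$sample_ids),
              paste(names(table(x$truth$subtype)),
                    table(x$truth$subtype), sep = "=", collapse = ", "),
              x$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Writes the cohort SEG file, one MAF per caller, expression and beta-value
#' matrix TSVs, the probe map, the pathway GMT, the germline-site BED and a
#' truth JSON. Every table carries a provenance comment with the seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("esomics synthetic cohort, seed %d", cohort$seed)
  write_seg(cohort$profiles, file.path(dir, "cohort.seg"), comments = prov)
  for (nm in names(cohort$call_sets))
    write_maf(cohort$call_sets[[nm]], file.path(dir, paste0(nm, ".maf")),
              comments = prov)
  write_matrix_tsv(cohort$expr_rpkm, file.path(dir, "expression_rpkm.tsv"),
                   id_column = "gene", comments = prov)
  write_matrix_tsv(cohort$meth_expr_rpkm,
                   file.path(dir, "meth_expression_rpkm.tsv"),
                   id_column = "gene", comments = prov)
  write_matrix_tsv(cohort$beta, file.path(dir, "methylation_beta.tsv"),
                   id_column = "probe", comments = prov)
  utils::write.table(cohort$probe_map, file.path(dir, "probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "pathways.gmt"))
  utils::write.table(
    data.frame(cohort$germline_sites$chrom, cohort$germline_sites$pos,
               cohort$germline_sites$pos + 1),
    file.path(dir, "germline_sites.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- cohort$truth
  truth$arm_events <- as.data.frame(truth$arm_events)
  truth$silenced <- as.data.frame(truth$silenced)
  truth$exposures <- as.data.frame(truth$exposures)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
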