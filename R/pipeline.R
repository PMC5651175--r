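## End-to-end orchestration: simulate (or load) a cohort, then run
## cin-call -> merge/filter mutations -> signatures -> pathway scores ->
## silencing -> per-platform clustering -> COCA/SuperCluster integration,
## writing every stage's table with a provenance header and a final
## per-sample summary. Stages are thin compositions of the exported module
## functions and are independently skippable when their inputs are absent.

#' Per-arm mean log2 ratio matrix for a cohort
#'
#' Overlap-length-weighted mean segment log2 ratio per (callable arm,
#' sample); used as the copy-number feature block for integrative
#' clustering. Arms without covering segments get 0.
#'
#' @param profiles named list of [scn_profile()] objects.
#' @param arm_table arm table (default [default_arm_table()]).
#' @return arms x samples numeric matrix.
#' @export
arm_mean_log2 <- function(profiles, arm_table = default_arm_table()) {
  arms <- arm_table[arm_table$callable, , drop = FALSE]
  out <- matrix(0, nrow(arms), length(profiles),
                dimnames = list(arms$arm,
                                vapply(profiles, `[[`, character(1L),
                                       "sample_id")))
  for (i in seq_along(profiles)) {
    s <- profiles[[i]]$segments
    for (j in seq_len(nrow(arms))) {
      k <- normalize_chrom(s$chrom) == arms$chrom[j]
      ov <- pmax(0, pmin(s$end[k], arms$end[j]) - pmax(s$start[k], arms$start[j]))
      if (sum(ov) > 0)
        out[j, i] <- sum(ov * s$log2_ratio[k]) / sum(ov)
    }
  }
  out
}

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed, recorded in every output header.
#' @param simulate if `TRUE` (default) the cohort is generated with
#'   `sim_config`; otherwise `files` must point at the platform inputs.
#' @param sim_config [cohort_config()] for the simulated cohort.
#' @param files named list of input paths for a real cohort: `seg`, `mafs`
#'   (vector), `germline` (BED), `expr`, `beta`, `probe_map`, `gmt`,
#'   `subtypes` (2-column TSV sample/label). Any may be omitted; dependent
#'   stages are skipped.
#' @param k_integrated clusters for the integrated partition (default: the
#'   number of simulated subtypes, else 3).
#' @param n_perm pathway permutations (default 1000 at pipeline scale).
#' @param nmf_restarts ARD-NMF restarts (default 5).
#' @param integration `"COCA"` or `"SuperCluster"`.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            sim_config = cohort_config(), files = list(),
                            k_integrated = NULL, n_perm = 1000L,
                            nmf_restarts = 5L,
                            integration = c("COCA", "SuperCluster")) {
  list(out_dir = out_dir, seed = seed, simulate = simulate,
       sim_config = sim_config, files = files,
       k_integrated = k_integrated, n_perm = n_perm,
       nmf_restarts = nmf_restarts, integration = match.arg(integration))
}

.stage <- function(name, expr) {
  message(sprintf("[esomics] stage %s ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' @param config from [pipeline_config()].
#' @return list with each stage's in-memory result (`cin`, `mutations`,
#'   `signatures`, `pathways`, `silencing`, `clustering`, `summary`) plus
#'   the inputs used; outputs are also written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("esomics %s | seed %d",
                  as.character(utils::packageVersion("esomics")), config$seed)
  inputs <- .stage("inputs", .pipeline_inputs(config))
  subtype <- inputs$subtype
  k <- config$k_integrated %||%
    (if (!is.null(subtype)) length(unique(subtype)) else 3L)
  res <- list(inputs = inputs)

  if (!is.null(inputs$profiles)) {
    res$cin <- .stage("cin-call", cohort_cin(inputs$profiles))
    utils::write.table(res$cin$cin_calls,
                       file.path(config$out_dir, "cin_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[esomics]   %d/%d samples SCNA-high",
                    sum(res$cin$cin_calls$label == "SCNA_high"),
                    nrow(res$cin$cin_calls)))
  }

  if (!is.null(inputs$call_sets)) {
    res$mutations <- .stage("merge-mutations",
                            filter_mutations(inputs$call_sets,
                                             germline_sites = inputs$germline_sites))
    write_maf(res$mutations$kept, file.path(config$out_dir, "merged.maf"),
              comments = prov)
    rej <- res$mutations$rejects
    utils::write.table(rej[, c("sample", "chrom", "pos", "ref", "alt", "reasons")],
                       file.path(config$out_dir, "rejects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[esomics]   %d merged, %d kept, %d rejected",
                    nrow(res$mutations$decisions), nrow(res$mutations$kept),
                    nrow(rej)))
    catalog <- build_catalog(res$mutations$kept)
    res$signatures <- .stage("signatures",
                             ard_nmf(catalog, n_restarts = config$nmf_restarts,
                                     seed = derive_seed(config$seed, "nmf")))
    fr <- signature_fractions(res$signatures)
    write_matrix_tsv(t(fr), file.path(config$out_dir, "signature_fractions.tsv"),
                     id_column = "signature", comments = prov)
  }

  if (!is.null(inputs$expr) && !is.null(subtype)) {
    res$pathways <- .stage("pathway-score",
                           score_all_pathways(inputs$expr, subtype,
                                              inputs$gene_sets,
                                              n_perm = config$n_perm,
                                              seed = derive_seed(config$seed,
                                                                 "pathways")))
    utils::write.table(res$pathways,
                       file.path(config$out_dir, "pathway_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(inputs$beta) && !is.null(inputs$meth_expr)) {
    res$silencing <- .stage("silencing", {
      calls <- call_silencing_matrix(inputs$beta,
                                     log2(inputs$meth_expr + 1),
                                     inputs$probe_map)
      assoc <- NULL
      if (!is.null(subtype) && length(unique(subtype)) >= 2L) {
        two <- names(sort(table(subtype), decreasing = TRUE))[1:2]
        keep <- colnames(calls$calls)[subtype[colnames(calls$calls)] %in% two]
        assoc <- silencing_subtype_association(
          calls$calls[, keep, drop = FALSE], subtype[keep])
      }
      list(calls = calls, association = assoc)
    })
    if (!is.null(res$silencing$association))
      utils::write.table(res$silencing$association,
                         file.path(config$out_dir, "silencing_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else message("[esomics] stage silencing skipped (no methylation input)")

  if (!is.null(inputs$expr)) {
    res$clustering <- .stage("cluster", {
      feats <- select_features(inputs$expr, fraction = 0.25, min_mean = 10)
      tr <- transform_for_clustering(inputs$expr[feats, , drop = FALSE])
      platforms <- list(mrna = hierarchical_cluster(tr, k = k,
                                                    platform = "mrna"))
      if (!is.null(inputs$beta))
        platforms$methylation <- hierarchical_cluster(
          inputs$beta, k = k, col_distance = "euclidean",
          platform = "methylation")
      if (!is.null(inputs$profiles))
        platforms$scna <- hierarchical_cluster(
          arm_mean_log2(inputs$profiles), k = k, col_distance = "euclidean",
          platform = "scna")
      if (length(platforms) >= 2L)
        integrate_clusters(platforms, method = config$integration, k = k)
      else platforms[[1L]]
    })
  }

  ## per-subtype CIN enrichment (each subtype vs the rest, exact Fisher)
  if (!is.null(res$cin) && !is.null(subtype)) {
    cin_high <- res$cin$cin_calls$label == "SCNA_high"
    st <- subtype[res$cin$cin_calls$sample]
    res$cin_enrichment <- do.call(rbind, lapply(unique(st), function(g) {
      a <- sum(cin_high & st == g); b <- sum(!cin_high & st == g)
      c <- sum(cin_high & st != g); d <- sum(!cin_high & st != g)
      data.frame(subtype = g, n_scna_high = a, n = a + b,
                 fisher_p = fisher_exact_2x2(a, b, c, d),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(res$cin_enrichment,
                       file.path(config$out_dir, "cin_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  res$summary <- .pipeline_summary(res, subtype)
  con <- file(file.path(config$out_dir, "summary.tsv"), "w")
  writeLines(paste0("# ", prov), con)
  utils::write.table(res$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(res)
}

.pipeline_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(config$sim_config, seed = config$seed)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    return(list(profiles = cohort$profiles, call_sets = cohort$call_sets,
                germline_sites = cohort$germline_sites,
                expr = cohort$expr_rpkm, gene_sets = cohort$gene_sets,
                beta = cohort$beta, meth_expr = cohort$meth_expr_rpkm,
                probe_map = cohort$probe_map,
                subtype = cohort$truth$subtype, truth = cohort$truth))
  }
  f <- config$files
  inputs <- list()
  if (!is.null(f$seg)) inputs$profiles <- read_seg(f$seg)
  if (!is.null(f$mafs)) inputs$call_sets <- lapply(f$mafs, read_maf)
  if (!is.null(f$germline)) inputs$germline_sites <- read_site_list(f$germline)
  if (!is.null(f$expr)) inputs$expr <- read_matrix_tsv(f$expr, "RPKM")
  if (!is.null(f$gmt)) inputs$gene_sets <- read_gmt(f$gmt)
  if (!is.null(f$beta)) inputs$beta <- read_matrix_tsv(f$beta, "beta")
  if (!is.null(f$meth_expr)) inputs$meth_expr <- read_matrix_tsv(f$meth_expr, "RPKM")
  if (!is.null(f$probe_map))
    inputs$probe_map <- utils::read.delim(f$probe_map, stringsAsFactors = FALSE)
  if (!is.null(f$subtypes)) {
    d <- utils::read.delim(f$subtypes, header = TRUE, stringsAsFactors = FALSE)
    inputs$subtype <- setNames(d[[2L]], d[[1L]])
  }
  inputs
}

.pipeline_summary <- function(res, subtype) {
  samples <- if (!is.null(res$cin)) res$cin$cin_calls$sample
  else if (!is.null(subtype)) names(subtype)
  else if (!is.null(res$clustering)) names(res$clustering$labels)
  else character(0)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  if (!is.null(subtype)) out$subtype <- unname(subtype[samples])
  if (!is.null(res$cin))
    out$cin_label <- res$cin$cin_calls$label[match(samples,
                                                   res$cin$cin_calls$sample)]
  if (!is.null(res$clustering) && !is.null(res$clustering$labels))
    out$integrated_cluster <- unname(res$clustering$labels[samples])
  if (!is.null(res$signatures)) {
    fr <- signature_fractions(res$signatures)
    for (sg in colnames(fr))
      out[[paste0("fraction_", sg)]] <- unname(fr[match(samples,
                                                        rownames(fr)), sg])
  }
  out
}
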