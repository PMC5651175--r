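## Readers and writers for the plain-text formats the pipeline consumes:
## SEG segment tables, MAF-like mutation tables, GMT gene-set collections,
## feature-by-sample matrix TSVs and a BED-like chromosome-arm table.
##
## One coordinate convention holds internally everywhere: 0-based, half-open.
## SEG files are read/written 1-based inclusive by default (the common
## dialect); the arm table is BED-like and therefore already half-open.

.read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}

.match_column <- function(header, aliases, what, path) {
  idx <- which(tolower(header) %in% tolower(aliases))
  if (length(idx) == 0L)
    stop_validation("%s: no column for %s (accepted: %s)", path, what,
                    paste(aliases, collapse = ", "))
  idx[1L]
}

#' Construct a validated segmented copy-number profile
#'
#' @param sample_id sample label.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `log2_ratio` and optionally `n_probes`; coordinates 0-based half-open.
#' @return an object of class `"scn_profile"`.
#' @export
scn_profile <- function(sample_id, segments) {
  stopifnot(is.data.frame(segments))
  need <- c("chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(segments)))
    stop_validation("segments need columns %s", paste(need, collapse = ", "))
  if (!"n_probes" %in% names(segments)) segments$n_probes <- NA_integer_
  segments$chrom <- normalize_chrom(segments$chrom)
  if (any(!is.finite(segments$log2_ratio)))
    stop_validation("sample %s: non-finite log2 ratio", sample_id)
  if (any(segments$start >= segments$end))
    stop_validation("sample %s: segment with start >= end", sample_id)
  o <- order(segments$chrom, segments$start, segments$end)
  segments <- segments[o, c("chrom", "start", "end", "log2_ratio", "n_probes"),
                       drop = FALSE]
  rownames(segments) <- NULL
  ## overlapping segments within a chromosome are legal input but worth flagging
  by_chr <- split(segments, segments$chrom)
  overlaps <- vapply(by_chr, function(s) {
    nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])
  }, logical(1L))
  if (any(overlaps))
    warning(sprintf("sample %s: overlapping segments on chromosome(s) %s",
                    sample_id, paste(names(by_chr)[overlaps], collapse = ", ")),
            call. = FALSE)
  structure(list(sample_id = sample_id, segments = segments),
            class = "scn_profile")
}

#' @export
print.scn_profile <- function(x, ...) {
  cat(sprintf("<scn_profile> sample %s: %d segments on %d chromosome(s)\n",
              x$sample_id, nrow(x$segments), length(unique(x$segments$chrom))))
  invisible(x)
}

#' Read a SEG file of segmented copy-number profiles
#'
#' Expects a tab-separated file with a header naming sample, chromosome,
#' start, end and segment-mean columns (`Sample`/`ID`, `Chromosome`/`chrom`,
#' `Start`/`loc.start`, `End`/`loc.end`, `Segment_Mean`/`seg.mean`;
#' `Num_Probes` is optional). Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path file path.
#' @param convention coordinate convention of the file, `"one_based_inclusive"`
#'   (the usual SEG dialect, default) or `"zero_based_half_open"`.
#' @return a named list of [scn_profile()] objects, one per sample, segments
#'   sorted by (chromosome, start).
#' @export
read_seg <- function(path, convention = c("one_based_inclusive",
                                          "zero_based_half_open")) {
  convention <- match.arg(convention)
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) stop_validation("%s: empty file, no header", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  i_sam <- .match_column(header, c("sample", "id", "sample_id"), "sample id", path)
  i_chr <- .match_column(header, c("chromosome", "chrom", "chr"), "chromosome", path)
  i_sta <- .match_column(header, c("start", "loc.start", "start_position"), "start", path)
  i_end <- .match_column(header, c("end", "loc.end", "end_position"), "end", path)
  i_mean <- .match_column(header, c("segment_mean", "seg.mean", "log2", "mean"),
                          "segment mean", path)
  i_np <- which(tolower(header) %in% c("num_probes", "n_probes", "num.mark"))[1]
  if (length(lines) == 1L) return(structure(list(), names = character(0)))

  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < max(i_sam, i_chr, i_sta, i_end, i_mean)))
    stop_validation("%s: malformed row at line %d",
                    path, which(nf < length(header))[1L] + 1L)
  get <- function(i) vapply(fields, `[[`, character(1L), i)
  start <- suppressWarnings(as.double(get(i_sta)))
  end <- suppressWarnings(as.double(get(i_end)))
  log2r <- suppressWarnings(as.double(get(i_mean)))
  bad <- which(is.na(start) | is.na(end) | is.na(log2r))
  if (length(bad))
    stop_validation("%s: malformed row at line %d (non-numeric field)",
                    path, bad[1L] + 1L)
  if (convention == "one_based_inclusive") start <- start - 1
  d <- data.frame(sample = get(i_sam),
                  chrom = get(i_chr),
                  start = start, end = end, log2_ratio = log2r,
                  n_probes = if (!is.na(i_np))
                    suppressWarnings(as.integer(get(i_np))) else NA_integer_,
                  stringsAsFactors = FALSE)
  bad <- which(d$start >= d$end)
  if (length(bad))
    stop_validation("%s: start >= end after coordinate conversion at line %d",
                    path, bad[1L] + 1L)
  profiles <- lapply(split(d, d$sample), function(s)
    scn_profile(s$sample[1L], s[, -1L, drop = FALSE]))
  profiles[unique(d$sample)]
}

#' Write segmented profiles as a SEG file
#'
#' @param profiles named list of [scn_profile()] objects.
#' @param path output path.
#' @param convention coordinate convention to write (default 1-based inclusive).
#' @param comments optional character vector of provenance lines, written as
#'   leading `#` comments.
#' @export
write_seg <- function(profiles, path,
                      convention = c("one_based_inclusive", "zero_based_half_open"),
                      comments = NULL) {
  convention <- match.arg(convention)
  rows <- lapply(profiles, function(p) {
    s <- p$segments
    data.frame(Sample = p$sample_id, Chromosome = s$chrom,
               Start = if (convention == "one_based_inclusive") s$start + 1 else s$start,
               End = s$end, Num_Probes = s$n_probes, Segment_Mean = s$log2_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  if (is.null(out))
    out <- data.frame(Sample = character(), Chromosome = character(),
                      Start = double(), End = double(),
                      Num_Probes = integer(), Segment_Mean = double())
  utils::write.table(format(out, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within one set are removed with a warning.
#'
#' @param path file path.
#' @return named list of character gene vectors, with a `"descriptions"`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- .read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_validation("%s: line %d has fewer than 3 fields", path, short[1L])
  nms <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set %s: duplicated gene(s) removed", f[1L]), call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors (as from [read_gmt()]).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), character(1L)), path)
  invisible(path)
}

## canonical internal column set of a variant-call table
.maf_columns <- c("sample", "chrom", "pos", "ref", "alt",
                  "t_ref_count", "t_alt_count", "n_ref_count", "n_alt_count",
                  "caller", "context", "alt_f1r2", "alt_f2r1")

#' Read a MAF-like somatic variant table
#'
#' The minimal required columns are sample, chromosome, position (1-based in
#' the file), reference and alternate alleles, tumour ref/alt read counts and
#' normal ref/alt read counts; caller label, trinucleotide context and
#' F1R2/F2R1 orientation counts are optional and stay `NA` when absent
#' (missing data is never coerced to zero). Positions become 0-based
#' internally.
#'
#' @param path file path.
#' @return data.frame with columns
#'   `sample, chrom, pos, ref, alt, t_ref_count, t_alt_count, n_ref_count,
#'   n_alt_count, caller, context, alt_f1r2, alt_f2r1`.
#' @export
read_maf <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) stop_validation("%s: empty file, no header", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  col <- function(aliases, what) .match_column(header, aliases, what, path)
  opt <- function(aliases) which(tolower(header) %in% tolower(aliases))[1]
  i <- list(
    sample = col(c("sample", "tumor_sample_barcode", "sample_id"), "sample"),
    chrom = col(c("chromosome", "chrom", "chr"), "chromosome"),
    pos = col(c("position", "start_position", "pos"), "position"),
    ref = col(c("ref", "reference_allele"), "reference allele"),
    alt = col(c("alt", "tumor_seq_allele2", "alternate_allele"), "alternate allele"),
    t_ref_count = col("t_ref_count", "tumour ref count"),
    t_alt_count = col("t_alt_count", "tumour alt count"),
    n_ref_count = col("n_ref_count", "normal ref count"),
    n_alt_count = col("n_alt_count", "normal alt count"))
  iopt <- list(caller = opt(c("caller", "center", "centre")),
               context = opt(c("context", "trinucleotide_context", "ref_context")),
               alt_f1r2 = opt("alt_f1r2"), alt_f2r1 = opt("alt_f2r1"))
  if (length(lines) == 1L) {
    empty <- data.frame(sample = character(), chrom = character(), pos = double(),
                        ref = character(), alt = character(),
                        t_ref_count = integer(), t_alt_count = integer(),
                        n_ref_count = integer(), n_alt_count = integer(),
                        caller = character(), context = character(),
                        alt_f1r2 = integer(), alt_f2r1 = integer())
    return(empty)
  }
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(fields) < length(header)))
    stop_validation("%s: malformed row at line %d", path,
                    which(lengths(fields) < length(header))[1L] + 1L)
  get <- function(j) vapply(fields, `[[`, character(1L), j)
  geti <- function(j) suppressWarnings(as.integer(get(j)))
  d <- data.frame(
    sample = get(i$sample), chrom = normalize_chrom(get(i$chrom)),
    pos = as.double(get(i$pos)) - 1,
    ref = get(i$ref), alt = get(i$alt),
    t_ref_count = geti(i$t_ref_count), t_alt_count = geti(i$t_alt_count),
    n_ref_count = geti(i$n_ref_count), n_alt_count = geti(i$n_alt_count),
    caller = if (!is.na(iopt$caller)) {
      cl <- get(iopt$caller); cl[!nzchar(cl) | cl == "NA"] <- NA_character_; cl
    } else NA_character_,
    context = if (!is.na(iopt$context)) {
      ctx <- get(iopt$context); ctx[!nzchar(ctx) | ctx == "NA"] <- NA_character_; ctx
    } else NA_character_,
    alt_f1r2 = if (!is.na(iopt$alt_f1r2)) geti(iopt$alt_f1r2) else NA_integer_,
    alt_f2r1 = if (!is.na(iopt$alt_f2r1)) geti(iopt$alt_f2r1) else NA_integer_,
    stringsAsFactors = FALSE)
  counts <- d[, c("t_ref_count", "t_alt_count", "n_ref_count", "n_alt_count")]
  if (any(as.matrix(counts) < 0, na.rm = TRUE))
    stop_validation("%s: negative read count", path)
  if (any(d$ref == d$alt))
    stop_validation("%s: record with ref == alt", path)
  d
}

#' Write a MAF-like somatic variant table
#' @param variants data.frame in the [read_maf()] column layout (0-based `pos`).
#' @param path output path.
#' @param comments optional provenance comment lines.
#' @export
write_maf <- function(variants, path, comments = NULL) {
  stopifnot(all(.maf_columns %in% names(variants)))
  out <- variants[, .maf_columns]
  out$pos <- out$pos + 1  # file dialect is 1-based
  names(out)[names(out) == "pos"] <- "position"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Validate a feature-by-sample omics matrix
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param scale one of `"RPKM"`, `"RPM"`, `"RSEM"`, `"beta"`, `"log2ratio"`,
#'   `"zscore"`. Beta values must lie in `[0, 1]`; linear expression scales
#'   must be non-negative.
#' @return the matrix, with a `"scale"` attribute attached.
#' @export
omics_matrix <- function(values, scale = c("RPKM", "RPM", "RSEM", "beta",
                                           "log2ratio", "zscore")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("omics matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicated feature ids")
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicated sample ids")
  if (scale == "beta" && (min(values, na.rm = TRUE) < 0 ||
                          max(values, na.rm = TRUE) > 1))
    stop_validation("beta values must lie in [0, 1]")
  if (scale %in% c("RPKM", "RPM", "RSEM") && min(values, na.rm = TRUE) < 0)
    stop_validation("%s values must be non-negative", scale)
  attr(values, "scale") <- scale
  values
}

#' Read a feature-by-sample matrix TSV
#'
#' First column holds feature ids, the header holds sample ids.
#'
#' @param path file path.
#' @param scale matrix scale, see [omics_matrix()].
#' @return a validated matrix with a `"scale"` attribute.
#' @export
read_matrix_tsv <- function(path, scale = "RPKM") {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop_validation("%s: expected id column plus samples", path)
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) stop_validation("%s: duplicated feature ids", path)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  omics_matrix(m, scale)
}

#' Write a feature-by-sample matrix TSV
#' @param m matrix with rownames and colnames.
#' @param path output path.
#' @param id_column header name of the feature-id column.
#' @param comments optional provenance comment lines.
#' @export
write_matrix_tsv <- function(m, path, id_column = "feature", comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_column, colnames(m)), collapse = "\t"), con)
  utils::write.table(data.frame(rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like chromosome-arm table
#'
#' Five tab-separated columns: chromosome, start, end, arm name, callable
#' (0/1 or TRUE/FALSE). Coordinates are BED-style 0-based half-open. Arms on
#' one chromosome must not overlap.
#'
#' @param path file path.
#' @return data.frame with columns `chrom, start, end, arm, callable`.
#' @export
read_arm_table <- function(path) {
  d <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 5L) stop_validation("%s: arm table needs 5 columns", path)
  arms <- data.frame(chrom = normalize_chrom(d[[1L]]),
                     start = as.double(d[[2L]]), end = as.double(d[[3L]]),
                     arm = as.character(d[[4L]]),
                     callable = as.logical(as.integer(
                       ifelse(d[[5L]] %in% c("TRUE", "FALSE"),
                              d[[5L]] == "TRUE", d[[5L]]))),
                     stringsAsFactors = FALSE)
  validate_arm_table(arms)
}

#' Validate an arm table
#' @param arms data.frame with columns `chrom, start, end, arm, callable`.
#' @return the validated table (invisibly the same object).
#' @export
validate_arm_table <- function(arms) {
  stopifnot(all(c("chrom", "start", "end", "arm", "callable") %in% names(arms)))
  if (any(arms$end <= arms$start)) stop_validation("arm with end <= start")
  if (anyDuplicated(arms$arm)) stop_validation("duplicated arm names")
  for (s in split(arms, arms$chrom)) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop_validation("overlapping arms on chromosome %s", s$chrom[1L])
  }
  arms
}

#' Write an arm table as BED-like TSV
#' @param arms arm table data.frame.
#' @param path output path.
#' @export
write_arm_table <- function(arms, path) {
  utils::write.table(
    data.frame(arms$chrom, format(arms$start, scientific = FALSE, trim = TRUE),
               format(arms$end, scientific = FALSE, trim = TRUE),
               arms$arm, as.integer(arms$callable)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
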