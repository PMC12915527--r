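#' Read a BED3/BED4 file of peak intervals
#'
#' Parses a tab-separated BED file into a feature table. Coordinates are kept
#' in the native BED convention: 0-based, half-open `[start, end)`. When a
#' fourth column is present it is used as the feature identifier; otherwise an
#' identifier of the form `chrom:start-end` is synthesized.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `feature_id`,
#'   one row per input line, in input order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tpk1", "chr2\t0\t50"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      feature_id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3L)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 tab-separated columns",
                 bad[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) |
                 start_chr != as.character(start) | end_chr != as.character(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end (empty or inverted interval)",
                 bad[1]))
  }
  if (any(!nzchar(chrom))) {
    stop(sprintf("BED parse error at line %d: empty chromosome name",
                 which(!nzchar(chrom))[1]))
  }
  feature_id <- ifelse(n_col >= 4L,
                       vapply(fields, function(f) f[min(4L, length(f))], ""),
                       sprintf("%s:%d-%d", chrom, start, end))
  fs <- data.frame(chrom = chrom, start = start, end = end,
                   feature_id = feature_id, stringsAsFactors = FALSE)
  validate_feature_set(fs)
  fs
}

#' Write a feature table as BED4
#'
#' @param features Feature table as returned by [read_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(features, path) {
  validate_feature_set(features)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s", features$chrom, features$start,
                     features$end, features$feature_id), con)
  invisible(path)
}

validate_feature_set <- function(fs) {
  stopifnot(is.data.frame(fs),
            all(c("chrom", "start", "end", "feature_id") %in% names(fs)))
  if (anyDuplicated(fs$feature_id)) {
    stop("duplicate feature_id in feature set: ",
         fs$feature_id[anyDuplicated(fs$feature_id)])
  }
  if (nrow(fs) && any(fs$start >= fs$end)) stop("feature set has start >= end")
  invisible(fs)
}

#' Read a sample design table
#'
#' The design is an explicit TSV (never inferred from sample-id strings) with
#' columns `sample_id`, `assay`, `condition`, `washout_treatment`,
#' `timepoint_h`, `replicate`.
#'
#' @param path Path to a tab-separated design table with a header row.
#' @return A `data.frame` with the design columns, character/numeric typed.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(d)
}

validate_design <- function(d) {
  required <- c("sample_id", "condition", "replicate")
  missing <- setdiff(required, names(d))
  if (length(missing)) stop("design table missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  if (!"washout_treatment" %in% names(d)) d$washout_treatment <- "none"
  if (!"timepoint_h" %in% names(d)) d$timepoint_h <- NA_real_
  if (!"assay" %in% names(d)) d$assay <- NA_character_
  d$replicate <- as.integer(d$replicate)
  if (any(!is.na(d$replicate) & d$replicate < 1L)) stop("replicate must be >= 1")
  d
}

#' Write a sample design table
#' @param design Design `data.frame` (see [read_design()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count matrix
#'
#' The TSV must carry the feature identifier in the first column and one column
#' per sample. Every sample in the design must be present; columns are
#' reordered to match the design. Counts must be non-negative integers.
#'
#' @param path Path to a tab-separated counts table with a header row.
#' @param design Sample design `data.frame`; column order of the result follows
#'   `design$sample_id`.
#' @return Integer matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path, design) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  design <- validate_design(design)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("counts table needs a feature id column plus samples")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in counts table")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  unknown <- setdiff(colnames(mat), design$sample_id)
  if (length(unknown)) {
    stop("design-mismatch: counts columns not in design: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(design$sample_id, colnames(mat))
  if (length(absent)) {
    stop("design-mismatch: design samples missing from counts: ",
         paste(absent, collapse = ", "))
  }
  storage_ok <- is.numeric(mat)
  if (!storage_ok) stop("counts parse error: non-numeric count values")
  if (any(is.na(mat))) stop("counts parse error: missing count values")
  if (any(mat < 0)) stop("counts parse error: negative count values")
  if (any(mat != round(mat))) stop("counts parse error: non-integer count values")
  mat <- mat[, design$sample_id, drop = FALSE]
  rownames(mat) <- ids
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count matrix
#' @param counts Integer matrix, features x samples.
#' @param path Output path.
#' @param id_column Name for the feature-id column (default `"feature_id"`).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects tab-separated columns `gene_id`, `chrom`, `tss`, `strand`,
#' `protein_coding`. The TSS coordinate is 0-based; for a minus-strand gene it
#' is the downstream (right) end of the gene body interval.
#'
#' @param path Path to the annotation TSV.
#' @return A validated `data.frame`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop("TSS annotation file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_tss(d)
}

validate_tss <- function(d) {
  required <- c("gene_id", "chrom", "tss", "strand", "protein_coding")
  missing <- setdiff(required, names(d))
  if (length(missing)) stop("TSS table missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(d$gene_id)) stop("duplicate gene_id in TSS table")
  if (any(d$tss < 0)) stop("TSS coordinates must be >= 0")
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  d$protein_coding <- as.logical(d$protein_coding)
  d
}

#' Write a memory call report with a JSON parameter sidecar
#'
#' Emits one TSV row per feature with its class labels, effect sizes and FDRs,
#' plus a `<path>.params.json` sidecar recording the thresholds, seed and
#' package version that produced the calls, so every report is traceable to
#' its run parameters.
#'
#' @param calls A `data.frame` of per-feature calls (any columns; typically
#'   id, class labels, l2fc, fdr).
#' @param path Output TSV path.
#' @param params Named list of run parameters (thresholds, seed, ...).
#' @return Invisibly, `path`.
#' @export
write_report <- function(calls, path, params = list()) {
  stopifnot(is.data.frame(calls))
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  params$package_version <- as.character(utils::packageVersion("cytomem"))
  jsonlite::write_json(params, paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a memory call report written by [write_report()]
#' @param path Report TSV path.
#' @return The call `data.frame`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
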