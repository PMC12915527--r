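#' Counts-per-million normalization
#'
#' Scales each sample column so that it sums to one million:
#' `cpm[f, s] = counts[f, s] / libsize[s] * 1e6`, where the library size is
#' the column sum over the feature set. No pseudocount is applied here; see
#' [apply_pseudocount()].
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libsize <- colSums(counts)
  zero <- which(libsize == 0)
  if (length(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2L, libsize, "/") * 1e6
}

#' Apply a pseudocount floor to a CPM matrix
#'
#' Stabilizes log fold changes by flooring small CPM values. Two policies:
#' \describe{
#'   \item{`percentile_1_per_condition`}{for each condition group in the
#'     design, the floor is the 1st percentile of all CPM values across that
#'     group's samples and features (linear-interpolation quantile), applied
#'     elementwise within the group;}
#'   \item{`fixed_1`}{the floor is 1 CPM everywhere (the usual gene-expression
#'     convention).}
#' }
#' The floor is applied as `pmax(cpm, floor)`, not added, so values already
#' above it are untouched and the operation is idempotent and monotone.
#'
#' @param cpm CPM matrix from [cpm_normalize()].
#' @param design Sample design with `sample_id` and `condition`; required for
#'   the percentile policy.
#' @param policy `"percentile_1_per_condition"` or `"fixed_1"`.
#' @param percentile Quantile used by the percentile policy (default 0.01).
#' @return CPM matrix with the floor applied. The per-condition floors are
#'   attached as `attr(, "pseudocount")`.
#' @export
apply_pseudocount <- function(cpm, design = NULL,
                              policy = c("percentile_1_per_condition", "fixed_1"),
                              percentile = 0.01) {
  policy <- match.arg(policy)
  cpm <- as.matrix(cpm)
  if (policy == "fixed_1") {
    out <- pmax(cpm, 1)
    attr(out, "pseudocount") <- c(all = 1)
    return(out)
  }
  if (is.null(design)) stop("percentile pseudocount policy requires a design")
  design <- validate_design(design)
  if (!all(colnames(cpm) %in% design$sample_id)) {
    stop("cpm columns missing from design")
  }
  cond <- design$condition[match(colnames(cpm), design$sample_id)]
  floors <- numeric(0)
  out <- cpm
  for (cn in unique(cond)) {
    cols <- which(cond == cn)
    if (!length(cols)) stop("empty condition group: ", cn)
    vals <- cpm[, cols]
    p <- stats::quantile(vals, probs = percentile, names = FALSE, type = 7)
    if (p <= 0) {
      # sparse data can put the percentile at zero; fall back to the smallest
      # positive CPM so downstream log fold changes stay finite
      pos <- vals[vals > 0]
      if (!length(pos)) stop("condition group has no non-zero CPM: ", cn)
      p <- min(pos)
    }
    out[, cols] <- pmax(cpm[, cols, drop = FALSE], p)
    floors[cn] <- p
  }
  attr(out, "pseudocount") <- floors
  out
}

#' Abundance filter on acute-stimulation conditions
#'
#' Keeps a feature if, in at least one acute condition, its mean CPM across
#' that condition's replicates is at or above the chosen percentile (default:
#' the median, i.e. the "top 50th percentile") of that condition's per-feature
#' mean CPMs. Ties are inclusive, so a feature equal to the cutoff passes and
#' identical-abundance matrices keep everything.
#'
#' @param cpm CPM matrix (pre-pseudocount is fine; the filter is scale-free).
#' @param design Sample design.
#' @param acute_conditions Character vector of condition labels that define
#'   acute stimulation (e.g. unstimulated plus the 8-h stimuli).
#' @param percentile Fraction in `[0, 1]`; 0 keeps all features, values near 1
#'   keep only each condition's most abundant features.
#' @return Character vector of retained feature ids, in input row order.
#' @export
acute_abundance_filter <- function(cpm, design, acute_conditions,
                                   percentile = 0.5) {
  design <- validate_design(design)
  if (!length(acute_conditions)) stop("acute_conditions must be non-empty")
  absent <- setdiff(acute_conditions, design$condition)
  if (length(absent)) {
    stop("acute condition(s) not in design: ", paste(absent, collapse = ", "))
  }
  stopifnot(percentile >= 0, percentile <= 1)
  keep <- rep(FALSE, nrow(cpm))
  for (cn in acute_conditions) {
    samples <- design$sample_id[design$condition == cn]
    samples <- intersect(samples, colnames(cpm))
    if (!length(samples)) stop("no cpm columns for condition: ", cn)
    means <- rowMeans(cpm[, samples, drop = FALSE])
    cutoff <- stats::quantile(means, probs = percentile, names = FALSE, type = 7)
    keep <- keep | (means >= cutoff)
  }
  rownames(cpm)[keep]
}
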