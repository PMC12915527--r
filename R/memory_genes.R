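#' Build condition-mean CPM time courses from counts
#'
#' Converts a gene-level count matrix plus design into arm-wise time-course
#' matrices of pseudocounted condition-mean CPM (floor 1 CPM, the
#' gene-expression convention). An "arm" is a pretreatment x washout-culture
#' combination (e.g. PBS/media, IFNG/media, PBS/rux, IFNG/rux) followed over a
#' shared LPS-restimulation timepoint grid.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Sample design; rows used here must carry `condition` labels
#'   of the form `<arm>` with `timepoint_h` set, where `<arm>` is given by the
#'   `arm` column (or derived via `arm_of`).
#' @param arm_of Function mapping a design row's condition label to an arm
#'   label. Defaults to the design's `arm` column when present, else the
#'   condition label itself.
#' @return List of class `"restim_timecourse"`: `arms` (named list of genes x
#'   timepoints matrices), `timepoints` (ascending hours).
#' @export
restim_timecourse <- function(counts, design, arm_of = NULL) {
  design <- validate_design(design)
  cpm <- apply_pseudocount(cpm_normalize(counts), policy = "fixed_1")
  design <- design[design$sample_id %in% colnames(cpm), , drop = FALSE]
  arms_lab <- if (!is.null(arm_of)) {
    vapply(design$condition, arm_of, "")
  } else if ("arm" %in% names(design)) {
    design$arm
  } else {
    design$condition
  }
  tps <- sort(unique(design$timepoint_h))
  arms <- lapply(split(seq_len(nrow(design)), arms_lab), function(rows) {
    sub <- design[rows, , drop = FALSE]
    got <- sort(unique(sub$timepoint_h))
    if (!identical(got, tps)) {
      stop("timepoint grids mismatched across arms: expected {",
           paste(tps, collapse = ","), "}, got {",
           paste(got, collapse = ","), "}")
    }
    m <- vapply(tps, function(tp) {
      rowMeans(cpm[, sub$sample_id[sub$timepoint_h == tp], drop = FALSE])
    }, numeric(nrow(cpm)))
    m <- matrix(m, nrow = nrow(cpm),
                dimnames = list(rownames(cpm), as.character(tps)))
    m
  })
  structure(list(arms = arms, timepoints = tps), class = "restim_timecourse")
}

check_tc <- function(tc, arms) {
  stopifnot(inherits(tc, "restim_timecourse"))
  absent <- setdiff(arms, names(tc$arms))
  if (length(absent)) stop("time-course arms missing: ",
                           paste(absent, collapse = ", "))
  invisible(tc)
}

#' Call stimulus-induced genes
#'
#' A gene is induced when its pseudocounted mean CPM at the acute stimulation
#' timepoint is at least `fold_min` times its unstimulated value
#' (inclusive >=). Analysis is conventionally restricted to protein-coding
#' genes before calling.
#'
#' @param cpm_stim,cpm_unstim Named numeric vectors of pseudocounted mean CPM
#'   (same genes, same order).
#' @param fold_min Fold-change threshold (default 5).
#' @return Character vector of induced gene ids.
#' @export
call_induced_genes <- function(cpm_stim, cpm_unstim, fold_min = 5) {
  if (length(cpm_stim) != length(cpm_unstim)) {
    stop("stimulated and unstimulated CPM vectors differ in length")
  }
  if (anyNA(cpm_stim) || anyNA(cpm_unstim)) stop("missing CPM values")
  ids <- names(cpm_stim) %||% as.character(seq_along(cpm_stim))
  ids[cpm_stim / cpm_unstim >= fold_min]
}

#' Percent of acute expression retained after washout
#'
#' `100 * CPM_washout / CPM_8h` on pseudocounted mean CPM: the plain ratio of
#' the washed-out level to the acute level, not baseline-subtracted.
#'
#' @param cpm_washout,cpm_8h Named numeric vectors of pseudocounted mean CPM.
#' @return Numeric vector of percents (>= 0).
#' @export
persistence_percent <- function(cpm_washout, cpm_8h) {
  if (any(cpm_8h <= 0)) stop("acute CPM must be positive (pseudocount floor)")
  100 * cpm_washout / cpm_8h
}

#' Band persistence percents
#'
#' Partitions `[0, Inf)` into the three persistence bands used to summarize
#' washout retention: `>=90`, `[20, 90)`, `< 20` percent.
#'
#' @param percent Numeric vector from [persistence_percent()].
#' @return Factor with levels `">=90%"`, `"20-90%"`, `"<20%"`.
#' @export
persistence_band <- function(percent) {
  stopifnot(all(percent >= 0))
  cut(percent, breaks = c(-Inf, 20, 90, Inf), right = FALSE,
      labels = c("<20%", "20-90%", ">=90%")) |>
    factor(levels = c(">=90%", "20-90%", "<20%"))
}

# TRUE where >= `len` consecutive entries of `ok` are TRUE
has_run <- function(ok, len) {
  r <- rle(ok)
  any(r$values & r$lengths >= len)
}

tc_ratio <- function(num, den) num / den

#' Call potentiated LPS-response genes
#'
#' A gene is potentiated by cytokine pretreatment when (a) it is
#' LPS-inducible: the maximum over timepoints of CPM relative to the naive
#' baseline (the untreated arm at 0 h, "naive 0H") reaches `lps_fold_min` in
#' the `induction_arms` (by default the naive arm itself, so that basal
#' elevation in the pretreated arm cannot satisfy the induction gate); and
#' (b) the pretreated arm exceeds
#' the naive arm at least `delta_fold_min`-fold at `contiguous` consecutive
#' timepoints of the grid. All fold thresholds are inclusive (>=), and
#' "consecutive" means adjacent on the sampled grid.
#'
#' @param tc A `"restim_timecourse"`.
#' @param naive_arm,trained_arm Arm names for the untreated and
#'   cytokine-pretreated media arms (defaults `"pbs_media"`, `"ifng_media"`).
#' @param induction_arms Arms whose induction can satisfy the LPS gate
#'   (default: the naive media arm). For the JAK-blockade design pass the
#'   ruxolitinib arm and `lps_fold_min = 4`.
#' @param lps_fold_min LPS-induction gate (default 5).
#' @param delta_fold_min Trained/naive expression ratio gate (default 2).
#' @param contiguous Required run of consecutive qualifying timepoints
#'   (default 2).
#' @return `data.frame` with `gene_id`, `induction_fold`, `max_run`
#'   (longest qualifying run), `potentiated`.
#' @export
call_potentiated <- function(tc, naive_arm = "pbs_media",
                             trained_arm = "ifng_media",
                             induction_arms = naive_arm,
                             lps_fold_min = 5, delta_fold_min = 2,
                             contiguous = 2) {
  check_tc(tc, unique(c(naive_arm, trained_arm, induction_arms)))
  naive0 <- tc$arms[[naive_arm]][, 1L]
  induction <- Reduce(pmax, lapply(induction_arms, function(a) {
    apply(tc$arms[[a]] / naive0, 1L, max)
  }))
  ratio <- tc$arms[[trained_arm]] / tc$arms[[naive_arm]]
  runs <- apply(ratio >= delta_fold_min, 1L, function(ok) {
    r <- rle(ok); m <- r$lengths[r$values]; if (length(m)) max(m) else 0L
  })
  data.frame(
    gene_id = rownames(tc$arms[[naive_arm]]),
    induction_fold = induction,
    max_run = as.integer(runs),
    potentiated = induction >= lps_fold_min & runs >= contiguous,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Call tolerized LPS-response genes
#'
#' A gene is tolerized when cytokine pretreatment reduces its LPS response at
#' least `reduction_fold_min`-fold at `contiguous` consecutive timepoints
#' (naive/trained ratio >= threshold), and the gene remains LPS-inducible at
#' least `rux_induction_min`-fold in the JAK-blockade (ruxolitinib) arm --
#' the gate that restricts the call to genes whose LPS induction does not
#' itself require JAK signaling.
#'
#' @param tc A `"restim_timecourse"`.
#' @param naive_arm,trained_arm Media arm names as in [call_potentiated()].
#' @param rux_arm Arm used for the JAK-independent induction gate
#'   (default `"pbs_rux"`).
#' @param reduction_fold_min Naive/trained reduction gate (default 2).
#' @param contiguous Required consecutive qualifying timepoints (default 2).
#' @param rux_induction_min Induction gate in the ruxolitinib arm (default 4).
#' @return `data.frame` with `gene_id`, `rux_induction_fold`, `max_run`,
#'   `tolerized`.
#' @export
call_tolerized <- function(tc, naive_arm = "pbs_media",
                           trained_arm = "ifng_media", rux_arm = "pbs_rux",
                           reduction_fold_min = 2, contiguous = 2,
                           rux_induction_min = 4) {
  check_tc(tc, c(naive_arm, trained_arm, rux_arm))
  naive0 <- tc$arms[[naive_arm]][, 1L]
  rux_induction <- apply(tc$arms[[rux_arm]] / naive0, 1L, max)
  ratio <- tc$arms[[naive_arm]] / tc$arms[[trained_arm]]
  runs <- apply(ratio >= reduction_fold_min, 1L, function(ok) {
    r <- rle(ok); m <- r$lengths[r$values]; if (length(m)) max(m) else 0L
  })
  data.frame(
    gene_id = rownames(tc$arms[[naive_arm]]),
    rux_induction_fold = rux_induction,
    max_run = as.integer(runs),
    tolerized = rux_induction >= rux_induction_min & runs >= contiguous,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Split potentiated genes by basal set-point
#'
#' Compares pre-restimulation (0 h, 88 h post-washout) expression between the
#' pretreated and naive arms: `basal_elevated` iff
#' `log2(CPM_trained(0h) / CPM_naive(0h)) > threshold_l2fc`, strictly. A gene
#' exactly at the threshold goes to the equal-basal class.
#'
#' @param tc A `"restim_timecourse"`.
#' @param naive_arm,trained_arm Media arm names.
#' @param threshold_l2fc Strict log2 threshold (default 0.5).
#' @return `data.frame` with `gene_id`, `basal_l2fc`, `basal_elevated`.
#' @export
split_basal <- function(tc, naive_arm = "pbs_media",
                        trained_arm = "ifng_media", threshold_l2fc = 0.5) {
  check_tc(tc, c(naive_arm, trained_arm))
  l2fc <- log2(tc$arms[[trained_arm]][, 1L] / tc$arms[[naive_arm]][, 1L])
  data.frame(
    gene_id = rownames(tc$arms[[naive_arm]]),
    basal_l2fc = l2fc,
    basal_elevated = l2fc > threshold_l2fc,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Mean cytokine potentiation score per gene
#'
#' Both arms' log2 fold changes are taken against the common naive 0 h
#' baseline; the score is the per-gene mean over timepoints of
#' `L2FC_trained(t) - L2FC_naive(t)`. The 0 h timepoint is excluded by
#' default, since both arms are referenced there.
#'
#' @param tc A `"restim_timecourse"`.
#' @param naive_arm,trained_arm Media arm names.
#' @param include_zero Include the 0 h timepoint in the average
#'   (default `FALSE`).
#' @return Named numeric vector of mean potentiation (log2 units) per gene.
#' @export
mean_potentiation <- function(tc, naive_arm = "pbs_media",
                              trained_arm = "ifng_media",
                              include_zero = FALSE) {
  check_tc(tc, c(naive_arm, trained_arm))
  keep <- if (include_zero) seq_along(tc$timepoints) else
    which(tc$timepoints > 0)
  if (!length(keep)) stop("no timepoints to average over")
  naive0 <- tc$arms[[naive_arm]][, 1L]
  delta <- log2(tc$arms[[trained_arm]] / naive0) -
    log2(tc$arms[[naive_arm]] / naive0)
  rowMeans(delta[, keep, drop = FALSE])
}
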