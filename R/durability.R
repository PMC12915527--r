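#' Call washout persistence of induced features
#'
#' A feature induced at the acute timepoint counts as persistent under a given
#' post-washout treatment when the washout-vs-unstimulated contrast gives
#' `l2fc >= l2fc_min` (inclusive; default 0, i.e. still at or above baseline
#' significance) and `fdr < fdr_max` (strict; default 0.01). The contrast is
#' against the unstimulated baseline, not the acute timepoint, so "persistent"
#' means "still significantly above where it started".
#'
#' @param induced Character vector of induced feature ids.
#' @param washout_results Named list of differential result `data.frame`s
#'   (one per washout treatment, e.g. `media`, `rux`, `anti_ifng`), each for
#'   the washout-vs-unstimulated contrast.
#' @param l2fc_min Inclusive lower bound on washout l2fc (default 0).
#' @param fdr_max Strict FDR bound (default 0.01).
#' @return `data.frame` with columns `feature_id`, `washout_treatment`,
#'   `l2fc_washout_vs_unstim`, `fdr_washout_vs_unstim`, `persistent`.
#' @export
call_persistence <- function(induced, washout_results, l2fc_min = 0,
                             fdr_max = 0.01) {
  stopifnot(is.list(washout_results), length(names(washout_results)) > 0)
  out <- lapply(names(washout_results), function(trt) {
    res <- washout_results[[trt]]
    idx <- match(induced, res$feature_id)
    if (anyNA(idx)) {
      stop("induced feature(s) missing from washout results for ", trt, ": ",
           paste(utils::head(induced[is.na(idx)], 3), collapse = ", "))
    }
    data.frame(
      feature_id = induced,
      washout_treatment = trt,
      l2fc_washout_vs_unstim = res$l2fc[idx],
      fdr_washout_vs_unstim = res$fdr[idx],
      persistent = res$l2fc[idx] >= l2fc_min & res$fdr[idx] < fdr_max,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Fraction of induced features persisting under a treatment
#'
#' @param calls Persistence call `data.frame` from [call_persistence()].
#' @param treatment Washout treatment label to summarize.
#' @return Fraction in `[0, 1]`: persistent / induced.
#' @export
persistence_fraction <- function(calls, treatment) {
  sub <- calls[calls$washout_treatment == treatment, , drop = FALSE]
  if (!nrow(sub)) stop("no persistence calls for treatment: ", treatment)
  mean(sub$persistent)
}

#' Exact/approximate Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences. Zero
#' differences are dropped. For up to `exact_max` non-zero pairs the null
#' distribution of the signed-rank statistic is computed exactly by a
#' generating-function recursion over the (tie-midranked) ranks; beyond that a
#' normal approximation with continuity and tie corrections is used. The exact
#' branch handles ties, which is what lets boundary cases like five identical
#' positive deltas come out at p = 2/2^5.
#'
#' @param deltas Numeric vector of paired differences.
#' @param exact_max Largest number of non-zero pairs for which the exact
#'   distribution is enumerated (default 25).
#' @return List with `statistic` (sum of positive midranks), `n` (non-zero
#'   pairs), `p.value`, and `method` (`"exact"` or `"normal"`).
#' @export
signed_rank_test <- function(deltas, exact_max = 25) {
  d <- deltas[deltas != 0]
  m <- length(d)
  if (m < 2L) stop("signed-rank p undefined: fewer than 2 non-zero pairs")
  r <- rank(abs(d))          # midranks under ties
  w <- sum(r[d > 0])
  if (m <= exact_max) {
    # doubled midranks are integers; W distribution by polynomial recursion
    r2 <- as.integer(round(2 * r))
    s <- sum(r2)
    dist <- numeric(s + 1L)
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(s + 1L - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^m
    w2 <- as.integer(round(2 * w))
    mid <- s / 2
    p <- if (w2 > mid) {
      2 * sum(dist[(w2 + 1L):(s + 1L)])
    } else if (w2 < mid) {
      2 * sum(dist[1L:(w2 + 1L)])
    } else {
      1
    }
    list(statistic = w, n = m, p.value = min(1, p), method = "exact")
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    list(statistic = w, n = m,
         p.value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

#' Washout shift of induced features with a paired Wilcoxon test
#'
#' Quantifies how a set of induced features moves between two conditions
#' (typically acute stimulation and post-washout): per feature,
#' `delta = log2(mean CPM post) - log2(mean CPM pre)` on pseudocounted
#' condition-mean CPM, summarized by the mean delta and a two-sided paired
#' Wilcoxon signed-rank p-value over features. When fewer than two non-zero
#' deltas remain the p-value is `NA` (undefined), but the mean is still
#' returned.
#'
#' @param cpm Pseudocounted CPM matrix, features x samples.
#' @param design Sample design.
#' @param features Feature ids to include (e.g. the induced set).
#' @param pre_condition,post_condition Condition labels for the two states.
#' @return List with `mean_delta`, `p.value`, `n_features`, `n_nonzero`, and
#'   the per-feature `deltas`.
#' @export
washout_delta_stats <- function(cpm, design, features, pre_condition,
                                post_condition) {
  design <- validate_design(design)
  idx <- match(features, rownames(cpm))
  if (anyNA(idx)) stop("features missing from cpm matrix")
  cond_mean <- function(cond) {
    samples <- design$sample_id[design$condition == cond]
    samples <- intersect(samples, colnames(cpm))
    if (!length(samples)) stop("no samples for condition: ", cond)
    rowMeans(cpm[idx, samples, drop = FALSE])
  }
  deltas <- log2(cond_mean(post_condition)) - log2(cond_mean(pre_condition))
  nz <- sum(deltas != 0)
  p <- if (nz < 2L) NA_real_ else signed_rank_test(deltas)$p.value
  list(mean_delta = mean(deltas), p.value = p,
       n_features = length(deltas), n_nonzero = nz, deltas = deltas)
}

#' Condition-mean log2 CPM profiles
#'
#' Builds the per-feature trajectory matrix used for clustering: replicate CPM
#' averaged per condition, then log2 of the pseudocounted mean.
#'
#' @param cpm Pseudocounted CPM matrix.
#' @param design Sample design.
#' @param conditions Ordered condition labels forming the profile columns.
#' @param features Optional feature ids to keep (default: all rows).
#' @return Numeric matrix features x conditions of log2 mean CPM.
#' @export
condition_profiles <- function(cpm, design, conditions, features = NULL) {
  design <- validate_design(design)
  if (is.null(features)) features <- rownames(cpm)
  idx <- match(features, rownames(cpm))
  if (anyNA(idx)) stop("features missing from cpm matrix")
  prof <- vapply(conditions, function(cond) {
    samples <- intersect(design$sample_id[design$condition == cond],
                         colnames(cpm))
    if (!length(samples)) stop("no samples for condition: ", cond)
    log2(rowMeans(cpm[idx, samples, drop = FALSE]))
  }, numeric(length(idx)))
  prof <- matrix(prof, nrow = length(idx),
                 dimnames = list(features, conditions))
  prof
}

#' k-means clustering of washout trajectories
#'
#' Z-scores each feature's condition-mean log2 CPM profile (mean 0, sd 1
#' across the profile), excludes zero-variance features, and runs k-means
#' with a fixed seed and multiple restarts. Clusters are relabeled
#' deterministically by descending centroid value at the `order_by` column
#' (conventionally the washout-in-media condition), so cluster 1 is always
#' the most washout-elevated pattern regardless of k-means' arbitrary
#' labeling.
#'
#' @param profiles Matrix features x conditions of log2 mean CPM (see
#'   [condition_profiles()]).
#' @param k Number of clusters (default 3: the persist / decay / increase
#'   patterns seen after cytokine washout).
#' @param seed Integer seed for reproducible restarts.
#' @param order_by Column name used for deterministic relabeling (default:
#'   last column).
#' @param nstart Number of random restarts (default 10).
#' @return List of class `"trajectory_clusters"`: `assignments` (named integer
#'   vector), `centroids` (k x conditions), `k`, `seed`, `excluded`
#'   (zero-variance feature ids).
#' @export
cluster_trajectories <- function(profiles, k = 3, seed = 1,
                                 order_by = colnames(profiles)[ncol(profiles)],
                                 nstart = 10) {
  stopifnot(k >= 1)
  sds <- apply(profiles, 1L, stats::sd)
  excluded <- rownames(profiles)[sds == 0 | !is.finite(sds)]
  keep <- setdiff(rownames(profiles), excluded)
  z <- t(scale(t(profiles[keep, , drop = FALSE])))
  if (k > nrow(z)) stop("k exceeds the number of clusterable features")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  fit <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 50)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  ord <- order(fit$centers[, order_by], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[fit$cluster]
  names(assignments) <- keep
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  structure(list(assignments = assignments, centroids = centroids, k = k,
                 seed = seed, excluded = excluded),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat("Trajectory clustering: k =", x$k, "| seed =", x$seed, "\n")
  cat("Features clustered:", length(x$assignments),
      "| excluded (zero variance):", length(x$excluded), "\n")
  cat("Cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "),
      "\n")
  cat("Centroids (Z-scored), ordered by", colnames(x$centroids)[ncol(x$centroids)],
      ":\n")
  print(round(x$centroids, 2))
  invisible(x)
}
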