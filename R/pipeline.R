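cond_samples <- function(design, condition, cols) {
  s <- intersect(design$sample_id[design$condition == condition], cols)
  if (!length(s)) stop("no samples for condition: ", condition)
  s
}

cond_mean_cpm <- function(cpm, design, condition) {
  rowMeans(cpm[, cond_samples(design, condition, colnames(cpm)), drop = FALSE])
}

#' End-to-end peak memory analysis
#'
#' Runs the peak-level pipeline: acute-abundance filter, per-stimulus
#' differential test against the unstimulated baseline, induced-peak calling,
#' washout-vs-unstimulated contrasts under each post-washout treatment,
#' persistence calls and fractions, washout shift statistics, and k-means
#' trajectory clustering of the induced peaks.
#'
#' @param counts Integer matrix, peaks x samples.
#' @param design Sample design.
#' @param features Optional feature table (BED-style) for the peaks.
#' @param unstim Unstimulated condition label.
#' @param stim_conditions Named character vector of acute stimulation
#'   conditions (names are stimulus labels, e.g. `c(ifng = "IFNG_8H")`).
#' @param washout_conditions Named character vector mapping post-washout
#'   treatments to condition labels, for the stimulus in `washout_of`.
#' @param washout_of Stimulus label whose washout arms are analyzed (default:
#'   first of `stim_conditions`).
#' @param filter_percentile Acute-abundance filter percentile (default 0.5).
#' @param l2fc_min,fdr_max Induced-peak cutoffs (defaults 2, 0.01; strict).
#' @param persistence_l2fc_min,persistence_fdr_max Persistence cutoffs
#'   (defaults 0 inclusive, 0.01 strict).
#' @param k,seed Trajectory clustering parameters (defaults 3, 1).
#' @param shrinkage_weight Dispersion shrinkage weight (default 0.7).
#' @return Object of class `"peak_memory"` with the per-stage results.
#' @export
peak_memory_analysis <- function(counts, design, features = NULL,
                                 unstim = "UNSTIM",
                                 stim_conditions = c(ifng = "IFNG_8H"),
                                 washout_conditions = c(),
                                 washout_of = names(stim_conditions)[1],
                                 filter_percentile = 0.5,
                                 l2fc_min = 2, fdr_max = 0.01,
                                 persistence_l2fc_min = 0,
                                 persistence_fdr_max = 0.01,
                                 k = 3, seed = 1, shrinkage_weight = 0.7) {
  design <- validate_design(design)
  counts <- as.matrix(counts)
  cpm <- cpm_normalize(counts)
  acute <- c(unstim, unname(stim_conditions))
  kept <- acute_abundance_filter(cpm, design, acute, filter_percentile)
  counts_f <- counts[kept, , drop = FALSE]

  ref <- cond_samples(design, unstim, colnames(counts))
  differential <- list()
  induced <- list()
  for (stim in names(stim_conditions)) {
    trt <- cond_samples(design, stim_conditions[[stim]], colnames(counts))
    disp <- estimate_dispersion(counts_f, ref, trt, shrinkage_weight)
    differential[[stim]] <- nb_exact_test(counts_f, ref, trt, disp)
    induced[[stim]] <- call_induced(differential[[stim]], l2fc_min, fdr_max)
  }

  washout <- list()
  persistence <- NULL
  fractions <- NULL
  delta <- NULL
  clusters <- NULL
  if (length(washout_conditions)) {
    for (trt_name in names(washout_conditions)) {
      wtrt <- cond_samples(design, washout_conditions[[trt_name]],
                           colnames(counts))
      disp <- estimate_dispersion(counts_f, ref, wtrt, shrinkage_weight)
      washout[[trt_name]] <- nb_exact_test(counts_f, ref, wtrt, disp)
    }
    focal <- induced[[washout_of]]
    if (length(focal)) {
      persistence <- call_persistence(focal, washout,
                                      persistence_l2fc_min,
                                      persistence_fdr_max)
      fractions <- vapply(names(washout_conditions), function(trt)
        persistence_fraction(persistence, trt), numeric(1))
      cpm_ps <- apply_pseudocount(cpm, design,
                                  policy = "percentile_1_per_condition")
      delta <- lapply(names(stim_conditions), function(stim) {
        if (!length(induced[[stim]])) return(NULL)
        washout_delta_stats(cpm_ps, design, induced[[stim]],
                            pre_condition = stim_conditions[[stim]],
                            post_condition = washout_conditions[[1]])
      })
      names(delta) <- names(stim_conditions)
      prof_conditions <- c(unstim, stim_conditions[[washout_of]],
                           unname(washout_conditions))
      profiles <- condition_profiles(cpm_ps, design, prof_conditions,
                                     features = focal)
      if (length(focal) > k) {
        clusters <- cluster_trajectories(profiles, k = k, seed = seed,
                                         order_by = washout_conditions[[1]])
      }
    }
  }

  structure(list(
    filter = list(n_input = nrow(counts), kept = kept,
                  percentile = filter_percentile),
    differential = differential,
    induced = induced,
    washout = washout,
    persistence = persistence,
    fractions = fractions,
    delta = delta,
    clusters = clusters,
    features = features,
    params = list(unstim = unstim, stim_conditions = stim_conditions,
                  washout_conditions = washout_conditions,
                  washout_of = washout_of,
                  filter_percentile = filter_percentile,
                  l2fc_min = l2fc_min, fdr_max = fdr_max,
                  persistence_l2fc_min = persistence_l2fc_min,
                  persistence_fdr_max = persistence_fdr_max,
                  k = k, seed = seed, shrinkage_weight = shrinkage_weight)
  ), class = "peak_memory")
}

#' @export
print.peak_memory <- function(x, ...) {
  cat("Peak memory analysis\n")
  cat(sprintf("  features: %d input, %d pass abundance filter\n",
              x$filter$n_input, length(x$filter$kept)))
  for (stim in names(x$induced)) {
    cat(sprintf("  %s-induced peaks (l2fc > %g, FDR < %g): %d\n",
                stim, x$params$l2fc_min, x$params$fdr_max,
                length(x$induced[[stim]])))
  }
  if (!is.null(x$fractions)) {
    cat("  persistence fractions after washout:\n")
    for (trt in names(x$fractions)) {
      cat(sprintf("    %-10s %.1f%%\n", trt, 100 * x$fractions[[trt]]))
    }
  }
  if (!is.null(x$clusters)) {
    cat("  trajectory clusters (k =", x$clusters$k, "): sizes",
        paste(tabulate(x$clusters$assignments, x$clusters$k), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' End-to-end gene memory analysis
#'
#' Runs the gene-level pipeline on one or both RNA-seq panels:
#' \itemize{
#'   \item washout panel: induced genes (acute vs unstimulated fold), washout
#'     persistence percent and banding under each washout treatment;
#'   \item restimulation panel: potentiated genes (media design and
#'     JAK-blockade-gated design), tolerized genes, basal set-point split of
#'     the potentiated set, mean potentiation scores.
#' }
#' When a TSS annotation is given, analysis is restricted to protein-coding
#' genes.
#'
#' @param washout List with `counts` and `design` for the induction/washout
#'   panel, or `NULL` to skip.
#' @param restim List with `counts` and `design` (design carries `arm` and
#'   `timepoint_h`) for the LPS-restimulation panel, or `NULL` to skip.
#' @param tss Optional TSS annotation used for the protein-coding restriction.
#' @param washout_unstim,washout_stim,washout_treatments Condition labels of
#'   the washout panel.
#' @param fold_min Induced-gene fold cutoff (default 5, inclusive).
#' @param lps_fold_min,rux_lps_fold_min LPS-induction gates for the media and
#'   JAK-blockade potentiation designs (defaults 5 and 4).
#' @param delta_fold_min,contiguous Potentiation/tolerance rule parameters
#'   (defaults 2, 2).
#' @param basal_l2fc Basal set-point split threshold (default 0.5, strict).
#' @return Object of class `"gene_memory"`.
#' @export
gene_memory_analysis <- function(washout = NULL, restim = NULL, tss = NULL,
                                 washout_unstim = "GW_UNSTIM",
                                 washout_stim = "GW_IFNG_8H",
                                 washout_treatments = c(media = "GW_WASH_MEDIA",
                                                        rux = "GW_WASH_RUX"),
                                 fold_min = 5, lps_fold_min = 5,
                                 rux_lps_fold_min = 4, delta_fold_min = 2,
                                 contiguous = 2, basal_l2fc = 0.5) {
  coding <- NULL
  if (!is.null(tss)) {
    tss <- validate_tss(tss)
    coding <- tss$gene_id[tss$protein_coding]
  }
  # CPM is normalized against the full library first; the protein-coding
  # restriction then narrows the analyzed rows without changing the scale
  restrict <- function(mat) {
    if (is.null(coding)) return(mat)
    mat[intersect(rownames(mat), coding), , drop = FALSE]
  }

  wash_res <- NULL
  if (!is.null(washout)) {
    design <- validate_design(washout$design)
    cpm <- restrict(apply_pseudocount(cpm_normalize(washout$counts),
                                      policy = "fixed_1"))
    m_unstim <- cond_mean_cpm(cpm, design, washout_unstim)
    m_stim <- cond_mean_cpm(cpm, design, washout_stim)
    induced <- call_induced_genes(m_stim, m_unstim, fold_min)
    bands <- lapply(washout_treatments, function(cond) {
      pct <- persistence_percent(cond_mean_cpm(cpm, design, cond)[induced],
                                 m_stim[induced])
      data.frame(gene_id = induced, percent = pct,
                 band = persistence_band(pct),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    wash_res <- list(induced = induced, bands = bands,
                     band_counts = lapply(bands, function(b) table(b$band)))
  }

  restim_res <- NULL
  if (!is.null(restim)) {
    tc <- restim_timecourse(restim$counts, restim$design)
    tc$arms <- lapply(tc$arms, restrict)
    pot <- call_potentiated(tc, lps_fold_min = lps_fold_min,
                            delta_fold_min = delta_fold_min,
                            contiguous = contiguous)
    pot_rux <- if ("pbs_rux" %in% names(tc$arms)) {
      call_potentiated(tc, induction_arms = "pbs_rux",
                       lps_fold_min = rux_lps_fold_min,
                       delta_fold_min = delta_fold_min,
                       contiguous = contiguous)
    }
    tol <- if ("pbs_rux" %in% names(tc$arms)) {
      call_tolerized(tc, reduction_fold_min = delta_fold_min,
                     contiguous = contiguous,
                     rux_induction_min = rux_lps_fold_min)
    }
    basal <- split_basal(tc, threshold_l2fc = basal_l2fc)
    basal <- basal[basal$gene_id %in% pot$gene_id[pot$potentiated], ,
                   drop = FALSE]
    mp <- mean_potentiation(tc)
    scores <- data.frame(gene_id = pot$gene_id,
                         mean_potentiation = unname(mp[pot$gene_id]),
                         lps_induced = pot$induction_fold >= lps_fold_min,
                         stringsAsFactors = FALSE)
    restim_res <- list(timecourse = tc, potentiated = pot,
                       potentiated_rux_gated = pot_rux, tolerized = tol,
                       basal = basal, scores = scores)
  }

  structure(list(washout = wash_res, restim = restim_res,
                 params = list(fold_min = fold_min,
                               lps_fold_min = lps_fold_min,
                               rux_lps_fold_min = rux_lps_fold_min,
                               delta_fold_min = delta_fold_min,
                               contiguous = contiguous,
                               basal_l2fc = basal_l2fc)),
            class = "gene_memory")
}

#' @export
print.gene_memory <- function(x, ...) {
  cat("Gene memory analysis\n")
  if (!is.null(x$washout)) {
    cat(sprintf("  induced genes (fold >= %g): %d\n", x$params$fold_min,
                length(x$washout$induced)))
    for (trt in names(x$washout$band_counts)) {
      bc <- x$washout$band_counts[[trt]]
      cat(sprintf("    %s washout bands: >=90%%: %d | 20-90%%: %d | <20%%: %d\n",
                  trt, bc[">=90%"], bc["20-90%"], bc["<20%"]))
    }
  }
  if (!is.null(x$restim)) {
    cat(sprintf("  potentiated genes: %d (basal elevated: %d, equal: %d)\n",
                sum(x$restim$potentiated$potentiated),
                sum(x$restim$basal$basal_elevated),
                sum(!x$restim$basal$basal_elevated)))
    if (!is.null(x$restim$tolerized)) {
      cat(sprintf("  tolerized genes: %d\n", sum(x$restim$tolerized$tolerized)))
    }
  }
  invisible(x)
}

#' Link a peak analysis to a gene analysis
#'
#' Links the focal induced peak set to protein-coding gene TSSs, then relates
#' each linked gene's mean potentiation to the linked enhancer's washout fold
#' change (Spearman).
#'
#' @param peak_fit A `"peak_memory"` with washout results.
#' @param gene_fit A `"gene_memory"` with restimulation results.
#' @param features Peak feature table (defaults to `peak_fit$features`).
#' @param tss TSS annotation.
#' @param washout_treatment Washout arm providing the enhancer fold change
#'   (default `"media"`).
#' @param window,promoter_window Linkage geometry in bp (defaults 20000, 1000).
#' @return A `"potentiation_durability"` object with the link table attached
#'   as `$links`.
#' @export
link_memory <- function(peak_fit, gene_fit, features = peak_fit$features, tss,
                        washout_treatment = "media", window = 20000,
                        promoter_window = 1000) {
  stopifnot(inherits(peak_fit, "peak_memory"), inherits(gene_fit, "gene_memory"))
  if (is.null(features)) stop("peak feature table required for linkage")
  focal <- peak_fit$induced[[peak_fit$params$washout_of]]
  links <- link_peaks_to_genes(features[features$feature_id %in% focal, ,
                                        drop = FALSE],
                               tss, window, promoter_window)
  res <- potentiation_vs_durability(links, gene_fit$restim$scores,
                                    peak_fit$washout[[washout_treatment]])
  res$links <- links
  res
}

#' Read and validate a YAML run configuration
#'
#' Known top-level keys: `inputs` (file paths), `thresholds` (any parameter of
#' [peak_memory_analysis()], [gene_memory_analysis()] or [link_memory()]),
#' `seed`, `outdir`. Unknown keys are rejected rather than silently ignored.
#'
#' @param path Path to a YAML file.
#' @return Named list with the resolved configuration.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("inputs", "thresholds", "seed", "outdir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Write pipeline reports for a peak analysis
#'
#' Emits per-feature TSV reports (differential results, persistence calls,
#' cluster assignments), a JSON summary of every gate count, and a resolved
#' copy of the run parameters.
#'
#' @param fit A `"peak_memory"`.
#' @param dir Output directory.
#' @return Invisibly, the summary list.
#' @export
write_peak_reports <- function(fit, dir) {
  stopifnot(inherits(fit, "peak_memory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (stim in names(fit$differential)) {
    write_report(fit$differential[[stim]],
                 file.path(dir, paste0("differential_", stim, ".tsv")),
                 params = fit$params)
  }
  if (!is.null(fit$persistence)) {
    write_report(fit$persistence, file.path(dir, "persistence_calls.tsv"),
                 params = fit$params)
  }
  if (!is.null(fit$clusters)) {
    write_report(data.frame(feature_id = names(fit$clusters$assignments),
                            cluster = unname(fit$clusters$assignments),
                            stringsAsFactors = FALSE),
                 file.path(dir, "trajectory_clusters.tsv"),
                 params = fit$params)
  }
  summary <- list(
    n_input = fit$filter$n_input,
    n_filtered = length(fit$filter$kept),
    n_induced = lapply(fit$induced, length),
    persistence_fractions = as.list(fit$fractions)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
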