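#' Configuration for the synthetic memory-experiment generator
#'
#' Defaults emulate the statistical structure of a stimulus/washout
#' CUT&Tag-RNAseq study: negative-binomial counts over thousands of features,
#' two replicates per condition, an acute-stimulation panel (unstimulated,
#' IFNG 8 h, LPS 8 h, LPS+ruxolitinib 8 h), day-4 washout arms (media /
#' ruxolitinib / anti-IFNG after IFNG; media after LPS), an IFNG washout
#' RNA-seq panel, and LPS-restimulation time courses over
#' \{0, 1, 3, 6, 12\} h in four pretreatment x washout-culture arms. Planted
#' classes carry the memory phenotypes the pipeline must recover.
#'
#' Counts are NB with `var = mu + phi * mu^2`; induced ("de novo") features
#' start from a low baseline range, as nascent enhancers do, which also keeps
#' library-composition bias from planted induction small. Blockade arms
#' (ruxolitinib, anti-IFNG) erase washout persistence effects at the latent
#' log2-mean level, returning planted persistent/increasing features to
#' baseline.
#'
#' @param n_peaks,n_genes Feature counts (defaults 2000 / 3000).
#' @param replicates Replicates per condition (default 2).
#' @param nb_dispersion Peak-count NB dispersion (default 0.2).
#' @param nb_dispersion_genes Gene-count NB dispersion (default 0.02,
#'   i.e. ~14% biological CV: same-donor cultured-macrophage RNA-seq
#'   duplicates are far less dispersed than chromatin assays).
#' @param libsize Nominal library size; realized sizes are log2-uniform within
#'   a factor of 2 of nominal (default 1e7, of the order of the downsampled
#'   depths such studies use).
#' @param baseline_log2cpm Baseline log2 CPM range for unplanted features
#'   (default `c(1, 7)`).
#' @param induced_baseline_log2cpm Baseline log2 CPM range for planted induced
#'   peaks and stimulus-responsive genes (default `c(0, 3)`: de novo enhancers
#'   and strongly inducible genes start near silence, which also keeps
#'   library-composition bias from planted induction small).
#' @param induction_l2fc Acute induction effect for peaks (default 4).
#' @param increase_l2fc Additional washout gain of the further-increasing
#'   class (default 1).
#' @param gene_induction_l2fc Peak LPS/IFNG induction of planted induced genes
#'   (default 4, i.e. 16-fold, matching the acute induction effect used for
#'   peaks).
#' @param potentiation_l2fc,tolerance_l2fc Trained-vs-naive deltas applied at
#'   all post-0 restimulation timepoints (defaults 1.5).
#' @param basal_l2fc Basal set-point elevation of the elevated-basal
#'   potentiated class (default 1).
#' @param peak_class_fractions Named fractions over
#'   `ifng_persistent, ifng_decaying, ifng_increasing, lps_specific, shared`
#'   (remainder null).
#' @param gene_class_fractions Named fractions over
#'   `potentiated_equal_basal, potentiated_elevated_basal, tolerized,
#'   induced_null` (remainder null). Defaults mirror the proportions such
#'   studies report -- a few percent of protein-coding genes LPS-inducible,
#'   an order 1% potentiated and fewer tolerized -- which also keeps the
#'   planted response mass from distorting library composition.
#' @param washout_gene_fractions Named fractions over `band_high, band_mid,
#'   band_low` for the gene washout panel (remainder null).
#' @param couple_enhancers Couple durable enhancers to potentiated genes and
#'   decaying enhancers to non-potentiated induced genes (`TRUE`, default) or
#'   shuffle the pairing to give a null coupling (`FALSE`).
#' @param seed Integer seed; the same config yields identical output.
#' @return Named list of class `"sim_config"`.
#' @export
sim_config <- function(n_peaks = 2000, n_genes = 3000, replicates = 2,
                       nb_dispersion = 0.2, nb_dispersion_genes = 0.02,
                       libsize = 1e7,
                       baseline_log2cpm = c(1, 7),
                       induced_baseline_log2cpm = c(0, 3),
                       induction_l2fc = 4, increase_l2fc = 1,
                       gene_induction_l2fc = 4,
                       potentiation_l2fc = 1.5, tolerance_l2fc = 1.5,
                       basal_l2fc = 1,
                       peak_class_fractions = c(ifng_persistent = 0.10,
                                                ifng_decaying = 0.10,
                                                ifng_increasing = 0.05,
                                                lps_specific = 0.10,
                                                shared = 0.05),
                       gene_class_fractions = c(potentiated_equal_basal = 0.01,
                                                potentiated_elevated_basal = 0.01,
                                                tolerized = 0.01,
                                                induced_null = 0.05),
                       washout_gene_fractions = c(band_high = 0.05,
                                                  band_mid = 0.05,
                                                  band_low = 0.05),
                       couple_enhancers = TRUE, seed = 1) {
  cfg <- as.list(environment())
  if (sum(peak_class_fractions) > 1 || sum(gene_class_fractions) > 1 ||
      sum(washout_gene_fractions) > 1) {
    stop("class fractions must sum to at most 1")
  }
  stopifnot(n_peaks >= 1, n_genes >= 1, replicates >= 1,
            nb_dispersion >= 0, nb_dispersion_genes >= 0)
  structure(cfg, class = "sim_config")
}

# class label vector from fractions; remainder is "null"
assign_classes <- function(n, fractions) {
  counts <- floor(fractions * n)
  labels <- c(rep(names(counts), counts), rep("null", n - sum(counts)))
  labels
}

# NB counts for a latent log2-CPM matrix under per-sample library sizes
nb_counts <- function(log2cpm, libsize, phi) {
  mu <- sweep(2^log2cpm, 2L, libsize / 1e6, "*")
  n <- length(mu)
  counts <- if (phi > 0) {
    stats::rnbinom(n, size = 1 / phi, mu = mu)
  } else {
    stats::rpois(n, mu)
  }
  matrix(as.integer(counts), nrow = nrow(log2cpm), dimnames = dimnames(mu))
}

sample_design <- function(conditions, washout, timepoints, replicates, assay,
                          prefix, arm = NULL) {
  d <- data.frame(
    sample_id = paste0(prefix, rep(conditions, each = replicates), "_r",
                       rep(seq_len(replicates), length(conditions))),
    assay = assay,
    condition = rep(conditions, each = replicates),
    washout_treatment = rep(washout, each = replicates),
    timepoint_h = rep(timepoints, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE
  )
  if (!is.null(arm)) d$arm <- rep(arm, each = replicates)
  d
}

#' Generate a fully labelled synthetic memory dataset
#'
#' Produces three linked experiments with planted truth labels:
#' \describe{
#'   \item{`$peaks`}{acute-stimulation + washout peak panel (features, counts,
#'     design, truth) with planted persistent / decaying / further-increasing
#'     IFNG enhancers, LPS-specific and shared peaks;}
#'   \item{`$gene_washout`}{IFNG induction + washout gene panel with planted
#'     persistence bands;}
#'   \item{`$restim`}{LPS-restimulation time courses in four arms with planted
#'     potentiated (equal / elevated basal) and tolerized genes;}
#'   \item{`$tss`}{TSS annotation placing genes on the synthetic genome;}
#'   \item{`$truth`}{per-experiment class labels and the planted enhancer-gene
#'     couplings.}
#' }
#' Potentiated genes receive a durable (persistent) enhancer within 20 kb of
#' their TSS and non-potentiated induced genes a decaying one, unless
#' `couple_enhancers = FALSE`, in which case the pairing is shuffled.
#'
#' @param config A [sim_config()].
#' @return List of class `"memory_sim"`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reps <- config$replicates

  ## ---- gene classes first (couplings need them) ----
  gene_class <- assign_classes(config$n_genes, config$gene_class_fractions)
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  wash_class <- assign_classes(config$n_genes, config$washout_gene_fractions)

  ## TSS annotation: genes spaced 100 kb apart on chr1, forward strand
  tss <- data.frame(
    gene_id = gene_ids,
    chrom = "chr1",
    tss = 100000L * seq_len(config$n_genes),
    strand = "+",
    protein_coding = TRUE,
    stringsAsFactors = FALSE
  )

  ## ---- peak classes and genomic placement ----
  peak_class <- assign_classes(config$n_peaks, config$peak_class_fractions)
  peak_ids <- sprintf("peak%04d", seq_len(config$n_peaks))

  pot_genes <- which(gene_class %in% c("potentiated_equal_basal",
                                       "potentiated_elevated_basal"))
  neutral_genes <- which(gene_class == "induced_null")
  persistent_peaks <- which(peak_class == "ifng_persistent")
  decaying_peaks <- which(peak_class == "ifng_decaying")
  n_pp <- min(length(pot_genes), length(persistent_peaks))
  n_dd <- min(length(neutral_genes), length(decaying_peaks))
  paired_peaks <- c(persistent_peaks[seq_len(n_pp)], decaying_peaks[seq_len(n_dd)])
  paired_genes <- c(pot_genes[seq_len(n_pp)], neutral_genes[seq_len(n_dd)])
  if (!config$couple_enhancers && length(paired_peaks) > 1) {
    paired_peaks <- sample(paired_peaks)
  }
  chrom <- rep("chr9", config$n_peaks)
  start <- 50000L * seq_len(config$n_peaks)      # far from every gene
  if (length(paired_peaks)) {
    chrom[paired_peaks] <- "chr1"
    start[paired_peaks] <- tss$tss[paired_genes] + 4800L  # midpoint 5 kb downstream
  }
  peaks <- data.frame(chrom = chrom, start = start, end = start + 400L,
                      feature_id = peak_ids, stringsAsFactors = FALSE)
  coupling <- data.frame(
    gene_id = gene_ids[paired_genes],
    feature_id = peak_ids[paired_peaks],
    gene_class = gene_class[paired_genes],
    peak_class = peak_class[paired_peaks],
    stringsAsFactors = FALSE
  )

  ## ---- peak experiment ----
  peak_conditions <- c("UNSTIM", "IFNG_8H", "LPS_8H", "LPS_RUX_8H",
                       "IFNG_WASH_MEDIA", "IFNG_WASH_RUX", "IFNG_WASH_AIFNG",
                       "LPS_WASH_MEDIA")
  peak_washout <- c("none", "none", "none", "none",
                    "media", "rux", "anti_ifng", "media")
  peak_tp <- c(0, 8, 8, 8, 96, 96, 96, 96)
  pdesign <- sample_design(peak_conditions, peak_washout, peak_tp, reps,
                           "cuttag", "pk_")
  ind <- config$induction_l2fc
  peak_eff <- list(  # log2 offsets by condition, per class
    null            = stats::setNames(numeric(8), peak_conditions),
    ifng_persistent = c(0, ind, 0, 0, ind, 0, 0, 0),
    ifng_decaying   = c(0, ind, 0, 0, 0, 0, 0, 0),
    ifng_increasing = c(0, ind, 0, 0, ind + config$increase_l2fc, 0, 0, 0),
    lps_specific    = c(0, 0, ind, ind, 0, 0, 0, 0),
    shared          = c(0, ind, ind, 0, ind, 0, 0, 0)
  )
  base_peak <- numeric(config$n_peaks)
  is_null_pk <- peak_class == "null"
  base_peak[is_null_pk] <- stats::runif(sum(is_null_pk),
                                        config$baseline_log2cpm[1],
                                        config$baseline_log2cpm[2])
  base_peak[!is_null_pk] <- stats::runif(sum(!is_null_pk),
                                         config$induced_baseline_log2cpm[1],
                                         config$induced_baseline_log2cpm[2])
  log2cpm_pk <- matrix(base_peak, config$n_peaks, nrow(pdesign),
                       dimnames = list(peak_ids, pdesign$sample_id))
  for (j in seq_len(nrow(pdesign))) {
    eff <- vapply(peak_class, function(cl) {
      unname(peak_eff[[cl]][match(pdesign$condition[j], peak_conditions)])
    }, numeric(1))
    log2cpm_pk[, j] <- base_peak + eff
  }
  lib_pk <- config$libsize * 2^stats::runif(nrow(pdesign), -1, 1)
  counts_pk <- nb_counts(log2cpm_pk, lib_pk, config$nb_dispersion)

  ## ---- gene washout experiment ----
  gw_conditions <- c("GW_UNSTIM", "GW_IFNG_8H", "GW_WASH_MEDIA", "GW_WASH_RUX")
  gw_washout <- c("none", "none", "media", "rux")
  gw_tp <- c(0, 8, 96, 96)
  gw_design <- sample_design(gw_conditions, gw_washout, gw_tp, reps,
                             "rnaseq", "gw_")
  gi <- config$gene_induction_l2fc
  gw_eff <- list(
    null      = c(0, 0, 0, 0),
    band_high = c(0, gi, gi, 0),
    band_mid  = c(0, gi, gi - 1, 0),
    band_low  = c(0, gi, 0, 0)
  )
  base_gw <- numeric(config$n_genes)
  is_null_gw <- wash_class == "null"
  base_gw[is_null_gw] <- stats::runif(sum(is_null_gw),
                                      config$baseline_log2cpm[1],
                                      config$baseline_log2cpm[2])
  base_gw[!is_null_gw] <- stats::runif(sum(!is_null_gw),
                                  config$induced_baseline_log2cpm[1],
                                  config$induced_baseline_log2cpm[2])
  log2cpm_gw <- matrix(base_gw, config$n_genes, nrow(gw_design),
                       dimnames = list(gene_ids, gw_design$sample_id))
  for (j in seq_len(nrow(gw_design))) {
    eff <- vapply(wash_class, function(cl) {
      unname(gw_eff[[cl]][match(gw_design$condition[j], gw_conditions)])
    }, numeric(1))
    log2cpm_gw[, j] <- base_gw + eff
  }
  lib_gw <- config$libsize * 2^stats::runif(nrow(gw_design), -1, 1)
  counts_gw <- nb_counts(log2cpm_gw, lib_gw, config$nb_dispersion_genes)

  ## ---- restimulation experiment ----
  tps <- c(0, 1, 3, 6, 12)
  arms <- c("pbs_media", "ifng_media", "pbs_rux", "ifng_rux")
  rconditions <- as.vector(t(outer(arms, tps, function(a, t)
    paste0(toupper(a), "_LPS_", t, "H"))))
  rarm <- rep(arms, each = length(tps))
  rtp <- rep(tps, times = length(arms))
  rdesign <- sample_design(rconditions, "media", rtp, reps, "rnaseq", "rs_",
                           arm = rarm)
  rdesign$washout_treatment <- ifelse(grepl("rux", rdesign$arm), "rux", "media")

  shape <- c(0, 2, 3, 3, 2.5) / 3 * gi   # LPS induction profile vs naive 0 h
  pot <- config$potentiation_l2fc
  tol <- config$tolerance_l2fc
  bas <- config$basal_l2fc
  post0 <- c(0, pot, pot, pot, pot)
  arm_eff <- function(cl, arm) {
    switch(cl,
      null = numeric(5),
      induced_null = shape,
      potentiated_equal_basal = switch(arm,
        pbs_media = shape, pbs_rux = shape,
        ifng_media = shape + post0, ifng_rux = shape),
      potentiated_elevated_basal = switch(arm,
        pbs_media = shape, pbs_rux = shape,
        ifng_media = shape + post0 + bas, ifng_rux = shape),
      tolerized = switch(arm,
        pbs_media = shape, pbs_rux = shape,
        ifng_media = shape - c(0, tol, tol, tol, tol), ifng_rux = shape)
    )
  }
  base_rs <- numeric(config$n_genes)
  is_null_rs <- gene_class == "null"
  base_rs[is_null_rs] <- stats::runif(sum(is_null_rs),
                                      config$baseline_log2cpm[1],
                                      config$baseline_log2cpm[2])
  base_rs[!is_null_rs] <- stats::runif(sum(!is_null_rs),
                                  config$induced_baseline_log2cpm[1],
                                  config$induced_baseline_log2cpm[2])
  eff_by_class_arm <- list()
  for (cl in unique(gene_class)) {
    for (a in arms) eff_by_class_arm[[paste(cl, a)]] <- arm_eff(cl, a)
  }
  log2cpm_rs <- matrix(base_rs, config$n_genes, nrow(rdesign),
                       dimnames = list(gene_ids, rdesign$sample_id))
  tp_index <- match(rdesign$timepoint_h, tps)
  for (j in seq_len(nrow(rdesign))) {
    eff <- vapply(gene_class, function(cl) {
      eff_by_class_arm[[paste(cl, rdesign$arm[j])]][tp_index[j]]
    }, numeric(1))
    log2cpm_rs[, j] <- base_rs + eff
  }
  lib_rs <- config$libsize * 2^stats::runif(nrow(rdesign), -1, 1)
  counts_rs <- nb_counts(log2cpm_rs, lib_rs, config$nb_dispersion_genes)

  structure(list(
    peaks = list(features = peaks, counts = counts_pk, design = pdesign),
    gene_washout = list(counts = counts_gw, design = gw_design),
    restim = list(counts = counts_rs, design = rdesign, timepoints = tps),
    tss = tss,
    truth = list(
      peak_class = data.frame(feature_id = peak_ids, class = peak_class,
                              stringsAsFactors = FALSE),
      gene_class = data.frame(gene_id = gene_ids, class = gene_class,
                              stringsAsFactors = FALSE),
      washout_gene_class = data.frame(gene_id = gene_ids, class = wash_class,
                                      stringsAsFactors = FALSE),
      coupling = coupling
    ),
    config = config
  ), class = "memory_sim")
}

#' @export
print.memory_sim <- function(x, ...) {
  cat("Synthetic memory dataset (seed", x$config$seed, ")\n")
  cat("  peaks:", nrow(x$peaks$features), "x", ncol(x$peaks$counts),
      "samples\n")
  cat("  gene washout panel:", nrow(x$gene_washout$counts), "x",
      ncol(x$gene_washout$counts), "samples\n")
  cat("  restimulation panel:", nrow(x$restim$counts), "x",
      ncol(x$restim$counts), "samples\n")
  cat("  planted peak classes:\n")
  print(table(x$truth$peak_class$class))
  cat("  planted gene classes:\n")
  print(table(x$truth$gene_class$class))
  invisible(x)
}

#' Write a synthetic dataset to analysis-ready files
#'
#' Emits the standard external representations (BED, counts TSV, design TSV,
#' TSS TSV) so the analysis entry points can consume a simulated study
#' unmodified. Truth labels go to separate files and are never mixed into the
#' analysis-facing tables.
#'
#' @param sim A `"memory_sim"` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "memory_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_bed(sim$peaks$features, p("peaks.bed"))
  write_counts(sim$peaks$counts, p("peak_counts.tsv"))
  write_design(sim$peaks$design, p("peak_design.tsv"))
  write_counts(sim$gene_washout$counts, p("gene_washout_counts.tsv"),
               id_column = "gene_id")
  write_design(sim$gene_washout$design, p("gene_washout_design.tsv"))
  write_counts(sim$restim$counts, p("restim_counts.tsv"), id_column = "gene_id")
  write_design(sim$restim$design, p("restim_design.tsv"))
  utils::write.table(sim$tss, p("tss.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$peak_class, p("truth_peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_class, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$washout_gene_class, p("truth_washout_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$coupling, p("truth_coupling.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Hand-checkable worked-example fixture
#'
#' A tiny dataset (6 peaks, 8 genes) whose every downstream call can be
#' verified by hand: identical replicates (so the moment dispersion estimate
#' is exactly zero and the exact test reduces to a conditional binomial),
#' equal library sizes enforced by filler features, and round CPM values.
#' Expected outcomes:
#' \itemize{
#'   \item peaks `pk_persist`, `pk_decay`, `pk_increase` are IFNG-induced
#'     (l2fc = log2(40) vs unstimulated); `pk_weak` (l2fc = log2(3)) and
#'     `pk_null` are not;
#'   \item `pk_persist` and `pk_increase` persist under media washout but not
#'     ruxolitinib; `pk_decay` does not persist;
#'   \item `g_pot` is potentiated with equal basal, `g_pot_hi` potentiated
#'     with elevated basal (basal l2fc = 1), `g_alt` fails the
#'     contiguous-timepoint rule, `g_tol` is tolerized;
#'   \item `g_band_hi/mid/lo` land in the >=90\% / 20-90\% / <20\% washout
#'     persistence bands (95, 50, 15 percent).
#' }
#'
#' @return A list shaped like [generate_dataset()] output (without truth
#'   randomness; classes are implicit in the ids).
#' @export
worked_example_fixture <- function() {
  ## ---- peak panel: UNSTIM / IFNG_8H / WASH_MEDIA / WASH_RUX, 2 identical reps
  pk_conditions <- c("UNSTIM", "IFNG_8H", "IFNG_WASH_MEDIA", "IFNG_WASH_RUX")
  pdesign <- sample_design(pk_conditions, c("none", "none", "media", "rux"),
                           c(0, 8, 96, 96), 2, "cuttag", "fx_")
  per_cond <- cbind(
    pk_persist  = c(2, 80, 80, 2),
    pk_decay    = c(2, 80, 2, 2),
    pk_increase = c(2, 80, 160, 2),
    pk_weak     = c(2, 6, 2, 2),
    pk_null     = c(10, 10, 10, 10)
  )
  filler <- 1000 - rowSums(per_cond)
  per_cond <- cbind(per_cond, pk_filler = filler)
  counts_pk <- t(per_cond)[, rep(seq_len(4), each = 2)]
  colnames(counts_pk) <- pdesign$sample_id
  storage.mode(counts_pk) <- "integer"
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr9", "chr9", "chr9"),
    start = c(54800L, 350300L, 120100L, 500000L, 550000L, 600000L),
    end   = c(55200L, 350700L, 120500L, 500400L, 550400L, 600400L),
    feature_id = rownames(counts_pk),
    stringsAsFactors = FALSE
  )
  # pk_persist midpoint 55000: 5 kb downstream of g_pot's TSS (50000)
  # pk_decay   midpoint 350500: 0.5 kb from g_alt's TSS (350000) -> promoter
  # pk_increase midpoint 120300: 19.7 kb beyond g_pot_hi's TSS (100600)

  ## ---- restimulation panel: 4 arms x {0,1,3,6,12} h, 2 identical reps
  tps <- c(0, 1, 3, 6, 12)
  arms <- c("pbs_media", "ifng_media", "pbs_rux", "ifng_rux")
  rconditions <- as.vector(t(outer(arms, tps, function(a, t)
    paste0(toupper(a), "_LPS_", t, "H"))))
  rdesign <- sample_design(rconditions, "media", rep(tps, 4), 2, "rnaseq",
                           "fxr_", arm = rep(arms, each = 5))
  tc_vals <- list(  # per gene: list(pbs_media, ifng_media, pbs_rux, ifng_rux)
    g_pot    = list(c(10, 30, 80, 80, 50), c(10, 30, 200, 200, 50),
                    c(10, 30, 80, 80, 50), c(10, 30, 80, 80, 50)),
    g_pot_hi = list(c(10, 30, 80, 80, 50), c(20, 60, 200, 200, 100),
                    c(10, 30, 80, 80, 50), c(10, 30, 80, 80, 50)),
    g_tol    = list(c(10, 100, 100, 40, 20), c(10, 50, 50, 25, 20),
                    c(10, 60, 60, 40, 20), c(10, 60, 60, 40, 20)),
    g_alt    = list(c(10, 20, 20, 20, 20), c(10, 60, 20, 60, 20),
                    c(10, 20, 20, 20, 20), c(10, 20, 20, 20, 20)),
    g_null   = list(rep(10, 5), rep(10, 5), rep(10, 5), rep(10, 5))
  )
  counts_rs <- matrix(0L, length(tc_vals) + 1L, nrow(rdesign),
                      dimnames = list(c(names(tc_vals), "g_filler"),
                                      rdesign$sample_id))
  for (j in seq_len(nrow(rdesign))) {
    a <- match(rdesign$arm[j], arms)
    tp <- match(rdesign$timepoint_h[j], tps)
    col <- vapply(tc_vals, function(g) g[[a]][tp], numeric(1))
    counts_rs[, j] <- as.integer(c(col, 1000 - sum(col)))
  }

  ## ---- gene washout panel: UNSTIM / IFNG_8H / WASH_MEDIA / WASH_RUX
  gw_design <- sample_design(c("GW_UNSTIM", "GW_IFNG_8H", "GW_WASH_MEDIA",
                               "GW_WASH_RUX"),
                             c("none", "none", "media", "rux"),
                             c(0, 8, 96, 96), 2, "rnaseq", "fxg_")
  gw_vals <- cbind(
    g_band_hi  = c(4, 40, 38, 4),
    g_band_mid = c(4, 40, 20, 4),
    g_band_lo  = c(4, 40, 6, 4),
    g_flat     = c(10, 10, 10, 10)
  )
  gw_vals <- cbind(gw_vals, g_gwfiller = 1000 - rowSums(gw_vals))
  counts_gw <- t(gw_vals)[, rep(seq_len(4), each = 2)]
  colnames(counts_gw) <- gw_design$sample_id
  storage.mode(counts_gw) <- "integer"

  tss <- data.frame(
    gene_id = c("g_pot", "g_pot_hi", "g_tol", "g_alt", "g_null",
                "g_band_hi", "g_band_mid", "g_band_lo", "g_flat"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr2",
              "chr3", "chr3", "chr3", "chr3"),
    tss = c(50000L, 100600L, 200000L, 350000L, 900000L,
            100000L, 200000L, 300000L, 400000L),
    strand = "+",
    protein_coding = TRUE,
    stringsAsFactors = FALSE
  )

  list(
    peaks = list(features = peaks, counts = counts_pk, design = pdesign),
    gene_washout = list(counts = counts_gw, design = gw_design),
    restim = list(counts = counts_rs, design = rdesign, timepoints = tps),
    tss = tss
  )
}
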