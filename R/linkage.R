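#' Link enhancer peaks to candidate target genes by TSS proximity
#'
#' Forms one link per (peak, gene) pair on the same chromosome whose
#' peak-midpoint-to-TSS distance is within `window` base pairs (inclusive),
#' excluding promoter-proximal pairs (within `promoter_window` of the TSS),
#' which reflect promoter rather than distal-enhancer signal. Distances are
#' signed: positive means the peak midpoint lies downstream of the TSS in the
#' gene's orientation. A peak may link to several genes and vice versa.
#'
#' @param peaks Feature table (`chrom`, `start`, `end`, `feature_id`),
#'   typically the induced peak set.
#' @param tss TSS annotation (`gene_id`, `chrom`, `tss`, `strand`,
#'   `protein_coding`); non-protein-coding genes are dropped.
#' @param window Maximum absolute distance in bp (default 20000, inclusive).
#' @param promoter_window Promoter exclusion radius in bp (default 1000;
#'   pairs with absolute distance <= this are dropped).
#' @param keep_promoter_proximal Keep promoter-proximal pairs in the output,
#'   flagged, instead of dropping them (default `FALSE`).
#' @return `data.frame` with `feature_id`, `gene_id`, `distance`,
#'   `promoter_proximal`.
#' @export
link_peaks_to_genes <- function(peaks, tss, window = 20000,
                                promoter_window = 1000,
                                keep_promoter_proximal = FALSE) {
  validate_feature_set(peaks)
  tss <- validate_tss(tss)
  tss <- tss[tss$protein_coding, , drop = FALSE]
  out <- list()
  mid <- (peaks$start + peaks$end) / 2
  for (chr in intersect(unique(peaks$chrom), unique(tss$chrom))) {
    pk <- which(peaks$chrom == chr)
    gn <- which(tss$chrom == chr)
    d <- outer(mid[pk], tss$tss[gn], "-")           # + means right of TSS
    strand_sign <- ifelse(tss$strand[gn] == "+", 1, -1)
    d <- sweep(d, 2L, strand_sign, "*")             # + means downstream
    hit <- which(abs(d) <= window, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[chr]] <- data.frame(
      feature_id = peaks$feature_id[pk[hit[, 1L]]],
      gene_id = tss$gene_id[gn[hit[, 2L]]],
      distance = d[hit],
      promoter_proximal = abs(d[hit]) <= promoter_window,
      stringsAsFactors = FALSE
    )
  }
  links <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(), gene_id = character(),
               distance = numeric(), promoter_proximal = logical())
  rownames(links) <- NULL
  if (!keep_promoter_proximal) {
    links <- links[!links$promoter_proximal, , drop = FALSE]
    rownames(links) <- NULL
  }
  links
}

#' Relate gene potentiation to linked-enhancer durability
#'
#' For every enhancer-gene link whose gene passes the LPS-induction gate,
#' pairs the gene's mean potentiation score with the linked peak's washout
#' log2 fold change (washout vs unstimulated) and reports the Spearman rank
#' correlation with a two-sided p-value. Genes with several linked peaks
#' contribute one pair per link.
#'
#' @param links Link table from [link_peaks_to_genes()] (promoter-proximal
#'   pairs already excluded).
#' @param gene_scores `data.frame` with `gene_id`, `mean_potentiation`, and a
#'   logical `lps_induced` gate column.
#' @param peak_washout Differential result `data.frame` (washout vs
#'   unstimulated) with `feature_id` and `l2fc`.
#' @return List of class `"potentiation_durability"`: `pairs` (the per-link
#'   table), `rho`, `p.value`, `n`.
#' @export
potentiation_vs_durability <- function(links, gene_scores, peak_washout) {
  stopifnot(all(c("gene_id", "mean_potentiation", "lps_induced") %in%
                  names(gene_scores)),
            all(c("feature_id", "l2fc") %in% names(peak_washout)))
  gi <- match(links$gene_id, gene_scores$gene_id)
  pi <- match(links$feature_id, peak_washout$feature_id)
  keep <- !is.na(gi) & !is.na(pi) & gene_scores$lps_induced[gi]
  pairs <- data.frame(
    feature_id = links$feature_id[keep],
    gene_id = links$gene_id[keep],
    mean_potentiation = gene_scores$mean_potentiation[gi[keep]],
    enhancer_washout_l2fc = peak_washout$l2fc[pi[keep]],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (nrow(pairs) < 3L) {
    stop("correlation undefined: fewer than 3 enhancer-gene pairs")
  }
  ct <- suppressWarnings(stats::cor.test(pairs$mean_potentiation,
                                         pairs$enhancer_washout_l2fc,
                                         method = "spearman", exact = FALSE))
  structure(list(pairs = pairs, rho = unname(ct$estimate),
                 p.value = ct$p.value, n = nrow(pairs)),
            class = "potentiation_durability")
}

#' @export
print.potentiation_durability <- function(x, ...) {
  cat("Enhancer durability vs gene potentiation\n")
  cat(sprintf("  pairs: %d | Spearman rho = %.3f | p = %.3g\n",
              x$n, x$rho, x$p.value))
  invisible(x)
}
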