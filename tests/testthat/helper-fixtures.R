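# shared builders and independent oracles

# small named count matrix
toy_counts <- function(values, features, samples) {
  matrix(as.integer(values), nrow = length(features), byrow = TRUE,
         dimnames = list(features, samples))
}

toy_design <- function(sample_id, condition, timepoint_h = 0,
                       washout_treatment = "none") {
  data.frame(sample_id = sample_id, assay = "test", condition = condition,
             washout_treatment = washout_treatment, timepoint_h = timepoint_h,
             replicate = stats::ave(seq_along(sample_id), condition,
                                    FUN = seq_along),
             stringsAsFactors = FALSE)
}

# restimulation time-course object from per-arm CPM matrices
toy_tc <- function(arms, timepoints = c(0, 1, 3, 6, 12)) {
  arms <- lapply(arms, function(m) {
    m <- as.matrix(m)
    colnames(m) <- as.character(timepoints)
    m
  })
  structure(list(arms = arms, timepoints = timepoints),
            class = "restim_timecourse")
}

# Oracle 1: two-sided conditional binomial p (dispersion-0 exact test),
# written directly from choose() in log space, independent of the package's
# dnbinom-based path.
binom_cond_pvalue_oracle <- function(y_trt, total, n_trt, n_ref) {
  if (total == 0) return(1)
  a <- 0:total
  p <- n_trt / (n_trt + n_ref)
  logp <- lchoose(total, a) + a * log(p) + (total - a) * log1p(-p)
  sum(exp(logp[logp <= logp[y_trt + 1] + 1e-8]))
}

# Oracle 2: signed-rank p by full 2^m enumeration of sign assignments
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  mid <- sum(r) / 2
  if (w_obs > mid) {
    p <- 2 * mean(w_all >= w_obs - 1e-9)
  } else if (w_obs < mid) {
    p <- 2 * mean(w_all <= w_obs + 1e-9)
  } else {
    p <- 1
  }
  min(1, p)
}
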