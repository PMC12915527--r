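test_that("dispersion estimation recovers Poisson and NB truth", {
  set.seed(3)
  cts_p <- matrix(rpois(20 * 6, 100), 20, 6,
                  dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
  dp <- estimate_dispersion(cts_p, paste0("s", 1:3), paste0("s", 4:6))
  expect_lte(dp$common, 0.05)

  set.seed(4)
  cts_n <- matrix(rnbinom(200 * 6, size = 1 / 0.4, mu = 200), 200, 6,
                  dimnames = list(paste0("f", 1:200), paste0("s", 1:6)))
  dn <- estimate_dispersion(cts_n, paste0("s", 1:3), paste0("s", 4:6))
  expect_gte(dn$common, 0.2)
  expect_lte(dn$common, 0.6)
  # blend identity: final = w * common + (1 - w) * per_feature, all >= 0
  expect_equal(dn$final,
               dn$shrinkage_weight * dn$common +
                 (1 - dn$shrinkage_weight) * dn$per_feature)
  expect_true(all(dn$final >= 0))

  # one replicate per group: defined common-only fallback
  d1 <- estimate_dispersion(cts_n[, c(1, 4)], "s1", "s4")
  expect_true(all(d1$per_feature == d1$common))
})

test_that("exact test handles degenerate splits and the dispersion-0 bound", {
  # identical counts in both groups: observed split is the mode
  cts <- toy_counts(c(5, 5, 5, 5, 9, 9, 9, 9), c("f1", "f2"),
                    paste0("s", 1:4))
  res <- nb_exact_test(cts, c("s1", "s2"), c("s3", "s4"), dispersion = 0)
  expect_equal(res$pvalue, c(1, 1))
  expect_equal(res$l2fc, c(0, 0))

  # (0,0) vs (50,50) at dispersion 0: conditional binomial two-tail
  cts2 <- rbind(f1 = c(0L, 0L, 50L, 50L), f2 = c(100L, 100L, 50L, 50L))
  colnames(cts2) <- paste0("s", 1:4)
  res2 <- nb_exact_test(cts2, c("s1", "s2"), c("s3", "s4"), dispersion = 0)
  expect_equal(res2$pvalue[1], 2 * 0.5^100, tolerance = 1e-10)
})

test_that("exact test matches independent conditional-binomial enumeration", {
  set.seed(5)
  for (i in 1:20) {
    n_ref <- sample(1:3, 1)
    n_trt <- sample(1:3, 1)
    ref_counts <- rpois(n_ref, 20)
    trt_counts <- rpois(n_trt, 60)
    cts <- matrix(c(ref_counts, trt_counts, rep(30L, n_ref + n_trt)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("f1", "bal"),
                                  paste0("s", seq_len(n_ref + n_trt))))
    ref <- paste0("s", seq_len(n_ref))
    trt <- paste0("s", n_ref + seq_len(n_trt))
    # equal library sizes make the equalized pseudo-counts the raw counts
    cts[2, ] <- as.integer(200 - cts[1, ])
    res <- nb_exact_test(cts, ref, trt, dispersion = 0)
    expected <- binom_cond_pvalue_oracle(sum(cts[1, trt]), sum(cts[1, ]),
                                         n_trt, n_ref)
    expect_equal(res$pvalue[1], expected, tolerance = 1e-9)
  }
})

test_that("exact test agrees with an established NB exact implementation", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  n <- 200
  cts <- matrix(rnbinom(n * 4, size = 5, mu = 100), n, 4,
                dimnames = list(paste0("f", 1:n), paste0("s", 1:4)))
  mine <- nb_exact_test(cts, c("s1", "s2"), c("s3", "s4"), dispersion = 0.2)
  dge <- edgeR::DGEList(cts, group = c(1, 1, 2, 2),
                        lib.size = rep(sum(cts) / 4, 4))
  theirs <- edgeR::exactTest(dge, dispersion = 0.2)$table$PValue
  expect_gt(cor(log(mine$pvalue), log(theirs)), 0.995)
  expect_lt(max(abs(log10(mine$pvalue) - log10(theirs))), 0.15)
})

test_that("swapping group labels negates l2fc and preserves p-values", {
  set.seed(6)
  cts <- matrix(rnbinom(40 * 6, size = 5, mu = 80), 40, 6,
                dimnames = list(paste0("f", 1:40), paste0("s", 1:6)))
  a <- paste0("s", 1:3)
  b <- paste0("s", 4:6)
  fwd <- nb_exact_test(cts, a, b, dispersion = 0.2)
  rev <- nb_exact_test(cts, b, a, dispersion = 0.2)
  expect_equal(fwd$pvalue, rev$pvalue)
  expect_equal(fwd$l2fc, -rev$l2fc)
  expect_equal(fwd$mean_cpm_ref, rev$mean_cpm_trt)

  # fold changes are CPM-scale quantities: depth-scaling a sample leaves them
  cts2 <- cts
  cts2[, 1] <- cts[, 1] * 3L
  fwd2 <- nb_exact_test(cts2, a, b, dispersion = 0.2)
  expect_equal(fwd2$l2fc, fwd$l2fc, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))                 # adjusted never below raw
  expect_true(all(adj <= 1))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12)) # monotone in sorted-p order
})

test_that("induced calls use strict cutoffs", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    l2fc = c(2.0, 3, 5, 2.5),
                    fdr = c(0.001, 0.005, 0.01, 0.02))
  expect_equal(call_induced(res), "b")       # boundary l2fc and fdr excluded
  expect_equal(call_induced(res, l2fc_min = 1.9, fdr_max = 0.05),
               c("a", "b", "c", "d"))
})
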