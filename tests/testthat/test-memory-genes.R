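test_that("induced-gene calls use an inclusive fold threshold", {
  stim <- c(g1 = 5, g2 = 4.9, g3 = 50)
  base <- c(g1 = 1, g2 = 1, g3 = 1)
  expect_equal(call_induced_genes(stim, base), c("g1", "g3"))  # 5.0 passes
  expect_error(call_induced_genes(c(g1 = NA), c(g1 = 1)), "missing")
})

test_that("planted 8-fold induced genes are recovered from a full panel", {
  cfg <- sim_config(n_genes = 3000, gene_induction_l2fc = 3,
                    washout_gene_fractions = c(band_high = 0.10), seed = 17)
  sim <- generate_dataset(cfg)
  gfit <- gene_memory_analysis(washout = sim$gene_washout)
  truth <- sim$truth$washout_gene_class
  planted <- truth$gene_id[truth$class != "null"]
  expect_equal(length(planted), 300)
  expect_gte(mean(planted %in% gfit$washout$induced), 0.95)
  false_calls <- sum(!gfit$washout$induced %in% planted)
  expect_lte(false_calls, 0.01 * (nrow(truth) - length(planted)))
})

test_that("persistence percents band into an exhaustive, exclusive partition", {
  expect_equal(unname(persistence_percent(c(50, 45, 9), c(50, 50, 50))),
               c(100, 90, 18))
  b <- persistence_band(c(100, 90, 18, 89.999, 20, 19.999, 0))
  expect_equal(as.character(b),
               c(">=90%", ">=90%", "<20%", "20-90%", "20-90%", "<20%", "<20%"))

  set.seed(12)
  pct <- c(runif(200, 0, 200), 0, 20, 90)
  bands <- persistence_band(pct)
  expect_false(anyNA(bands))                     # exhaustive
  expect_equal(length(bands), length(pct))       # one band each
  expect_error(persistence_band(-1), "percent >= 0")
})

test_that("potentiation requires induction plus contiguous fold excess", {
  tps <- c(0, 1, 3, 6, 12)
  mk <- function(pbs, ratio) toy_tc(list(
    pbs_media = matrix(pbs, 1, 5, dimnames = list("g", NULL)),
    ifng_media = matrix(pbs * ratio, 1, 5, dimnames = list("g", NULL))
  ), tps)

  # alternating ratios {1,3,1,3,1}: 10-fold induced but never 2 consecutive
  alt <- mk(c(10, 100, 20, 100, 20), c(1, 3, 1, 3, 1))
  expect_false(call_potentiated(alt)$potentiated)

  # ratios {1,1,2,2,1} with 6-fold induction: timepoints 3 and 6 h qualify
  ok <- mk(c(10, 20, 60, 60, 20), c(1, 1, 2, 2, 1))
  pot <- call_potentiated(ok)
  expect_true(pot$potentiated)
  expect_equal(pot$max_run, 2L)

  # ratios all >= 4 but induction only 3-fold: fails the LPS gate
  weak <- mk(c(10, 30, 30, 30, 30), c(4, 4, 4, 4, 4))
  expect_false(call_potentiated(weak)$potentiated)
  expect_true(call_potentiated(weak, lps_fold_min = 3)$potentiated)
})

test_that("potentiation calls are order-invariant and threshold-monotone", {
  set.seed(13)
  tps <- c(0, 1, 3, 6, 12)
  pbs <- matrix(2^runif(50, 3, 7), 10, 5,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
  ifng <- pbs * 2^matrix(rnorm(50, 0.6, 0.8), 10, 5)
  tc <- toy_tc(list(pbs_media = pbs, ifng_media = ifng), tps)

  base <- call_potentiated(tc, lps_fold_min = 1)
  perm <- sample(10)
  tc_perm <- toy_tc(list(pbs_media = pbs[perm, ], ifng_media = ifng[perm, ]), tps)
  shuffled <- call_potentiated(tc_perm, lps_fold_min = 1)
  expect_equal(shuffled[match(base$gene_id, shuffled$gene_id), ], base,
               ignore_attr = TRUE)

  # raising delta_fold_min never adds a gene: called sets are nested
  sets <- lapply(c(1.5, 2, 3, 4), function(thr) {
    p <- call_potentiated(tc, lps_fold_min = 1, delta_fold_min = thr)
    p$gene_id[p$potentiated]
  })
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("tolerance requires contiguous reduction plus JAK-independent induction", {
  tps <- c(0, 1, 3, 6)
  mk <- function(ratio, rux_peak) toy_tc(list(
    pbs_media = matrix(c(10, 40, 40, 20), 1, 4, dimnames = list("g", NULL)),
    ifng_media = matrix(c(10, 40, 40, 20) / ratio, 1, 4,
                        dimnames = list("g", NULL)),
    pbs_rux = matrix(c(10, rux_peak, rux_peak, 10), 1, 4,
                     dimnames = list("g", NULL))
  ), tps)

  tol <- call_tolerized(mk(c(1, 2, 2, 1), 50))    # 5-fold rux induction
  expect_true(tol$tolerized)

  expect_false(call_tolerized(mk(c(2, 1, 2, 1), 50))$tolerized)  # no contiguity
  expect_false(call_tolerized(mk(c(4, 4, 4, 4), 20))$tolerized)  # rux 2-fold
})

test_that("basal split is strict at the threshold", {
  tc <- toy_tc(list(
    pbs_media = matrix(rep(10, 15), 3, 5,
                       dimnames = list(c("same", "double", "edge"), NULL)),
    ifng_media = matrix(c(10, rep(10, 4), 20, rep(20, 4),
                          10 * 2^0.5, rep(10, 4)), 3, 5, byrow = TRUE,
                        dimnames = list(c("same", "double", "edge"), NULL))
  ))
  sp <- split_basal(tc)
  # ratio 1 -> l2fc 0 (equal); ratio 2 -> l2fc 1 (elevated)
  expect_equal(sp$basal_elevated[1:2], c(FALSE, TRUE))
  expect_equal(sp$basal_l2fc[1:2], c(0, 1))
  # boundary is strict: a gene sitting exactly at the threshold stays in the
  # equal-basal class (ratio 2 against threshold l2fc 1 is exactly log2 = 1)
  sp1 <- split_basal(tc, threshold_l2fc = 1)
  expect_false(sp1$basal_elevated[sp1$gene_id == "double"])
})

test_that("mean potentiation averages the arm-wise delta L2FC over time", {
  pbs <- matrix(c(10, 20, 40, 40, 20), 1, 5, dimnames = list("g", NULL))
  same <- toy_tc(list(pbs_media = pbs, ifng_media = pbs))
  expect_equal(unname(mean_potentiation(same)), 0)

  # deltas {1, 2, 3, 2} at the four post-0 timepoints -> mean 2
  ifng <- pbs * 2^matrix(c(0, 1, 2, 3, 2), 1, 5)
  tc <- toy_tc(list(pbs_media = pbs, ifng_media = ifng))
  expect_equal(unname(mean_potentiation(tc)), 2)

  # cancellation on a two-point grid
  pbs2 <- matrix(c(10, 20, 20), 1, 3, dimnames = list("g", NULL))
  ifng2 <- pbs2 * 2^matrix(c(0, -1, 1), 1, 3)
  tc2 <- toy_tc(list(pbs_media = pbs2, ifng_media = ifng2),
                timepoints = c(0, 1, 3))
  expect_equal(unname(mean_potentiation(tc2)), 0)
})
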