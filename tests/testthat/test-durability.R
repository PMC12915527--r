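test_that("persistence calls honor the inclusive-l2fc / strict-FDR rule", {
  res <- list(media = data.frame(
    feature_id = c("p1", "p2", "p3"),
    l2fc = c(0.0, 1.5, -0.1),
    fdr = c(0.001, 0.02, 0.001)
  ))
  calls <- call_persistence(c("p1", "p2", "p3"), res)
  expect_equal(calls$persistent, c(TRUE, FALSE, FALSE))
  # p1: l2fc exactly 0 is persistent; p2 fails FDR; p3 fails l2fc

  expect_error(call_persistence(c("p1", "missing"), res), "missing")
})

test_that("persistence fraction is a plain ratio, order-invariant", {
  calls <- data.frame(
    feature_id = sprintf("f%d", 1:16),
    washout_treatment = "media",
    persistent = c(rep(TRUE, 13), rep(FALSE, 3))
  )
  expect_equal(persistence_fraction(calls, "media"), 0.8125)
  shuffled <- calls[sample(nrow(calls)), ]
  expect_equal(persistence_fraction(shuffled, "media"), 0.8125)

  calls$persistent <- FALSE
  expect_equal(persistence_fraction(calls, "media"), 0)
  calls$persistent <- TRUE
  expect_equal(persistence_fraction(calls, "media"), 1)
  expect_error(persistence_fraction(calls, "rux"), "no persistence calls")
})

test_that("signed-rank test reproduces exact enumeration values", {
  # five identical positive deltas: only the all-plus and all-minus sign
  # patterns reach |W| this extreme -> p = 2/2^5
  r <- signed_rank_test(rep(1, 5))
  expect_equal(r$p.value, 0.0625)
  expect_equal(r$method, "exact")

  # symmetric deltas (zero dropped): W sits at the null mean
  expect_equal(signed_rank_test(c(-2, -1, 0, 1, 2))$p.value, 1)

  expect_error(signed_rank_test(c(0, 0, 1)), "fewer than 2")
})

test_that("signed-rank exact branch matches brute-force sign enumeration", {
  set.seed(8)
  for (i in 1:25) {
    m <- sample(3:12, 1)
    d <- round(rnorm(m), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(signed_rank_test(d)$p.value, signed_rank_oracle(d),
                 tolerance = 1e-12, label = paste("case", i))
  }
  # and agrees with stats::wilcox.test when ties are absent
  set.seed(9)
  d <- rnorm(10)
  expect_equal(signed_rank_test(d)$p.value,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("normal-approximation branch is close to exact near the cutover", {
  set.seed(10)
  d <- rnorm(26, mean = 0.3)
  approx_p <- signed_rank_test(d)$p.value             # 26 pairs: normal
  exact_p <- signed_rank_test(d, exact_max = 30)$p.value
  expect_equal(signed_rank_test(d)$method, "normal")
  expect_equal(approx_p, exact_p, tolerance = 0.08)
})

test_that("washout delta stats summarize log2 shifts with a paired test", {
  d <- toy_design(c("s1", "s2"), c("PRE", "POST"))
  pre <- c(f1 = 10, f2 = 20, f3 = 40, f4 = 80, f5 = 160)
  cpm <- cbind(s1 = pre, s2 = pre * 2)   # every delta exactly +1
  out <- washout_delta_stats(cpm, d, names(pre), "PRE", "POST")
  expect_equal(out$mean_delta, 1)
  expect_equal(out$p.value, 0.0625)

  same <- cbind(s1 = pre, s2 = pre)      # no shift at all
  out0 <- washout_delta_stats(same, d, names(pre), "PRE", "POST")
  expect_equal(out0$mean_delta, 0)
  expect_true(is.na(out0$p.value))       # all zero deltas dropped
})

test_that("trajectory clustering recovers planted archetypes deterministically", {
  set.seed(11)
  up <- matrix(rep(c(0, 4, 4), each = 30), 30, 3) + rnorm(90, sd = 0.3)
  down <- matrix(rep(c(4, 4, 0), each = 30), 30, 3) + rnorm(90, sd = 0.3)
  prof <- rbind(up, down)
  dimnames(prof) <- list(sprintf("f%02d", 1:60), c("unstim", "stim", "wash"))

  cl <- cluster_trajectories(prof, k = 2, seed = 42, order_by = "wash")
  expect_equal(unname(cl$assignments[1:30]), rep(1L, 30))   # washout-high first
  expect_equal(unname(cl$assignments[31:60]), rep(2L, 30))

  cl2 <- cluster_trajectories(prof, k = 2, seed = 42, order_by = "wash")
  expect_identical(cl$assignments, cl2$assignments)          # same seed, same fit

  one <- cluster_trajectories(prof, k = 1, seed = 1, order_by = "wash")
  expect_equal(length(unique(one$assignments)), 1L)
  z <- t(scale(t(prof)))
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(z)),
               tolerance = 1e-8)

  expect_error(cluster_trajectories(prof, k = 100, seed = 1), "k exceeds")

  flat <- rbind(prof, zv = c(2, 2, 2))   # zero-variance feature excluded
  clf <- cluster_trajectories(flat, k = 2, seed = 1, order_by = "wash")
  expect_equal(clf$excluded, "zv")
  expect_false("zv" %in% names(clf$assignments))
})
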