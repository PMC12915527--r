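test_that("generator is deterministic: same config, identical files", {
  cfg <- sim_config(n_peaks = 60, n_genes = 40, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$peaks$counts, b$peaks$counts)
  expect_identical(a$restim$counts, b$restim$counts)

  dir_a <- file.path(withr::local_tempdir(), "a")
  dir_b <- file.path(withr::local_tempdir(), "b")
  write_dataset(a, dir_a)
  write_dataset(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)), label = f)
  }
})

test_that("class fractions, labels and couplings are internally consistent", {
  cfg <- sim_config(n_peaks = 200, n_genes = 100, seed = 2)
  sim <- generate_dataset(cfg)
  expect_equal(nrow(sim$truth$peak_class), 200)
  expect_false(anyNA(sim$truth$peak_class$class))
  expect_equal(sum(sim$truth$peak_class$class == "ifng_persistent"), 20)

  # couplings place a peak within the linkage window of the gene TSS
  cp <- sim$truth$coupling
  expect_gt(nrow(cp), 0)
  pk <- sim$peaks$features[match(cp$feature_id, sim$peaks$features$feature_id), ]
  ts <- sim$tss[match(cp$gene_id, sim$tss$gene_id), ]
  d <- (pk$start + pk$end) / 2 - ts$tss
  expect_true(all(abs(d) <= 20000 & abs(d) > 1000))
  expect_true(all(pk$chrom == ts$chrom))

  # truth labels never leak into the analysis-facing tables
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  counts_cols <- colnames(read_counts(file.path(dir, "peak_counts.tsv"),
                                      sim$peaks$design))
  expect_false(any(grepl("class|truth", counts_cols)))

  expect_error(sim_config(peak_class_fractions = c(ifng_persistent = 1.2)),
               "at most 1")
})

test_that("realized library sizes follow the drawn log-uniform depths", {
  # with no planted effects, column sums differ across samples only through
  # the factor-of-two log-uniform library draw (plus count noise)
  cfg <- sim_config(n_peaks = 500, n_genes = 50,
                    peak_class_fractions = c(ifng_persistent = 0), seed = 3)
  sim <- generate_dataset(cfg)
  libs <- colSums(sim$peaks$counts)
  expect_true(all(libs > 0))
  expect_lt(max(libs) / min(libs), 4.5)
})

test_that("an all-null dataset yields only FDR-level induced calls", {
  cfg <- sim_config(n_peaks = 2000,
                    peak_class_fractions = c(ifng_persistent = 0), seed = 5)
  sim <- generate_dataset(cfg)
  d <- sim$peaks$design
  res <- nb_exact_test(sim$peaks$counts,
                       d$sample_id[d$condition == "UNSTIM"],
                       d$sample_id[d$condition == "IFNG_8H"])
  expect_lte(length(call_induced(res)), 0.01 * nrow(sim$peaks$counts))
})

test_that("planted persistent/decaying mix reproduces the expected fractions", {
  cfg <- sim_config(n_peaks = 1000,
                    peak_class_fractions = c(ifng_persistent = 0.1,
                                             ifng_decaying = 0.1),
                    seed = 6)
  sim <- generate_dataset(cfg)
  d <- sim$peaks$design
  fit <- peak_memory_analysis(sim$peaks$counts, d,
                              stim_conditions = c(ifng = "IFNG_8H"),
                              washout_conditions = c(media = "IFNG_WASH_MEDIA",
                                                     rux = "IFNG_WASH_RUX"))
  expect_gt(fit$fractions[["media"]], 0.4)
  expect_lt(fit$fractions[["media"]], 0.6)
  expect_lte(fit$fractions[["rux"]], 0.1)
})

test_that("recall of induced calls degrades as dispersion grows", {
  recall_at <- function(phi) {
    cfg <- sim_config(n_peaks = 800, nb_dispersion = phi,
                      induction_l2fc = 2.5,
                      peak_class_fractions = c(ifng_persistent = 0.05),
                      seed = 7)
    sim <- generate_dataset(cfg)
    d <- sim$peaks$design
    res <- nb_exact_test(sim$peaks$counts,
                         d$sample_id[d$condition == "UNSTIM"],
                         d$sample_id[d$condition == "IFNG_8H"])
    planted <- sim$truth$peak_class$feature_id[
      sim$truth$peak_class$class != "null"]
    mean(planted %in% call_induced(res))
  }
  r <- vapply(c(0.05, 0.3, 1.0), recall_at, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("the worked-example fixture is structurally valid", {
  fx <- worked_example_fixture()
  expect_true(all(colSums(fx$peaks$counts) == 1000))
  expect_true(all(colSums(fx$restim$counts) == 1000))
  expect_true(all(colSums(fx$gene_washout$counts) == 1000))
  expect_identical(colnames(fx$peaks$counts), fx$peaks$design$sample_id)
  validate_tss(fx$tss)
})
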