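test_that("ks sampling is deterministic and hits its component means", {
  spec <- ks_mixture_spec(means = 0.5, sds = 0.05, weights = 1,
                          background_fraction = 0, n = 2000, seed = 60)
  x <- sample_ks(spec)
  expect_equal(length(x), 2000)
  expect_equal(mean(x), 0.5, tolerance = 0.01)
  expect_identical(x, sample_ks(spec))
  expect_true(all(x >= 0))
  # vanishing spread collapses onto the means
  tight <- ks_mixture_spec(means = c(0.2, 0.8), sds = c(1e-6, 1e-6),
                           weights = c(0.5, 0.5), background_fraction = 0,
                           n = 500, seed = 61)
  y <- sample_ks(tight)
  expect_true(all(pmin(abs(y - 0.2), abs(y - 0.8)) < 1e-4))
  expect_error(ks_mixture_spec(means = 0.5, sds = 0.05, weights = 0.9),
               "sum to 1")
})

test_that("zero-depth duplicates are identical and estimate to ks 0", {
  sim <- simulate_duplicated_transcriptome(n_families = 2, depths = 0,
                                           codons_per_gene = 100, seed = 62)
  expect_equal(sim$records$seq[1], sim$records$seq[2])
  expect_equal(estimate_ks(sim$records$seq[1], sim$records$seq[2])$ks, 0)
  expect_equal(sim$truth$realized_ps, c(0, 0))
})

test_that("planted depth 0.5 is recovered by the estimator within 0.06", {
  sim <- simulate_duplicated_transcriptome(n_families = 1, depths = 0.5,
                                           codons_per_gene = 500,
                                           omega = 0.2, seed = 63)
  r <- estimate_ks(sim$records$seq[1], sim$records$seq[2])
  expect_equal(r$ks, 0.5, tolerance = 0.06)
  expect_equal(r$ks, sim$truth$realized_ks, tolerance = 1e-9)
})

test_that("truth-table bookkeeping scales with families and depths", {
  sim <- simulate_duplicated_transcriptome(n_families = 10,
                                           depths = c(0.1, 0.5, 0.9),
                                           codons_per_gene = 60, seed = 64)
  expect_equal(nrow(sim$truth), 30)
  expect_equal(nrow(sim$records), 60)
  expect_false(anyDuplicated(sim$records$id) > 0)
  expect_true(all(sim$truth$id_a %in% sim$records$id))
})

test_that("the same seed yields byte-identical FASTA output", {
  sim1 <- simulate_duplicated_transcriptome(n_families = 3, depths = 0.3,
                                            codons_per_gene = 80, seed = 65)
  sim2 <- simulate_duplicated_transcriptome(n_families = 3, depths = 0.3,
                                            codons_per_gene = 80, seed = 65)
  f1 <- tmp_fasta(sim1$records); f2 <- tmp_fasta(sim2$records)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the sequences
  sim3 <- simulate_duplicated_transcriptome(n_families = 3, depths = 0.3,
                                            codons_per_gene = 80, seed = 66)
  expect_false(identical(sim1$records$seq, sim3$records$seq))
})

test_that("planted and estimated Ks agree with slope near one across depths", {
  depths <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)
  sim <- simulate_duplicated_transcriptome(n_families = 8, depths = depths,
                                           codons_per_gene = 500, seed = 67)
  tab <- ks_table(sim$records,
                  sim$truth[, c("id_a", "id_b")])
  expect_true(all(tab$status == "ok"))
  fit <- stats::lm(tab$ks ~ sim$truth$planted_ks)
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
})

test_that("unreachable depths are refused", {
  expect_error(simulate_duplicated_transcriptome(n_families = 1, depths = Inf,
                                                 codons_per_gene = 60,
                                                 seed = 68),
               "unattainable")
  expect_error(simulate_duplicated_transcriptome(n_families = 1, depths = -1,
                                                 codons_per_gene = 60,
                                                 seed = 68),
               "non-negative")
  expect_error(simulate_duplicated_transcriptome(n_families = 1, depths = 0.5,
                                                 codons_per_gene = 10,
                                                 seed = 68),
               "at least 50")
})
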