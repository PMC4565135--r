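test_that("paired t statistic matches the textbook formula and t.test", {
  diffs <- matrix(c(1.0, 1.2, 0.8), nrow = 1)
  ds <- dataset_from_diffs(diffs)
  res <- paired_t_test(ds)
  # oracle: t = mean / (sd / sqrt(n)), df = n - 1, two-sided
  d <- c(1.0, 1.2, 0.8)
  t_exp <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t_stat, t_exp)
  expect_equal(res$p_value, 2 * pt(-abs(t_exp), df = 2))
  expect_equal(res$mean_log2_diff, 1)
  expect_equal(res$direction, "up")
  # independent cross-check against stats::t.test
  tt <- t.test(c(9, 9.2, 8.8), c(8, 8, 8), paired = TRUE)
  expect_equal(res$t_stat, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("degenerate and antisymmetric cases behave as documented", {
  ds0 <- dataset_from_diffs(matrix(0, 1, 5))
  r0 <- paired_t_test(ds0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$direction, "flat")
  expect_true(r0$degenerate)

  ds <- dataset_from_diffs(matrix(c(1, 1.2, 0.8, 0.3, -0.1, 0.2), 2,
                                  byrow = TRUE))
  swapped <- ds
  swapped$pairs[, c("tumour", "normal")] <- ds$pairs[, c("normal", "tumour")]
  a <- paired_t_test(ds)
  b <- paired_t_test(swapped)
  expect_equal(b$t_stat, -a$t_stat)
  expect_equal(b$p_value, a$p_value)

  expect_error(paired_t_test(dataset_from_diffs(matrix(1, 2, 1))),
               "at least 2 pairs")
})

test_that("pi0 estimation is calibrated on known mixtures", {
  set.seed(4)
  expect_true(estimate_pi0(runif(10000)) >= 0.95)
  expect_true(estimate_pi0(runif(10000)) <= 1)
  mix <- c(runif(5000), rbeta(5000, 0.5, 25))
  expect_equal(estimate_pi0(mix), 0.5, tolerance = 0.1)
  expect_equal(estimate_pi0(rep(1, 500)), 1)
  expect_equal(estimate_pi0(runif(10), method = "fixed", pi0 = 0.7), 0.7)
  expect_error(estimate_pi0(numeric(0)), "no p-values")
  expect_error(estimate_pi0(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("adaptive threshold is 1/(pi0 N) and monotone", {
  expect_equal(significance_threshold(1, 22277), 1 / 22277)
  expect_equal(significance_threshold(0.5, 100), 0.02)
  expect_equal(significance_threshold(1, 1), 1)
  expect_error(significance_threshold(0, 100), "pi0")
  expect_error(significance_threshold(1.5, 100), "pi0")
  # threshold strictly decreases as pi0 or N increases
  expect_true(significance_threshold(0.9, 100) > significance_threshold(1, 100))
  expect_true(significance_threshold(1, 100) > significance_threshold(1, 200))
})

test_that("fold change is 2^mean_log2_diff with a 2-fold filter boundary", {
  ds <- dataset_from_diffs(matrix(c(1, 1, -1.585, -1.585, 0.5, 0.5),
                                  3, 2, byrow = TRUE))
  fc <- fold_change(ds)
  expect_equal(unname(fc), c(2, 2^-1.585, sqrt(2)))
  passes <- abs(rowMeans(matrix(c(1, 1, -1.585, -1.585, 0.5, 0.5),
                                3, 2, byrow = TRUE))) >= 1
  expect_equal(unname(passes), c(TRUE, TRUE, FALSE))
})

test_that("run_diffexp recovers planted genes and controls the null", {
  set.seed(11)
  n_genes <- 2000
  n_deg <- 50
  diffs <- matrix(rnorm(n_genes * 10, 0, 0.7), n_genes, 10)
  diffs[seq_len(n_deg), ] <- diffs[seq_len(n_deg), ] + 2
  rownames(diffs) <- sprintf("g%04d", seq_len(n_genes))
  de <- run_diffexp(dataset_from_diffs(diffs))
  planted <- sprintf("g%04d", seq_len(n_deg))
  expect_gte(sum(planted %in% de$significant_ids), 45)

  # complete null: expected false positives ~ 1, allow a small margin
  null_diffs <- matrix(rnorm(n_genes * 10, 0, 0.7), n_genes, 10,
                       dimnames = list(rownames(diffs), NULL))
  de0 <- run_diffexp(dataset_from_diffs(null_diffs))
  expect_lte(de0$M, 5)

  # significant_ids is the prefix of the p-ascending ordering
  ord <- order(de$results$p_value, -abs(de$results$t_stat),
               de$results$gene_id)
  expect_equal(de$significant_ids, de$results$gene_id[ord][seq_len(de$M)])
  expect_true(all(de$results$p_value[match(de$significant_ids,
                                           de$results$gene_id)] < de$threshold))
})

test_that("null p-values are approximately uniform", {
  set.seed(21)
  diffs <- matrix(rnorm(10000 * 8, 0, 1), 10000, 8)
  rownames(diffs) <- sprintf("g%05d", 1:10000)
  res <- paired_t_test(dataset_from_diffs(diffs))
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("diffexp results round-trip through the TSV writer", {
  set.seed(3)
  diffs <- matrix(rnorm(50 * 4), 50, 4)
  de <- run_diffexp(dataset_from_diffs(diffs))
  path <- tempfile(fileext = ".tsv")
  write_diffexp(de, path)
  back <- read.delim(path)
  expect_equal(back$gene_id, de$results$gene_id)
  expect_equal(back$p_value, de$results$p_value, tolerance = 1e-12)
  expect_equal(back$significant, as.integer(de$results$significant))
})
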