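test_that("pearson_correlation matches hand-evaluated cases and guards input", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "mdsn_constant_vector")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("fisher_z is the half-log odds transform, odd, and finite at |r| = 1", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(is.finite(fisher_z(c(-1, 1)))))
})

test_that("the correlation-difference z-test matches its closed form", {
  x <- rnorm(20); y <- rnorm(20)
  null_case <- correlation_difference_test(x, y, x, y)
  expect_equal(null_case$z_AB, 0)
  expect_equal(null_case$p_value, 1)

  # strong opposite correlations: z = 2 * atanh(0.9) / sqrt(2/47) ~ 14.3
  set.seed(1)
  a <- rbvn(50, 0.9); b <- rbvn(50, -0.9)
  res <- correlation_difference_test(a[, 1], a[, 2], b[, 1], b[, 2])
  z_expected <- (atanh(res$r_A) - atanh(res$r_B)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(res$z_AB, z_expected)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$dys, res$r_A - res$r_B)

  expect_error(correlation_difference_test(1:3, 1:3, x, y), ">= 4 samples")
})

test_that("swapping the groups negates z and preserves p", {
  set.seed(2)
  for (i in 1:20) {
    a <- rbvn(sample(10:40, 1), runif(1, -0.8, 0.8))
    b <- rbvn(sample(10:40, 1), runif(1, -0.8, 0.8))
    ab <- correlation_difference_test(a[, 1], a[, 2], b[, 1], b[, 2])
    ba <- correlation_difference_test(b[, 1], b[, 2], a[, 1], a[, 2])
    expect_equal(ab$z_AB, -ba$z_AB)
    expect_equal(ab$p_value, ba$p_value)
  }
})

test_that("the Fisher test is calibrated under the null", {
  # common true correlation in both groups; p-values should be uniform
  set.seed(11)
  p <- replicate(1000, {
    a <- rbvn(50, 0.3); b <- rbvn(50, 0.3)
    correlation_difference_test(a[, 1], a[, 2], b[, 1], b[, 2])$p_value
  })
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("the permutation test is deterministic and agrees with Fisher", {
  set.seed(3)
  a <- rbvn(60, -0.5); b <- rbvn(60, 0.2)
  p1 <- permutation_difference_test(a[, 1], a[, 2], b[, 1], b[, 2],
                                    n_perm = 2000, seed = 7)
  p2 <- permutation_difference_test(a[, 1], a[, 2], b[, 1], b[, 2],
                                    n_perm = 2000, seed = 7)
  expect_identical(p1, p2)
  expect_lte(p1, 0.001)    # strongly dysregulated planted pair

  # identical groups: permutation p concentrates near 1
  x <- rnorm(30); y <- x + rnorm(30)
  expect_gt(permutation_difference_test(x, y, x, y, n_perm = 500, seed = 1), 0.5)
})

test_that("pairwise analyses enumerate subtype pairs and apply the filters", {
  sim <- simulate_cohort(
    n_mirna = 12, n_mrna = 20, n_modules = 2, mirnas_per_module = 3,
    targets_per_module = 5, subtype_sizes = c(a = 30, b = 30, c = 30, d = 30),
    corr_scheme = matrix(c(-0.8, 0, 0, 0, -0.8, 0, 0, 0), 2, 4), seed = 21
  )
  assoc <- run_pairwise_analyses(sim$mirna, sim$mrna, sim$design)
  expect_length(assoc$analysis_ids, 6)       # C(4, 2) analysis blocks
  expect_equal(ncol(assoc$A), 6 * 20)
  expect_identical(assoc$analysis_ids, sort(assoc$analysis_ids))
  expect_true(all(assoc$A %in% c(0L, 1L)))

  # bit-exact reproducibility of the Fisher path
  assoc2 <- run_pairwise_analyses(sim$mirna, sim$mrna, sim$design)
  expect_identical(assoc$A, assoc2$A)

  # every positive entry passes threshold + prerequisite on the records
  tab <- dysregulation_table(sim$mirna, sim$mrna, sim$design, "a", "b")
  mrna_ids <- rownames(sim$mrna$values)
  key <- assoc$columns$analysis_id == "a_vs_b"
  hits <- which(assoc$A[, key, drop = FALSE] == 1L, arr.ind = TRUE)
  for (i in seq_len(min(nrow(hits), 20))) {
    rec <- tab[tab$mirna_id == assoc$mirna_ids[hits[i, 1]] &
                 tab$mrna_id == mrna_ids[hits[i, 2]], ]
    expect_lt(rec$p_value, 0.001)
    expect_true(rec$eligible)
  }
})

test_that("the inverse-correlation prerequisite suppresses positive-positive pairs", {
  # force a pair with strong positive correlation in both groups but a
  # significant difference: eligible must be FALSE and A must stay 0
  set.seed(9)
  n <- 80
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- c(0.98 * f1 + sqrt(1 - 0.98^2) * rnorm(n),
         0.5 * f2 + sqrt(0.75) * rnorm(n))
  y <- c(0.98 * f1 + sqrt(1 - 0.98^2) * rnorm(n),
         0.5 * f2 + sqrt(0.75) * rnorm(n))
  res <- correlation_difference_test(x[1:n], y[1:n], x[n + 1:n], y[n + 1:n])
  expect_gt(res$r_A, 0); expect_gt(res$r_B, 0)
  expect_lt(res$p_value, 0.001)
  expect_false(res$eligible)

  mirna <- expr_matrix(matrix(x, 1, dimnames = list("m1", paste0("s", 1:(2 * n)))),
                       processed = TRUE)
  mrna <- expr_matrix(matrix(y, 1, dimnames = list("g1", paste0("s", 1:(2 * n)))),
                      processed = TRUE)
  design <- group_design(paste0("s", 1:(2 * n)), rep(c("A", "B"), each = n))
  with_neg <- run_pairwise_analyses(mirna, mrna, design, require_negative = TRUE)
  without <- run_pairwise_analyses(mirna, mrna, design, require_negative = FALSE)
  expect_equal(sum(with_neg$A), 0)
  expect_equal(sum(without$A), 1)
})

test_that("small subtypes are excluded with a warning and constant pairs skipped", {
  sim <- simulate_cohort(n_mirna = 6, n_mrna = 8, n_modules = 1,
                         mirnas_per_module = 2, targets_per_module = 2,
                         subtype_sizes = c(a = 20, b = 20), seed = 30)
  design <- sim$design
  design$subtype[design$subtype == "b"][1:18] <- "tiny"
  expect_warning(
    assoc <- run_pairwise_analyses(sim$mirna, sim$mrna, design,
                                   subtypes = c("a", "b", "tiny")),
    "excluding subtype"
  )
  expect_identical(assoc$excluded_subtypes, "b")  # b dropped to 2 samples
  expect_length(assoc$analysis_ids, 1)

  # a feature constant within one group is skipped and counted
  mir2 <- sim$mirna
  mir2$values[1, design$subtype %in% "a"] <- 5
  assoc2 <- suppressWarnings(
    run_pairwise_analyses(mir2, sim$mrna, design, subtypes = c("a", "tiny"))
  )
  expect_gt(sum(assoc2$counts$n_skipped), 0)
  expect_equal(sum(assoc2$A[1, ]), 0)
})
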