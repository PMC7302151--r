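test_that("log2 transform maps values and preserves the missing pattern", {
  design <- make_design(n_tp = 1, n_rep = 2)
  m <- make_matrix(matrix(c(8, 1, NA, 2, 4, 16, 32, 64), 2, 4), design)
  lg <- log2_transform(m)
  expect_equal(unname(lg$values[1, 1]), 3)   # log2(8)
  expect_equal(unname(lg$values[2, 1]), 0)   # log2(1)
  expect_true(is.na(lg$values[1, 2]))
  expect_identical(lg$scale, "log2")

  bad <- make_matrix(matrix(c(0, 2, 3, 4, 5, 6, 7, 8), 2, 4), design)
  expect_error(log2_transform(bad), "non-positive")
})

test_that("half-of-samples filter counts presence per condition", {
  # 4 samples per condition (2 timepoints x 2 reps); min_fraction 0.5 -> need 2
  design <- make_design(n_tp = 2, n_rep = 2)
  vals <- matrix(1, 3, 8)
  vals[1, c(1, 2)] <- NA          # e1: 2/4 in Nminus, 4/4 in Nplus -> kept
  vals[2, c(1, 2, 3)] <- NA       # e2: 1/4 in Nminus -> removed
  m <- log2_transform(make_matrix(matrix(2^vals, 3, 8), design))
  m$values[is.na(vals)] <- NA
  res <- filter_min_quantified(m, 0.5, mode = "sample")
  expect_setequal(res$report$kept_ids, c("e01", "e03"))
  expect_equal(res$report$removed_ids, "e02")
  expect_setequal(union(res$report$kept_ids, res$report$removed_ids),
                  rownames(m$values))

  # no missing values -> everything kept
  full <- log2_transform(make_matrix(matrix(2, 3, 8), design))
  expect_equal(length(filter_min_quantified(full)$report$removed_ids), 0)
})

test_that("timepoint-level filter counts a timepoint quantified at >= 1 replicate", {
  design <- make_design(n_tp = 2, n_rep = 2)
  vals <- matrix(1, 2, 8)
  # e1: Nminus tp1 has 1 of 2 reps -> both timepoints quantified -> kept
  vals[1, 1] <- NA
  # e2: Nminus tp1 fully missing -> 1/2 timepoints -> still >= ceil(0.5*2)=1 -> kept
  vals[2, c(1, 2)] <- NA
  m <- make_matrix(vals, design, scale = "raw")
  m <- log2_transform(m)
  res <- filter_min_quantified(m, 0.5, mode = "timepoint")
  expect_setequal(res$report$kept_ids, c("e01", "e02"))
  # raising min_fraction to 1 now drops e2 (needs both timepoints)
  res2 <- filter_min_quantified(m, 1, mode = "timepoint")
  expect_equal(res2$report$removed_ids, "e02")
})

test_that("filter is monotone in min_fraction", {
  design <- make_design(n_tp = 3, n_rep = 3)
  withr::with_seed(21, {
    vals <- matrix(stats::runif(30 * 18, 1, 100), 30, 18)
    vals[stats::runif(length(vals)) < 0.4] <- NA
  })
  m <- make_matrix(vals, design)
  m$scale <- "log2"
  kept_prev <- NULL
  for (f in c(1, 0.75, 0.5, 0.25)) {
    kept <- filter_min_quantified(m, f)$report$kept_ids
    if (!is.null(kept_prev)) expect_true(all(kept_prev %in% kept))
    kept_prev <- kept
  }
})

test_that("imputation fills only missing cells, deterministically from the seed", {
  design <- make_design(n_tp = 1, n_rep = 3)
  withr::with_seed(3, vals <- matrix(stats::rnorm(60, 25, 2), 10, 6))
  vals[c(3, 17, 42)] <- NA
  m <- make_matrix(vals, design, scale = "raw")
  m$scale <- "log2"
  a <- impute_downshifted_normal(m, seed = 99)
  b <- impute_downshifted_normal(m, seed = 99)
  expect_identical(a$values, b$values)          # determinism contract
  expect_false(anyNA(a$values))
  present <- !is.na(vals)
  expect_identical(a$values[present], vals[present])  # present values untouched

  # a fully observed column is returned unchanged
  expect_identical(unname(a$values[, 6]), vals[, 6])

  # column with < 2 present values errors
  short <- vals; short[2:10, 1] <- NA
  ms <- make_matrix(short, design, scale = "raw"); ms$scale <- "log2"
  expect_error(impute_downshifted_normal(ms), "fewer than 2")
})

test_that("imputed draws recover the down-shifted moments", {
  # column whose present values have sample mean 20 and sample sd 2 exactly,
  # so the target imputation distribution is N(20 - 1.8*2, (0.3*2)^2)
  design <- data.frame(condition = "Nminus", timepoint = 3, replicate = 1)
  vals <- matrix(c(18, 20, 22, rep(NA_real_, 1e5)), ncol = 1)
  m <- make_matrix(vals, design, scale = "raw")
  m$scale <- "log2"
  imp <- impute_downshifted_normal(m, width = 0.3, down_shift = 1.8, seed = 4)
  draws <- imp$values[-(1:3), 1]
  expect_equal(mean(draws), 16.4, tolerance = 0.02 / 16.4)
  expect_equal(stats::sd(draws), 0.6, tolerance = 0.01 / 0.6)
})

test_that("fold changes are replicate means of log2 differences", {
  design <- make_design(n_tp = 1, n_rep = 3)
  vals <- matrix(c(10, 10, 10, 8, 9, 10), 1, 6)  # Nminus {10,10,10}, Nplus {8,9,10}
  m <- make_matrix(vals, design, scale = "raw"); m$scale <- "log2"
  fc <- fold_change(m, "protein")
  expect_equal(unname(fc$values[1, 1]), 1)       # 10 - mean(8,9,10)

  # identical conditions -> all-zero fold changes
  same <- make_matrix(matrix(rep(c(5, 6, 7), 2), 2, 6, byrow = TRUE), design,
                      scale = "raw")
  same$scale <- "log2"
  expect_true(all(fold_change(same, "protein")$values == 0))
})

test_that("fold change is antisymmetric under swapping condition labels", {
  design <- make_design(n_tp = 3, n_rep = 3)
  withr::with_seed(8, vals <- matrix(stats::rnorm(15 * 18, 20, 3), 15, 18))
  m <- make_matrix(vals, design, scale = "raw"); m$scale <- "log2"
  swapped <- m
  swapped$samples$condition <- ifelse(m$samples$condition == "Nminus", "Nplus", "Nminus")
  expect_equal(fold_change(m, "protein")$values,
               -fold_change(swapped, "protein")$values)
})

test_that("timepoints present in only one condition are excluded with a warning", {
  design <- make_design(n_tp = 2, n_rep = 2)
  design <- design[!(design$condition == "Nplus" & design$timepoint == 6), ]
  vals <- matrix(1, 2, nrow(design))
  m <- make_matrix(vals, design, scale = "raw"); m$scale <- "log2"
  expect_warning(fc <- fold_change(m, "protein"), "one condition only")
  expect_equal(fc$timepoints, 3)
})

test_that("differential test reproduces the closed-form Welch example and conventions", {
  design <- make_design(n_tp = 1, n_rep = 3)
  vals <- rbind(c(1, 2, 3, 2, 3, 4),     # Welch t = -1.2247, p ~ 0.288
                c(5, 5, 5, 5, 5, 5))     # zero variance, equal means
  m <- make_matrix(vals, design, scale = "raw"); m$scale <- "log2"
  res <- suppressMessages(differential_test(m))
  expect_equal(res$t_statistic[1], -1.224745, tolerance = 1e-6)
  expect_equal(res$p_value[1], 0.2878641, tolerance = 1e-6)
  expect_equal(res$t_statistic[2], 0)
  expect_equal(res$p_value[2], 1)

  # zero variance, unequal means -> p = 0 by convention
  m2 <- make_matrix(rbind(c(7, 7, 7, 5, 5, 5)), design, scale = "raw")
  m2$scale <- "log2"
  expect_equal(suppressMessages(differential_test(m2))$p_value, 0)
})

test_that("Welch statistics agree with stats::t.test across random inputs", {
  design <- make_design(n_tp = 1, n_rep = 4)
  withr::with_seed(13, vals <- matrix(stats::rnorm(25 * 8, 20, 2), 25, 8))
  m <- make_matrix(vals, design, scale = "raw"); m$scale <- "log2"
  res <- differential_test(m)
  for (i in c(1, 7, 25)) {
    ref <- stats::t.test(vals[i, 1:4], vals[i, 5:8])
    expect_equal(res$t_statistic[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("q-values agree with a brute-force BH oracle and flag significance", {
  design <- make_design(n_tp = 1, n_rep = 3)
  withr::with_seed(17, {
    for (n in c(5, 20, 50)) {
      vals <- matrix(stats::rnorm(n * 6, 20, 1), n, 6)
      vals[seq_len(ceiling(n / 3)), 1:3] <- vals[seq_len(ceiling(n / 3)), 1:3] + 2
      m <- make_matrix(vals, design, scale = "raw"); m$scale <- "log2"
      res <- differential_test(m, level = 0.05)
      expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
      expect_identical(res$significant, res$q_value <= 0.05)
    }
  })
})

test_that("identical p-values below the level are all significant after BH", {
  p <- rep(0.01, 12)
  expect_true(all(bh_oracle(p) <= 0.05))
  expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
})
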