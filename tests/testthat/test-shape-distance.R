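test_that("z-normalization centres, scales and is idempotent", {
  z <- znormalize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(as.numeric(z)^2)), 1)  # population-sd convention
  expect_equal(as.numeric(znormalize(as.numeric(z))), as.numeric(z))

  flat <- znormalize(c(5, 5, 5, 5))
  expect_equal(as.numeric(flat), rep(0, 4))
  expect_true(attr(flat, "degenerate"))
  expect_error(znormalize(3), "length")
})

test_that("NCCc peaks at 1 on self-correlation and at the lag of a delayed series", {
  withr::with_seed(2, x <- stats::rnorm(8))
  cc <- ncc_c(x, x)
  shifts <- attr(cc, "shifts")
  expect_equal(cc[shifts == 0], 1, tolerance = 1e-12)
  expect_equal(length(cc), 2 * 8 - 1)

  # y lags x by one position -> positive best shift under the convention
  x4 <- c(1, 2, 1, 0); y4 <- c(0, 1, 2, 1)
  cc4 <- ncc_c(x4, y4)
  expect_equal(attr(cc4, "shifts")[which.max(cc4)], 1)
  expect_error(ncc_c(1:4, 1:5), "equal length")
})

test_that("FFT path equals the direct sliding-dot-product oracle", {
  withr::with_seed(31, {
    for (i in 1:300) {
      m <- sample(2:64, 1)
      x <- stats::rnorm(m); y <- stats::rnorm(m)
      expect_lt(max(abs(ncc_c(x, y) - ncc_c_direct(x, y))), 1e-9)
    }
  })
})

test_that("NCC coefficients and SBD respect their bounds on random pairs", {
  withr::with_seed(32, {
    worst_cc <- 0; lo <- Inf; hi <- -Inf
    for (i in 1:2000) {
      m <- sample(3:12, 1)
      x <- stats::rnorm(m); y <- stats::rnorm(m)
      cc <- ncc_c(x, y)
      worst_cc <- max(worst_cc, max(abs(cc)))
      d <- sbd(x, y)$distance
      lo <- min(lo, d); hi <- max(hi, d)
    }
    expect_lte(worst_cc, 1 + 1e-12)
    expect_gte(lo, 0)
    expect_lte(hi, 2)
  })
})

test_that("SBD identities: self-distance, affine invariance, symmetry", {
  withr::with_seed(33, {
    for (i in 1:50) {
      x <- stats::rnorm(6)
      self <- sbd(x, x)
      expect_equal(self$distance, 0, tolerance = 1e-12)
      expect_identical(self$best_shift, 0L)
      expect_equal(self$ncc_max, 1, tolerance = 1e-12)
      a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1, 0, 10)
      expect_equal(sbd(x, a * x + b)$distance, 0, tolerance = 1e-12)
      y <- stats::rnorm(6)
      expect_equal(sbd(x, y)$distance, sbd(y, x)$distance, tolerance = 1e-12)
      expect_equal(sbd(x, y)$best_shift, -sbd(y, x)$best_shift)
    }
  })
})

test_that("SBD matches the oracle on the worked shift example", {
  x <- c(1, 2, 1, 0); y <- c(0, 1, 2, 1)
  s <- sbd(x, y)
  oracle <- ncc_c_direct(x, y)
  expect_equal(s$distance, 1 - max(oracle), tolerance = 1e-12)
  expect_equal(abs(s$best_shift), 1)
})

test_that("degenerate series follow the flat-series conventions", {
  flat <- rep(2, 5)
  wig <- c(1, 3, 2, 5, 4)
  expect_equal(sbd(flat, flat)$distance, 0)
  expect_equal(sbd(flat, wig)$distance, 1)
  expect_equal(sbd(wig, flat)$distance, 1)
})

test_that("noiseless delayed copies of interior shapes recover the shift exactly", {
  withr::with_seed(41, {
    for (i in 1:500) {
      m <- sample(c(6, 9, 12), 1)
      d_max <- floor(m / 3)
      d <- sample(seq_len(d_max), 1)
      x <- bump_series(m, d_max)
      y <- c(rep(x[1], d), x)[seq_len(m)]   # edge-padded delay by d
      expect_identical(sbd(x, y)$best_shift, as.integer(d))
    }
  })
})

test_that("profile pairing restricts to shared timepoints and entities", {
  t_vals <- matrix(stats::rnorm(12), 4, 3,
                   dimnames = list(paste0("g", 1:4), NULL))
  p_vals <- matrix(stats::rnorm(18), 3, 6,
                   dimnames = list(paste0("g", 3:5), NULL))
  fc_t <- fold_change_table(t_vals, c(3, 6, 12), "transcript")
  fc_p <- fold_change_table(p_vals, c(3, 6, 12, 24, 48, 240), "protein")
  pr <- pair_profiles(fc_t, fc_p)
  expect_equal(pr$timepoints, c(3, 6, 12))
  expect_setequal(rownames(pr$transcript), c("g3", "g4"))
  expect_setequal(pr$unpaired_transcript, c("g1", "g2"))
  expect_setequal(pr$unpaired_protein, "g5")

  # identical tables pair everything at distance zero
  same <- pair_profiles(fold_change_table(t_vals, c(3, 6, 12), "transcript"),
                        fold_change_table(t_vals, c(3, 6, 12), "protein"))
  recs <- sbd_records(same)
  expect_true(all(recs$sbd < 1e-12))

  fc_short <- fold_change_table(t_vals[, 1:2], c(3, 6), "transcript")
  expect_error(pair_profiles(fc_short, fc_p), "shared timepoints")
})

test_that("quartile classification reproduces the hand-computed thresholds", {
  recs <- data.frame(entity_id = letters[1:8], sbd = 1:8,
                     best_shift = 0L, ncc_max = 0)
  out <- classify_similarity(recs)
  expect_equal(out$thresholds$q1, 2.75)
  expect_equal(out$thresholds$q3, 6.25)
  cls <- out$records$similarity_class
  expect_equal(cls[1:2], rep("highly_similar", 2))
  expect_equal(cls[7:8], rep("highly_unsimilar", 2))
  expect_equal(cls[3:6], rep("indistinct", 4))

  # tied SBDs: strict inequalities leave everything indistinct
  tied <- data.frame(entity_id = letters[1:6], sbd = rep(0.4, 6))
  expect_true(all(classify_similarity(tied)$records$similarity_class == "indistinct"))
  expect_error(classify_similarity(tied[1:3, ]), "at least 4")
})

test_that("with n divisible by 4 and distinct SBDs exactly n/4 land in each tail", {
  withr::with_seed(51, {
    for (n in c(8, 20, 40)) {
      recs <- data.frame(entity_id = seq_len(n), sbd = sample(stats::runif(n)))
      cls <- classify_similarity(recs)$records$similarity_class
      expect_equal(sum(cls == "highly_similar"), n / 4)
      expect_equal(sum(cls == "highly_unsimilar"), n / 4)
    }
  })
})

test_that("shape extraction returns a centroid at SBD zero from its members", {
  x <- as.numeric(znormalize(c(1, 3, 2, 5, 4, 6)))
  cent <- kshape_extract_shape(rbind(x), x)
  expect_lt(sbd(cent, x)$distance, 1e-10)
  cent2 <- kshape_extract_shape(rbind(x, x), x)
  expect_lt(sbd(cent2, x)$distance, 1e-10)

  # empty member set: centroid unchanged, flagged
  out <- kshape_extract_shape(matrix(numeric(0), 0, 6), x)
  expect_true(attr(out, "empty"))
  expect_equal(as.numeric(out), x)
})

test_that("shape extraction recovers a planted shape from noisy copies", {
  withr::with_seed(61, {
    shape <- sin(2 * pi * (1:10) / 10)
    members <- t(replicate(20, shape + stats::rnorm(10, 0, 0.05)))
    cent <- kshape_extract_shape(members, as.numeric(znormalize(shape)))
    expect_lt(sbd(cent, shape)$distance, 0.01)
  })
})

test_that("k-shape recovers a planted two-class partition exactly", {
  skip_if_not_installed("mclust")
  withr::with_seed(71, {
    m <- 10
    sine <- sin(2 * pi * (1:m) / m)
    ramp <- seq(-1, 1, length.out = m)
    profiles <- rbind(t(replicate(20, sine + stats::rnorm(m, 0, 0.1))),
                      t(replicate(20, ramp + stats::rnorm(m, 0, 0.1))))
    rownames(profiles) <- sprintf("s%02d", 1:40)
  })
  km <- kshape_cluster(profiles, k = 2, seed = 3)
  truth <- rep(1:2, each = 20)
  expect_equal(mclust::adjustedRandIndex(km$assignments, truth), 1.0)
  expect_true(km$converged)
  # refinement objective never increases
  expect_true(all(diff(km$objective) <= 1e-8))
})

test_that("k-shape handles the trivial and degenerate cluster counts", {
  withr::with_seed(81, profiles <- matrix(stats::rnorm(50), 10, 5))
  rownames(profiles) <- paste0("p", 1:10)
  one <- kshape_cluster(profiles, k = 1, seed = 1)
  expect_true(all(one$assignments == 1))
  expect_true(one$converged)
  expect_error(kshape_cluster(profiles, k = 0, seed = 1), "domain error")
  expect_error(kshape_cluster(profiles, k = 11, seed = 1), "domain error")
})
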