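test_that("macrophage orientation probabilities are normalized prevalences", {
  res <- macrophage_orientation(1, 1, 2)
  expect_equal(unlist(res), c(p_m0 = 0.25, p_m1 = 0.25, p_m2 = 0.5))
  res <- macrophage_orientation(0, 5, 0)
  expect_equal(unlist(res), c(p_m0 = 0, p_m1 = 1, p_m2 = 0))
  expect_error(macrophage_orientation(-1, 1, 1), "non-negative")
})

test_that("all-zero macrophage samples are flagged degenerate with a warning", {
  expect_warning(res <- macrophage_orientation(c(1, 0), c(1, 0), c(2, 0)),
                 "zero total")
  expect_true(is.na(res$p_m0[2]))
  expect_equal(attr(res, "degenerate"), c(FALSE, TRUE))
})

test_that("orientation probabilities sum to one for positive inputs", {
  withr::with_seed(42, {
    m <- matrix(runif(3 * 500, min = 1e-6, max = 10), ncol = 3)
  })
  res <- macrophage_orientation(m[, 1], m[, 2], m[, 3])
  expect_true(all(abs(rowSums(res) - 1) < 1e-12))
})

test_that("feature tables validate their inputs", {
  m <- cbind(a = c(1, 2), b = c(0, 1))
  ft <- feature_table(m, column_kind = c(b = "attribute01"))
  expect_equal(unname(ft$column_kind), c("continuous", "attribute01"))
  m_bad <- cbind(a = c(1, NA), b = c(0, 1))
  expect_error(feature_table(m_bad), "missing value.*feature 'a'")
  expect_error(feature_table(cbind(a = c(1, 2), b = c(0, 2)),
                             column_kind = c(b = "attribute01")),
               "outside \\{0, 1\\}")
  expect_error(feature_table(m, sample_ids = c("s", "s")), "unique")
})

test_that("preprocessing log-transforms then scales each column to [0, 1]", {
  ft <- feature_table(cbind(f = c(0, 9, 99), g = c(5, 1, 3)))
  out <- preprocess_features(ft)
  expect_equal(out$values[, "f"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(min(out$values[, "g"]), 0)
  expect_equal(max(out$values[, "g"]), 1)
  # monotone input order is preserved
  expect_equal(order(out$values[, "g"]), order(ft$values[, "g"]))
  # attribute columns pass through unchanged
  ft2 <- feature_table(cbind(f = c(0, 9, 99), c = c(0, 1, 1)),
                       column_kind = c(c = "attribute01"))
  out2 <- preprocess_features(ft2)
  expect_equal(out2$values[, "c"], c(0, 1, 1), ignore_attr = TRUE)
})

test_that("preprocessing is applied exactly once and flags constants", {
  ft <- feature_table(cbind(f = c(1, 2, 3)))
  out <- preprocess_features(ft)
  expect_true(out$normalized)
  expect_error(preprocess_features(out), "exactly once")
  expect_warning(cst <- preprocess_features(feature_table(cbind(k = c(2, 2)))),
                 "constant")
  expect_equal(cst$values[, "k"], c(0, 0), ignore_attr = TRUE)
  expect_error(preprocess_features(feature_table(cbind(f = c(-1, 2)))),
               "negative")
})

test_that("discretization uses equal-width intervals with inclusive top bin", {
  ft <- feature_table(cbind(f = c(0, 0.4, 0.6, 1)))
  ft$normalized <- TRUE
  out <- discretize_features(ft, 2)
  expect_equal(out$values[, "f"], c(0, 0, 1, 1), ignore_attr = TRUE)
  ftc <- feature_table(cbind(f = rep(0, 4)))
  ftc$normalized <- TRUE
  expect_equal(unique(discretize_features(ftc, 7)$values[, "f"]), 0)
  # a uniform grid of 15 values occupies all 15 codes
  ftg <- feature_table(cbind(f = seq(0, 1, length.out = 15)))
  ftg$normalized <- TRUE
  expect_equal(sort(unique(discretize_features(ftg, 15)$values[, "f"])), 0:14)
  expect_error(discretize_features(ft, 1), ">= 2")
})

test_that("discretization midpoints reconstruct within half a bin width", {
  withr::with_seed(7, x <- runif(200))
  ft <- feature_table(cbind(f = x))
  ft$normalized <- TRUE
  for (k in c(2, 6, 15)) {
    codes <- discretize_features(ft, k)$values[, "f"]
    mid <- (codes + 0.5) / k
    expect_true(all(abs(mid - x) <= 1 / (2 * k) + 1e-12))
  }
})

test_that("zero profiles count exact zeros and suggest leaves inclusively", {
  ft <- feature_table(cbind(a = c(0, 0, 0, 1, 2), b = c(1, 2, 3, 4, 5),
                            c = c(0, 0, 1, 1, 3)))
  zp <- zero_profile(ft, zero_leaf_fraction = 0.4)
  expect_equal(zp$n_zero, c(3L, 0L, 2L))
  expect_equal(zp$zero_fraction, c(0.6, 0, 0.4))
  expect_equal(zp$suggest_leaf, c(TRUE, FALSE, TRUE))  # boundary inclusive
})
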