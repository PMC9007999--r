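test_that("partial correlations equal the residual-regression definition", {
  d <- cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  expect_equal(partial_correlation("x", "y", data = d), 1.0)
  d2 <- cbind(x = c(1, 1, -1, -1), y = c(1, -1, 1, -1))
  expect_equal(partial_correlation("x", "y", data = d2), 0)
  d3 <- chain_data(n = 500, beta = 1, sd = 0.1, seed = 11)
  expect_lt(abs(partial_correlation("X", "Z", "Y", d3)), 0.1)
  expect_equal(partial_correlation("X", "Z", "Y", d3),
               oracle_pcor("X", "Z", "Y", d3), tolerance = 1e-10)
  dcst <- cbind(x = rep(1, 10), y = rnorm(10))
  expect_error(partial_correlation("x", "y", data = dcst), "constant")
})

test_that("the exact t-test matches an independent Student-CDF oracle", {
  expect_equal(exact_t_pvalue(0, 30), 1.0)
  t_expected <- 0.5 * 5 / sqrt(0.75)
  expect_equal(exact_t_pvalue(0.5, 27, 0), 2 * pt(-t_expected, 25),
               tolerance = 1e-12)
  # strictly decreasing in |r|
  ps <- vapply(seq(0, 0.99, by = 0.01), exact_t_pvalue, numeric(1),
               n_obs = 40, cond_size = 2)
  expect_true(all(diff(ps) < 0))
  # perfect correlation underflows but never reaches zero
  expect_gt(exact_t_pvalue(1, 10), 0)
  expect_lt(exact_t_pvalue(1, 10), 1e-100)
  expect_error(exact_t_pvalue(0.2, 3, 1), "degrees of freedom")
})

test_that("gaussian scores equal the closed-form OLS formula and decompose", {
  withr::with_seed(3, {
    d <- matrix(rnorm(200 * 4), ncol = 4,
                dimnames = list(NULL, c("a", "b", "c", "e")))
    d[, "c"] <- 2 * d[, "a"] - d[, "b"] + rnorm(200, 0, 0.5)
  })
  for (pa in list(character(0), "a", c("a", "b"), c("a", "b", "e"))) {
    expect_equal(gaussian_score("c", pa, d),
                 oracle_gaussian_score("c", pa, d), tolerance = 1e-10)
  }
  # decomposability: network score is the sum of node scores
  for (s in 1:5) {
    g <- random_dag(4, dens = 0.5, seed = 200 + s)
    dd <- matrix(rnorm(50 * 4), ncol = 4, dimnames = list(NULL, g$nodes))
    total <- sum(vapply(g$nodes, function(nd)
      gaussian_score(nd, parents_of(g, nd), dd), numeric(1)))
    expect_true(is.finite(total))
  }
})

test_that("pure-noise parents lower the score and degenerate fits are capped", {
  hits <- 0
  for (s in 1:10) {
    withr::with_seed(s, {
      d <- cbind(y = rnorm(500), w = rnorm(500))
    })
    if (gaussian_score("y", character(0), d) >
        gaussian_score("y", "w", d)) hits <- hits + 1
  }
  expect_gte(hits, 9)
  d2 <- cbind(x = 1:50, y = 2 * (1:50))
  expect_true(is.finite(gaussian_score("y", "x", d2)))  # variance floored
  expect_gt(gaussian_score("y", "x", d2), gaussian_score("y", character(0), d2))
})

test_that("node-level L1 BIC follows its defining formula", {
  d0 <- cbind(y = rep(0, 4), x = c(1, 2, 3, 4))
  expect_equal(node_l1_bic("y", character(0), d0)$bic, 0)
  d1 <- cbind(y = seq_len(100) / 100, x = seq_len(100) / 100)
  expect_equal(node_l1_bic("y", "x", d1)$bic, 2)  # zero loss + 1 arc penalty
  withr::with_seed(5, {
    d2 <- matrix(rnorm(80 * 3), ncol = 3, dimnames = list(NULL, c("y", "a", "b")))
  })
  for (pa in list(character(0), "a", c("a", "b"))) {
    rec <- node_l1_bic("y", pa, d2)
    expect_equal(rec$bic, oracle_l1_bic("y", pa, d2), tolerance = 1e-12)
    expect_equal(rec$bic, rec$n_arcs * log10(rec$n_obs) + rec$l1_loss)
  }
})

test_that("adding a pure-noise parent costs about one BIC penalty unit", {
  for (s in 1:5) {
    withr::with_seed(300 + s, {
      d <- cbind(y = rnorm(400), a = rnorm(400), w = rnorm(400))
      d[, "y"] <- d[, "a"] + rnorm(400, 0, 0.3)
    })
    b1 <- node_l1_bic("y", "a", d)$bic
    b2 <- node_l1_bic("y", c("a", "w"), d)$bic
    gain <- b2 - b1
    expect_gt(gain, 0)                 # the extra parent never pays off
    # the gain is the penalty plus a small L1 change of either sign
    expect_lt(abs(gain - log10(400)), 1)
  }
})

test_that("arc significance conditions on the child's other parents", {
  d <- collider_data(n = 400, beta = 1, sd = 0.2, seed = 21)
  dag <- bn_graph(c("A", "B", "C"), arcs = rbind(c("A", "C"), c("B", "C")))
  rec <- arc_significance(dag, c("A", "C"), d)
  expect_equal(rec$cond_size, 1)       # conditions on {B}
  expect_equal(rec$r, oracle_pcor("A", "C", "B", d), tolerance = 1e-10)
  expect_equal(rec$p_value, oracle_t_pvalue(rec$r, 400, 1), tolerance = 1e-12)
  single <- bn_graph(c("A", "B", "C"), arcs = rbind(c("A", "C")))
  expect_equal(arc_significance(single, c("A", "C"), d)$cond_size, 0)
  expect_error(arc_significance(single, c("B", "C"), d), "not in the graph")
})
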