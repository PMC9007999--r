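test_that("ground truths honor the role map", {
  tr <- make_ground_truth(seed = 1)
  a <- arcs(tr$dag)
  expect_false(any(a[, 2] == "Cancer"))                 # root has no parents
  expect_false(any(a[, 1] %in% c("CD4_T_cells", "Neutrophils"))) # leaves
  qr_parents <- unname(a[a[, 2] == "CCN4", 1])
  expect_equal(qr_parents, "Cancer")                    # oncogene <- root only
  expect_true(is_acyclic(tr$dag))
})

test_that("full density yields the complete admissible lower triangle", {
  tr <- make_ground_truth(nodes = c("a", "b", "c"), roles = node_roles(),
                          density = 1, zero_inflation = numeric(0), seed = 2)
  expect_equal(nrow(arcs(tr$dag)), 3)
})

test_that("ground truths and datasets are reproducible per seed", {
  t1 <- make_ground_truth(seed = 5)
  t2 <- make_ground_truth(seed = 5)
  expect_identical(t1$dag$amat, t2$dag$amat)
  expect_identical(t1$net$cpds, t2$net$cpds)
  d1 <- sample_dataset(t1, 100, seed = 9)
  d2 <- sample_dataset(t2, 100, seed = 9)
  expect_identical(d1$values, d2$values)
  expect_error(make_ground_truth(density = 0, seed = 1), "density")
})

test_that("structural zeros appear at their stated binomial rate", {
  tr <- make_ground_truth(seed = 3)
  d <- sample_dataset(tr, 1000, seed = 33)
  zp <- zero_profile(d)
  n_cd4 <- zp$n_zero[zp$feature == "CD4_T_cells"]
  expect_lt(abs(n_cd4 - 600), 3 * sqrt(1000 * 0.6 * 0.4))
  n_neu <- zp$n_zero[zp$feature == "Neutrophils"]
  expect_lt(abs(n_neu - 750), 3 * sqrt(1000 * 0.75 * 0.25))
  expect_true(all(d$values >= 0 & d$values <= 1))
})

test_that("degenerate generator settings behave as contracts say", {
  tr <- make_ground_truth(root_prob = 1, seed = 4)
  d <- sample_dataset(tr, 50, seed = 44)
  expect_true(all(d$values[, "Cancer"] == 1))
  tr0 <- make_ground_truth(sd = 0, zero_inflation = numeric(0), seed = 4)
  d0 <- sample_dataset(tr0, 50, seed = 45, rescale = FALSE)
  # zero noise: every node is an exact function of the root draw
  for (nd in tr0$dag$nodes) {
    cpd <- tr0$net$cpds[[nd]]
    if (cpd$type != "gaussian" || length(cpd$parents) == 0) next
    pred <- cpd$intercept +
      d0$values[, cpd$parents, drop = FALSE] %*% cpd$coefficients
    expect_equal(unname(d0$values[, nd]), unname(drop(pred)),
                 tolerance = 1e-8)
  }
})

test_that("recovery metrics score exact, empty, and reversed graphs", {
  tr <- make_ground_truth(seed = 6)
  r <- evaluate_recovery(tr$dag, tr$dag, "directed")
  expect_equal(r$f1, 1)
  expect_equal(r$shd, 0)
  empty <- bn_graph(tr$dag$nodes)
  r0 <- evaluate_recovery(tr$dag, empty, "directed")
  expect_equal(r0$recall, 0)
  expect_equal(r0$shd, nrow(arcs(tr$dag)))
  # a reversible arc reversed within its class: penalized only directed-wise
  chain <- bn_graph(c("A", "B"), arcs = rbind(c("A", "B")))
  rev <- bn_graph(c("A", "B"), arcs = rbind(c("B", "A")))
  expect_equal(evaluate_recovery(chain, rev, "directed")$f1, 0)
  expect_equal(evaluate_recovery(chain, rev, "cpdag")$f1, 1)
  # a compelled arc reversed is penalized in both modes
  coll <- bn_graph(c("A", "B", "C"), arcs = rbind(c("A", "C"), c("B", "C")))
  flip <- bn_graph(c("A", "B", "C"), arcs = rbind(c("C", "A"), c("B", "C")))
  expect_lt(evaluate_recovery(coll, flip, "cpdag")$f1, 1)
  expect_error(evaluate_recovery(chain, bn_graph(c("A", "X"))), "node set")
})

test_that("d-separations of the truth show up as small partial correlations", {
  bad <- 0; checked <- 0
  for (s in 1:5) {
    tr <- make_ground_truth(seed = 700 + s, zero_inflation = numeric(0))
    d <- sample_dataset(tr, 2000, seed = 710 + s)
    m <- d$values
    a <- arcs(tr$dag)
    adj <- paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
    for (nd in tr$dag$nodes) {
      pa <- parents_of(tr$dag, nd)
      if (length(pa) == 0) next
      # non-descendant non-parents are d-separated from nd given its parents
      nondesc <- setdiff(tr$dag$nodes, c(nd, pa))
      nondesc <- nondesc[!vapply(nondesc, function(x)
        cycle_check(tr$dag, x, nd), logical(1))]  # drop descendants of nd
      for (x in nondesc) {
        checked <- checked + 1
        if (abs(partial_correlation(x, nd, pa, m)) >= 0.1) bad <- bad + 1
      }
    }
  }
  expect_gt(checked, 20)
  expect_lte(bad / checked, 0.05)
})

test_that("recovery does not degrade as the sample size grows", {
  ns <- c(125, 500, 2000)
  mean_f1 <- vapply(ns, function(n) {
    f1 <- vapply(1:5, function(s) {
      tr <- make_ground_truth(seed = 800 + s)
      d <- sample_dataset(tr, n, seed = 810 + s)
      evaluate_recovery(tr$dag,
                        learn_structure(d, learn_config("hc")), "cpdag")$f1
    }, numeric(1))
    mean(f1)
  }, numeric(1))
  expect_gte(mean_f1[2], mean_f1[1] - 0.05)
  expect_gte(mean_f1[3], mean_f1[2] - 0.05)
})
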