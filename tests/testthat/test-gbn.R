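test_that("maximum-likelihood fits recover exact linear relations", {
  x <- seq(0, 1, length.out = 50)
  d <- cbind(x = x, y = 0.5 + 2 * x)
  dag <- bn_graph(c("x", "y"), arcs = rbind(c("x", "y")))
  net <- fit_linear_gaussian(dag, d)
  expect_equal(net$cpds$y$intercept, 0.5, tolerance = 1e-10)
  expect_equal(unname(net$cpds$y$coefficients["x"]), 2, tolerance = 1e-10)
  expect_lte(net$cpds$y$sd, 1e-6)          # floored, never negative
  # root: sample mean and population (MLE) standard deviation
  expect_equal(net$cpds$x$intercept, mean(x))
  expect_equal(net$cpds$x$sd, sd(x) * sqrt(49 / 50))
  d2 <- cbind(a = x, b = x, y = x)
  dag2 <- bn_graph(c("a", "b", "y"), arcs = rbind(c("a", "y"), c("b", "y")))
  expect_error(fit_linear_gaussian(dag2, d2), "collinear")
})

test_that("fitted coefficients land within three standard errors of truth", {
  hits <- 0; total <- 0
  for (rep in 1:10) {
    tr <- make_ground_truth(seed = rep, zero_inflation = numeric(0))
    d <- sample_dataset(tr, 2000, seed = 400 + rep, rescale = FALSE)
    net <- fit_linear_gaussian(tr$dag, d)
    for (nd in tr$dag$nodes) {
      pa <- net$cpds[[nd]]$parents
      if (length(pa) == 0) next
      X <- cbind(1, d$values[, pa, drop = FALSE])
      sigma2 <- net$cpds[[nd]]$sd^2
      se <- sqrt(diag(solve(crossprod(X))) * sigma2 * 2000 / (2000 - ncol(X)))
      for (p1 in pa) {
        total <- total + 1
        err <- abs(net$cpds[[nd]]$coefficients[p1] -
                     tr$net$cpds[[nd]]$coefficients[p1])
        if (err <= 3 * se[match(p1, pa) + 1]) hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("logic sampling matches analytic marginals and is reproducible", {
  net <- two_node_net(sd = 0.1)
  s <- logic_sample(net, n = 1e5, seed = 15)
  mcse <- sqrt(var(s$X) / 1e5)
  expect_lt(abs(mean(s$X) - 0.45), 3 * mcse)
  expect_identical(s, logic_sample(net, n = 1e5, seed = 15))
  # zero-noise networks propagate deterministically
  net0 <- two_node_net(sd = 1e-12)
  s0 <- logic_sample(net0, n = 100, seed = 6)
  expect_true(all(s0$X %in% c(0.2, 0.7)))
  expect_equal(s0$X, 0.2 + 0.5 * s0$Cancer)
})

test_that("marginal means converge at the Monte-Carlo rate", {
  net <- two_node_net(sd = 0.1)
  errs <- vapply(c(1e3, 1e4, 1e5), function(n)
    abs(mean(logic_sample(net, n, seed = 9)$X) - 0.45), numeric(1))
  # errors shrink roughly like 1/sqrt(n): two decades of n, one of error
  expect_lt(errs[3], 0.005)
  expect_lt(errs[2], 0.05)
})

test_that("conditional queries filter samples by the evidence", {
  net <- two_node_net(sd = 0.1)
  hi <- conditional_query(net, query_spec("Cancer > 0.95"), seed = 2)
  lo <- conditional_query(net, query_spec("Cancer < 0.05"), seed = 2)
  mcse <- 0.1 / sqrt(2e4)
  expect_lt(abs(hi$summary$mean[hi$summary$feature == "X"] - 0.7), 3 * mcse)
  expect_lt(abs(lo$summary$mean[lo$summary$feature == "X"] - 0.2), 3 * mcse)
  expect_error(conditional_query(net, query_spec("Cancer > 2"), seed = 2),
               "empty support")
  expect_error(conditional_query(net, query_spec("Bogus > 0.5"), seed = 2),
               "unknown node")
})

test_that("an evidence-free query equals the unconditional summary", {
  net <- two_node_net(sd = 0.1)
  q <- conditional_query(net, query_spec(n_samples = 5000), seed = 3)
  s <- logic_sample(net, 5000, seed = 3)
  expect_equal(q$n_survivors, 5000)
  expect_equal(q$summary$mean[q$summary$feature == "X"], mean(s$X))
  expect_equal(q$summary$mean[q$summary$feature == "Cancer"], mean(s$Cancer))
})

test_that("trend slopes are reported for conditional and raw samples", {
  net <- two_node_net(sd = 0.1)
  q <- conditional_query(net, query_spec(report = "X", trend = "Cancer",
                                         n_samples = 2e4), seed = 4)
  expect_equal(q$summary$trend_slope_unconditional, 0.5, tolerance = 0.05)
  expect_equal(q$summary$trend_slope_conditional,
               q$summary$trend_slope_unconditional)  # no evidence filter
})

test_that("quantile contrasts compare the extreme groups", {
  key <- seq(0.01, 1, length.out = 100)
  withr::with_seed(61, {
    d <- cbind(CCN4 = key, up = key + rnorm(100, 0, 0.1),
               noise = rnorm(100))
  })
  qc <- quantile_contrast(d, "CCN4", n_quantiles = 5)
  expect_equal(unique(qc$n_bottom), 20)
  expect_equal(unique(qc$n_top), 20)
  up <- qc[qc$feature == "up", ]
  expect_gt(up$delta, 0.5)
  # the key feature against itself reproduces the extreme-quantile gap
  qk <- quantile_contrast(d, "CCN4", 5, report_features = "CCN4")
  expect_equal(qk$delta, mean(key[81:100]) - mean(key[1:20]))
  # an independent feature stays within sampling noise
  nz <- qc[qc$feature == "noise", ]
  pooled_se <- sqrt(1 / 20 + 1 / 20)
  expect_lt(abs(nz$delta), 3 * pooled_se)
  # n = 10 with 5 quantiles gives groups of exactly two
  q10 <- quantile_contrast(cbind(k = 1:10, v = rnorm(10)), "k", 5)
  expect_equal(unique(q10$n_bottom), 2)
  expect_error(quantile_contrast(cbind(k = rep(1, 10), v = rnorm(10)), "k"),
               "identical")
})

test_that("annotation merges coefficients, signs, and inclusion strengths", {
  x <- seq(0, 1, length.out = 60)
  withr::with_seed(71, {
    d <- cbind(x = x, y = 1 - 0.8 * x + rnorm(60, 0, 0.05),
               z = 0.5 * x + rnorm(60, 0, 0.05))
  })
  dag <- bn_graph(c("x", "y", "z"), arcs = rbind(c("x", "y"), c("x", "z")))
  net <- fit_linear_gaussian(dag, d)
  st <- data.frame(from = c("x", "x"), to = c("y", "z"),
                   strength = c(1.0, 0.8), direction = c(1, 1),
                   algorithm = "mmhc", n_boot = 100, seed = 1)
  ann <- annotate_network(net, st)
  expect_equal(ann$arcs$effect, c("inhibit", "promote"))
  expect_equal(ann$arcs$inclusion_probability, c(1.0, 0.8))
  # JSON round trip preserves the annotated graph
  path <- withr::local_tempfile(fileext = ".json")
  write_annotated_network(ann, path)
  back <- read_annotated_network(path)
  expect_equal(back$arcs, ann$arcs, tolerance = 1e-12)
  expect_equal(back$nodes, ann$nodes, tolerance = 1e-12)
  st_missing <- st[1, ]
  expect_error(annotate_network(net, st_missing), "no bootstrap strength")
})

test_that("refitting on logic samples recovers the generating parameters", {
  tr <- make_ground_truth(seed = 30, zero_inflation = numeric(0))
  d <- sample_dataset(tr, 2000, seed = 500, rescale = FALSE)
  net1 <- fit_linear_gaussian(tr$dag, d)
  s <- logic_sample(net1, 1e5, seed = 501)
  m <- as.matrix(s)
  net2 <- fit_linear_gaussian(tr$dag, m)
  for (nd in tr$dag$nodes) {
    pa <- net1$cpds[[nd]]$parents
    if (length(pa) == 0) next
    expect_equal(net2$cpds[[nd]]$coefficients, net1$cpds[[nd]]$coefficients,
                 tolerance = 0.1)
  }
})
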