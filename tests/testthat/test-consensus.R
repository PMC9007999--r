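test_that("ensemble aggregation counts detections and direction votes", {
  withr::with_seed(51, {
    x <- rnorm(200)
    d <- cbind(X = x, Y = x + rnorm(200, 0.1), Z = rnorm(200))
  })
  gXY <- bn_graph(c("X", "Y", "Z"), arcs = rbind(c("X", "Y")))
  gYX <- bn_graph(c("X", "Y", "Z"), arcs = rbind(c("Y", "X")))
  ev <- aggregate_ensemble(rep(list(gXY), 10), d)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_algorithms, 10)
  expect_true(ev$direction_consistent)
  expect_equal(c(ev$from, ev$to), c("X", "Y"))
  expect_lte(ev$min_p, ev$max_p)

  ev2 <- aggregate_ensemble(c(rep(list(gXY), 5), rep(list(gYX), 5)), d)
  expect_false(ev2$direction_consistent)

  gU <- bn_graph(c("X", "Y", "Z"), edges = rbind(c("X", "Y")))
  ev3 <- aggregate_ensemble(list(gXY, gU), d)
  expect_equal(ev3$n_algorithms, 2)
  expect_true(ev3$direction_consistent)  # the undirected net casts no vote

  expect_error(aggregate_ensemble(list(gXY, bn_graph(c("X", "Y"))), d),
               "node set")
})

test_that("candidate whitelists grow monotonically with the threshold", {
  nodes <- c("A", "B", "C")
  ev <- make_evidence(data.frame(
    from = c("A", "B", "A"), to = c("B", "C", "C"),
    n_algorithms = c(4, 3, 2),
    direction_consistent = c(TRUE, TRUE, FALSE),
    min_p = c(1e-15, 1e-8, 1e-12), max_p = c(1e-4, 1e-3, 1e-2)), nodes)
  sizes <- vapply(10^seq(-20, -2, length.out = 10), function(t)
    nrow(consensusbn:::evidence_whitelist(ev, t, NULL, "min_p")), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # direction-inconsistent arcs never enter
  wl <- consensusbn:::evidence_whitelist(ev, 1e-2, NULL, "min_p")
  expect_false(any(wl[, 1] == "A" & wl[, 2] == "C"))
  # blacklisted arcs are removed
  cl <- constraint_lists(blacklist = rbind(c("A", "B")))
  wl2 <- consensusbn:::evidence_whitelist(ev, 1e-2, cl, "min_p")
  expect_false(any(wl2[, 1] == "A" & wl2[, 2] == "B"))
})

test_that("the sweep records node-level BIC minima under growing whitelists", {
  tr <- make_ground_truth(seed = 20)
  d <- sample_dataset(tr, 300, seed = 201)
  bm <- benchmark_nodes()
  cl <- constraint_lists(blacklist = build_blacklist(bm$nodes, bm$roles))
  avg <- lapply(c("hc", "tabu"), function(a)
    averaged_network(bootstrap_arc_strengths(d, learn_config(a), cl,
                                             n_boot = 20, seed = 5)))
  ev <- aggregate_ensemble(avg, d)
  sw <- sweep_whitelist(ev, d, cl,
                        threshold_grid = 10^seq(-10, -2, length.out = 3))
  expect_s3_class(sw, "bic_sweep")
  expect_equal(sort(unique(sw$node)), sort(bm$nodes))
  expect_equal(nrow(sw), 3 * length(bm$nodes))
  expect_true(all(sw$bic >= 0))
  seed_wl <- suppressMessages(select_consensus_seed(sw))
  g <- bn_graph(bm$nodes, arcs = seed_wl)
  expect_true(is_acyclic(g))
})

test_that("consensus seed selection excludes exactly the cycle-forming arcs", {
  # a worked fixture: the hub node's five minimum-BIC parents include two
  # arcs that close cycles against other nodes' minimum-BIC selections
  nodes <- c("Endothelial", "Proliferation", "Cancer", "naiveB",
             "Mesenchymal", "pM1")
  parent_sets <- list(
    Endothelial = c("Proliferation", "Cancer", "naiveB", "Mesenchymal", "pM1"),
    Proliferation = "Endothelial",
    naiveB = "Endothelial",
    Cancer = character(0), Mesenchymal = character(0), pM1 = character(0))
  rows <- data.frame(threshold = 1e-10, node = nodes,
                     n_arcs = vapply(parent_sets[nodes], length, numeric(1)),
                     bic = c(119.4, 80, 60, 70, 50, 40))
  ev <- make_evidence(data.frame(
    from = c("Proliferation", "Cancer", "naiveB", "Mesenchymal", "pM1",
             "Endothelial", "Endothelial"),
    to = c(rep("Endothelial", 5), "Proliferation", "naiveB"),
    n_algorithms = 5, direction_consistent = TRUE,
    min_p = c(1e-6, 1e-9, 1e-5, 1e-10, 1e-8, 1e-12, 1e-11),
    max_p = 1e-3), nodes)
  sw <- make_sweep(rows, parent_sets, ev)
  expect_message(wl <- select_consensus_seed(sw), "cycle-forming")
  into_hub <- wl[wl[, 2] == "Endothelial", 1]
  expect_setequal(into_hub, c("Cancer", "Mesenchymal", "pM1"))
  excl <- attr(wl, "excluded")
  expect_setequal(excl[, 1], c("Proliferation", "naiveB"))
  expect_true(is_acyclic(bn_graph(nodes, arcs = wl)))
})

test_that("every randomized consensus seed is acyclic", {
  withr::with_seed(99, {
    for (k in 1:200) {
      p <- sample(4:7, 1)
      nodes <- paste0("n", seq_len(p))
      parent_sets <- lapply(seq_len(p), function(j)
        sample(nodes[-j], sample(0:min(3, p - 1), 1)))
      names(parent_sets) <- nodes
      rows <- data.frame(threshold = 1e-5, node = nodes,
                         n_arcs = vapply(parent_sets, length, numeric(1)),
                         bic = runif(p, 10, 100))
      ev <- make_evidence(data.frame(from = "n1", to = "n2",
                                     n_algorithms = 1,
                                     direction_consistent = TRUE,
                                     min_p = 1e-6, max_p = 1e-3), nodes)
      wl <- suppressMessages(select_consensus_seed(make_sweep(rows,
                                                              parent_sets,
                                                              ev)))
      expect_true(is_acyclic(bn_graph(nodes, arcs = wl)))
    }
  })
})

test_that("no-cycle selections take the union and deduplicate shared arcs", {
  nodes <- c("A", "B", "C")
  parent_sets <- list(A = character(0), B = "A", C = c("A", "B"))
  rows <- data.frame(threshold = 1e-5, node = nodes, n_arcs = c(0, 1, 2),
                     bic = c(1, 2, 3))
  ev <- make_evidence(data.frame(from = "A", to = "B", n_algorithms = 2,
                                 direction_consistent = TRUE,
                                 min_p = 1e-8, max_p = 1e-4), nodes)
  wl <- select_consensus_seed(make_sweep(rows, parent_sets, ev))
  expect_equal(nrow(wl), 3)
  expect_equal(nrow(unique(wl)), 3)
})

test_that("final learning honors both lists and reports inclusion", {
  tr <- make_ground_truth(seed = 22)
  d <- sample_dataset(tr, 300, seed = 220)
  bm <- benchmark_nodes()
  bl <- build_blacklist(bm$nodes, bm$roles)
  cl <- constraint_lists(blacklist = bl,
                         whitelist = rbind(c("Cancer", "CCN4")))
  fin <- final_learning(d, cl, n_boot = 30, seed = 3)
  st <- fin$strengths
  wl_row <- st[(st$from == "Cancer" & st$to == "CCN4") |
                 (st$from == "CCN4" & st$to == "Cancer"), ]
  expect_equal(wl_row$strength, 1.0)
  expect_equal(wl_row$direction, if (wl_row$from == "Cancer") 1.0 else 0.0)
  bl_pairs <- paste(pmin(bl[, 1], bl[, 2]), pmax(bl[, 1], bl[, 2]))
  fully_forbidden <- names(which(table(bl_pairs) == 2))
  pair <- paste(st$from, st$to)
  expect_true(all(st$strength[pair %in% fully_forbidden] == 0))
  expect_true(is_acyclic(fin$dag))
  a <- arcs(fin$dag)
  expect_true(any(a[, 1] == "Cancer" & a[, 2] == "CCN4"))
})

test_that("edges classify into the four evidence categories", {
  ev <- data.frame(from = c("A", "B", "C", "D"),
                   to = c("B", "C", "D", "E"),
                   n_algorithms = c(9, 7, 4, 1),
                   direction_consistent = c(TRUE, FALSE, FALSE, TRUE),
                   min_p = c(1e-12, 1e-9, 1e-4, 0.5),
                   max_p = c(1e-5, 1e-4, 1e-2, 0.9))
  seed_wl <- rbind(c("A", "B"), c("B", "C"))
  out <- classify_edges(ev, seed_wl)
  expect_equal(as.character(out$category),
               c("directed_seeded", "undirected_seeded", "undirected_only",
                 "excluded"))
})
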