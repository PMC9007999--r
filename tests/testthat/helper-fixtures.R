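# Shared fixtures and independent oracles used across the test files.

# chain X -> Y -> Z with configurable effect size and noise
chain_data <- function(n = 500, beta = 1, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- beta * x + rnorm(n, 0, sd)
    z <- beta * y + rnorm(n, 0, sd)
    cbind(X = x, Y = y, Z = z)
  })
}

# collider A -> C <- B
collider_data <- function(n = 500, beta = 1, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    a <- rnorm(n)
    b <- rnorm(n)
    cbind(A = a, B = b, C = beta * a + beta * b + rnorm(n, 0, sd))
  })
}

# independent oracle for the partial correlation: correlate the residuals
# of least-squares regressions on the conditioning set
oracle_pcor <- function(x, y, z, data) {
  resid_on <- function(v) {
    if (length(z) == 0) return(data[, v] - mean(data[, v]))
    stats::lm.fit(cbind(1, data[, z, drop = FALSE]), data[, v])$residuals
  }
  stats::cor(resid_on(x), resid_on(y))
}

# independent oracle for the exact t-test p-value (Student CDF)
oracle_t_pvalue <- function(r, n, nz) {
  df <- n - nz - 2
  t <- abs(r) * sqrt(df / (1 - r^2))
  2 * stats::pt(-t, df)
}

# brute-force node-level L1 BIC via explicit normal equations
oracle_l1_bic <- function(node, parents, data) {
  y <- data[, node]
  if (length(parents) == 0) {
    yhat <- rep(mean(y), length(y))
  } else {
    X <- cbind(1, data[, parents, drop = FALSE])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    yhat <- drop(X %*% beta)
  }
  length(parents) * log10(length(y)) + sum(abs(yhat - y))
}

# brute-force Gaussian BIC network score of one node
oracle_gaussian_score <- function(node, parents, data) {
  y <- data[, node]
  n <- length(y)
  if (length(parents) == 0) {
    res <- y - mean(y)
  } else {
    res <- stats::lm.fit(cbind(1, data[, parents, drop = FALSE]), y)$residuals
  }
  s2 <- max(sum(res^2) / n, 1e-12)
  -n / 2 * (log(2 * pi * s2) + 1) - (length(parents) + 2) / 2 * log(n)
}

# exhaustive path-existence oracle (tries all simple paths)
oracle_path_exists <- function(amat, from, to) {
  p <- nrow(amat)
  reach <- amat > 0
  for (k in seq_len(p)) reach <- reach | (reach %*% reach > 0)
  reach[from, to] > 0
}

# all DAG orientations of a skeleton, as a list of adjacency matrices
all_dag_orientations <- function(skel_pairs, nodes) {
  out <- list()
  np <- nrow(skel_pairs)
  if (np == 0) {
    g <- bn_graph(nodes)
    return(list(g))
  }
  for (mask in 0:(2^np - 1)) {
    arcs <- t(vapply(seq_len(np), function(k) {
      if (bitwAnd(mask, 2^(k - 1)) > 0) skel_pairs[k, 2:1] else skel_pairs[k, 1:2]
    }, character(2)))
    g <- bn_graph(nodes, arcs = arcs)
    if (is_acyclic(g)) out[[length(out) + 1]] <- g
  }
  out
}

# equivalence-class oracle: CPDAG by enumerating all DAGs with the same
# skeleton and v-structures and taking the union of orientations
oracle_cpdag <- function(dag) {
  nodes <- dag$nodes
  a <- arcs(dag)
  pairs <- cbind(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
  vkey <- function(g) {
    vs <- consensusbn:::find_v_structures(g$amat)
    if (nrow(vs) == 0) return(character(0))
    sort(apply(vs, 1, paste, collapse = ","))
  }
  ref <- vkey(dag)
  members <- Filter(function(g) identical(vkey(g), ref),
                    all_dag_orientations(pairs, nodes))
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (g in members) amat <- pmax(amat, consensusbn:::directed_amat(g))
  consensusbn:::as_bn_graph(amat, nodes)
}

# random DAG over p nodes (uniform order, arc probability dens)
random_dag <- function(p, dens = 0.4, seed = 1) {
  withr::with_seed(seed, {
    nodes <- paste0("N", seq_len(p))
    ord <- sample(p)
    arcs <- NULL
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      if (runif(1) < dens)
        arcs <- rbind(arcs, c(nodes[ord[a]], nodes[ord[b]]))
    }
    bn_graph(nodes, arcs = arcs)
  })
}

# hand-built edge-evidence and BIC-sweep objects for consensus tests
make_evidence <- function(df, nodes) {
  attr(df, "nodes") <- nodes
  class(df) <- c("edge_evidence", "data.frame")
  df
}

make_sweep <- function(rows, parent_sets, evidence) {
  key <- format(unique(rows$threshold), digits = 15)
  attr(rows, "whitelists") <- stats::setNames(list(NULL), key)
  attr(rows, "parent_sets") <- stats::setNames(list(parent_sets), key)
  attr(rows, "evidence") <- evidence
  attr(rows, "p_select") <- "min_p"
  class(rows) <- c("bic_sweep", "data.frame")
  rows
}

# hand-built two-node fitted network: Cancer ~ Bernoulli(0.5),
# X = 0.2 + 0.5 * Cancer + N(0, sd^2)
two_node_net <- function(sd = 0.1) {
  dag <- bn_graph(c("Cancer", "X"), arcs = rbind(c("Cancer", "X")))
  structure(list(
    dag = dag,
    cpds = list(
      Cancer = list(node = "Cancer", parents = character(0),
                    type = "bernoulli", prob = 0.5),
      X = list(node = "X", parents = "Cancer", type = "gaussian",
               intercept = 0.2, coefficients = c(Cancer = 0.5), sd = sd)),
    n_obs = NA_integer_), class = "fitted_network")
}
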