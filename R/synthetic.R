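# Ground-truth generators and recovery metrics. The benchmark family mimics
# the cell-level feature tables the pipeline consumes: a binary "Cancer"
# root attribute, an oncogene ("CCN4") child of the root, linear-Gaussian
# dependencies among free cell-prevalence nodes, and heavily zero-inflated
# leaf features.

#' Default node set and roles of the 12-node benchmark family
#'
#' One binary root (Cancer), one quasi-root oncogene (CCN4, child of
#' Cancer), eight free cell-level features, and two zero-inflated leaves
#' (CD4 T cells and Neutrophils, with zero fractions 0.60 and 0.75
#' mirroring the 350/582 and 439/582 zero counts of the breast-cancer
#' cohort).
#'
#' @return list with `nodes`, `roles` (a [node_roles()]), and
#'   `zero_inflation` (named vector of structural-zero probabilities).
#' @export
benchmark_nodes <- function() {
  nodes <- c("Cancer", "CCN4", "Mesenchymal", "Endothelial", "Proliferation",
             "Macrophages", "p_M1", "p_M2", "NK_active", "B_naive",
             "CD4_T_cells", "Neutrophils")
  list(nodes = nodes,
       roles = node_roles(root = "Cancer",
                          leaf = c("CD4_T_cells", "Neutrophils"),
                          quasi_root = list(CCN4 = "Cancer")),
       zero_inflation = c(CD4_T_cells = 0.60, Neutrophils = 0.75))
}

#' Generate a ground-truth network
#'
#' Draws a random DAG honoring a role map - the root has no parents,
#' leaves have no children, a quasi-root receives arcs only from its
#' allowed parents (those arcs are always present, making the oncogene a
#' child of the root) - and equips it with linear-Gaussian conditional
#' distributions: coefficients of random sign with magnitude drawn
#' uniformly from `coef_range`, residual standard deviation `sd`, and a
#' Bernoulli root attribute.
#'
#' @param nodes node names in generative (topological) order; default the
#'   12-node benchmark set.
#' @param roles a [node_roles()]; default the benchmark roles.
#' @param density probability that an admissible arc is present (default
#'   0.25).
#' @param coef_range magnitude range of arc coefficients (default
#'   `c(0.5, 1.5)`).
#' @param sd residual standard deviation of every non-root node (default
#'   0.2).
#' @param root_prob Bernoulli probability of the binary root (default 0.5,
#'   a balanced design).
#' @param zero_inflation named vector of structural-zero probabilities in
#'   \[0, 1); default the benchmark leaves.
#' @param seed integer seed; the truth is reproducible given the seed.
#' @return a `ground_truth` object (contains `dag`, the sampling network
#'   `net`, `roles`, `zero_inflation`, `seed`).
#' @export
make_ground_truth <- function(nodes = NULL, roles = NULL, density = 0.25,
                              coef_range = c(0.5, 1.5), sd = 0.2,
                              root_prob = 0.5, zero_inflation = NULL,
                              seed = 1) {
  if (is.null(nodes)) {
    bm <- benchmark_nodes()
    nodes <- bm$nodes
    if (is.null(roles)) roles <- bm$roles
    if (is.null(zero_inflation)) zero_inflation <- bm$zero_inflation
  }
  if (is.null(roles)) roles <- node_roles()
  if (is.null(zero_inflation)) zero_inflation <- numeric(0)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (any(coef_range <= 0)) stop("coefficient magnitudes must be positive")
  if (any(zero_inflation < 0 | zero_inflation >= 1))
    stop("zero-inflation probabilities must be in [0, 1)")
  unknown <- setdiff(names(zero_inflation), nodes)
  if (length(unknown) > 0)
    stop("zero_inflation names unknown node(s): ",
         paste(unknown, collapse = ", "))
  p <- length(nodes)
  is_root <- nodes %in% roles$root
  is_leaf <- nodes %in% roles$leaf
  qr <- roles$quasi_root
  admissible <- function(i, j) {
    # arc nodes[i] -> nodes[j], i earlier in the generative order
    if (is_root[j]) return(FALSE)
    if (is_leaf[i]) return(FALSE)
    if (nodes[j] %in% names(qr)) return(nodes[i] %in% qr[[nodes[j]]])
    TRUE
  }
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  with_local_seed(seed, function() {
    for (j in 2:p) for (i in 1:(j - 1)) {
      if (!admissible(i, j)) next
      forced <- nodes[j] %in% names(qr) && nodes[i] %in% qr[[nodes[j]]]
      if (forced || stats::runif(1) < density) amat[i, j] <<- 1L
    }
  })
  dag <- as_bn_graph(amat, nodes)
  cpds <- list()
  with_local_seed(derive_seed(seed, 1), function() {
    for (nd in nodes) {
      pa <- parents_of(dag, nd)
      if (length(pa) == 0 && is_root[match(nd, nodes)]) {
        cpds[[nd]] <<- list(node = nd, parents = character(0),
                            type = "bernoulli", prob = root_prob)
      } else {
        beta <- stats::runif(length(pa), coef_range[1], coef_range[2]) *
          sample(c(-1, 1), length(pa), replace = TRUE)
        cpds[[nd]] <<- list(node = nd, parents = pa, type = "gaussian",
                            intercept = stats::runif(1, 0.25, 0.75),
                            coefficients = stats::setNames(beta, pa),
                            sd = max(sd, SD_FLOOR))
      }
    }
  })
  net <- structure(list(dag = dag, cpds = cpds, n_obs = NA_integer_),
                   class = "fitted_network")
  structure(list(dag = dag, net = net, roles = roles,
                 zero_inflation = zero_inflation, root_prob = root_prob,
                 sd = sd, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$dag$nodes), "nodes,", nrow(arcs(x$dag)),
      "arcs, seed", x$seed, "\n")
  invisible(x)
}

#' Sample a dataset from a ground truth
#'
#' Ancestral sampling of the linear-Gaussian network. With
#' `rescale = TRUE` (the default) every continuous node is min-max scaled
#' to \[0, 1\] as it is generated, before feeding its children - the
#' features are bounded prevalence-like scores throughout, influences act
#' on that bounded scale, and noise never washes out (nor compounds into
#' near-determinism) down long causal chains. Structural zeros are then
#' injected: each zero-inflated feature is set to exactly 0 with its
#' stated probability, mirroring the zero-heavy features of real
#' digital-cytometry tables. With `rescale = FALSE` the raw structural
#' equations are returned unscaled and without zero inflation, so the
#' generative coefficients are exactly the regression coefficients of the
#' data - the mode used for parameter-recovery checks.
#'
#' @param truth a `ground_truth`.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param rescale bound each continuous feature to \[0, 1\] during
#'   generation and apply zero inflation (default `TRUE`).
#' @return a [feature_table()] with the binary root declared `attribute01`;
#'   flagged normalized when `rescale = TRUE`.
#' @export
sample_dataset <- function(truth, n_samples, seed = 1, rescale = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), n_samples >= 1)
  nodes <- truth$dag$nodes
  ord <- topological_order(truth$dag)
  raw <- matrix(NA_real_, n_samples, length(nodes),
                dimnames = list(NULL, nodes))
  with_local_seed(seed, function() {
    for (nd in ord) {
      cpd <- truth$net$cpds[[nd]]
      if (cpd$type == "bernoulli") {
        raw[, nd] <<- stats::rbinom(n_samples, 1, cpd$prob)
        next
      }
      mu <- rep(cpd$intercept, n_samples)
      if (length(cpd$parents) > 0)
        mu <- mu + raw[, cpd$parents, drop = FALSE] %*% cpd$coefficients
      x <- mu + stats::rnorm(n_samples, 0, cpd$sd)
      if (rescale) {
        rng <- range(x)
        x <- if (rng[1] == rng[2]) rep(0, n_samples) else
          (x - rng[1]) / (rng[2] - rng[1])
      }
      raw[, nd] <<- x
    }
  })
  if (rescale && length(truth$zero_inflation) > 0) {
    with_local_seed(derive_seed(seed, 1), function() {
      for (nd in names(truth$zero_inflation)) {
        mask <- stats::runif(n_samples) < truth$zero_inflation[[nd]]
        raw[mask, nd] <<- 0
      }
    })
  }
  binary <- vapply(nodes, function(nd)
    truth$net$cpds[[nd]]$type == "bernoulli", logical(1))
  kind <- stats::setNames(ifelse(binary, "attribute01", "continuous"), nodes)
  ft <- feature_table(raw[, nodes, drop = FALSE], column_kind = kind)
  if (rescale) ft$normalized <- TRUE  # columns are already in [0, 1]
  ft
}

#' Structure-recovery metrics against a ground truth
#'
#' Compares a learned graph to the true DAG. In `directed` mode arcs must
#' match exactly (an undirected learned edge never matches a directed true
#' arc). In `cpdag` mode both graphs are collapsed to their Markov
#' equivalence classes with [to_cpdag()] first, so an arc reversed within
#' its equivalence class is not penalized. The structural Hamming distance
#' (SHD) counts edge insertions, deletions, and re-orientations.
#'
#' @param truth_dag the true `bn_graph` (fully directed, acyclic).
#' @param learned the learned `bn_graph` (may contain undirected edges; a
#'   partially directed graph is compared as-is in `cpdag` mode).
#' @param mode `"directed"` or `"cpdag"`.
#' @return data.frame with `precision`, `recall`, `f1`, `shd`, `tp`,
#'   `n_true`, `n_learned`.
#' @export
evaluate_recovery <- function(truth_dag, learned,
                              mode = c("directed", "cpdag")) {
  mode <- match.arg(mode)
  if (!identical(sort(truth_dag$nodes), sort(learned$nodes)))
    stop("truth and learned graphs must share one node set")
  gt <- truth_dag
  gl <- learned
  if (mode == "cpdag") {
    gt <- to_cpdag(truth_dag)
    if (nrow(undirected_edges(learned)) == 0) gl <- to_cpdag(learned)
  }
  # canonical edge descriptors ("a>b" directed, "a-b" undirected) plus the
  # unordered pair of each
  describe <- function(g) {
    a <- arcs(g)
    e <- undirected_edges(g)
    desc <- character(0); pair <- character(0)
    if (nrow(a) > 0) {
      desc <- c(desc, paste(a[, 1], a[, 2], sep = ">"))
      pair <- c(pair, paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]),
                            sep = "\r"))
    }
    if (nrow(e) > 0) {
      desc <- c(desc, paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
                            sep = "-"))
      pair <- c(pair, paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
                            sep = "\r"))
    }
    list(desc = desc, pair = pair)
  }
  dt <- describe(gt)
  dl <- describe(gl)
  tp <- length(intersect(dt$desc, dl$desc))
  n_true <- length(dt$desc)
  n_learned <- length(dl$desc)
  precision <- if (n_learned == 0) 0 else tp / n_learned
  recall <- if (n_true == 0) 1 else tp / n_true
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  # SHD over unordered pairs: insertions, deletions, re-orientations
  shared <- intersect(dt$pair, dl$pair)
  mismatched <- sum(!(dt$desc[dt$pair %in% shared] %in% dl$desc))
  shd <- length(setdiff(dt$pair, dl$pair)) +
    length(setdiff(dl$pair, dt$pair)) + mismatched
  data.frame(precision = precision, recall = recall, f1 = f1, shd = shd,
             tp = tp, n_true = n_true, n_learned = n_learned)
}
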