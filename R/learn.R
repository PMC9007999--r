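#' Configuration for structure learning
#'
#' @param algorithm one of `"hc"`, `"tabu"` (score-based greedy search),
#'   `"pc_stable"`, `"gs"`, `"iamb"`, `"iamb_fdr"` (constraint-based),
#'   `"mmpc"`, `"si_hiton_pc"` (local discovery of undirected
#'   parent-children graphs), `"mmhc"`, `"rsmax2"` (hybrid
#'   restrict-then-maximize).
#' @param alpha significance level of the conditional-independence tests
#'   (default 0.05).
#' @param max_parents cap on the number of parents per node in score-based
#'   search; 0 = unlimited.
#' @param max_sepset largest conditioning-set size examined by the
#'   constraint-based and local-discovery algorithms (default 5).
#' @param tabu_length length of the tabu list (visited-graph memory).
#' @param restarts number of random restarts for `hc` (default 1; each
#'   restart perturbs the best graph with random admissible arc additions
#'   and climbs again, keeping the higher-scoring optimum; uses the R RNG).
#' @param restrict,maximize component algorithms for `rsmax2` (defaults:
#'   `si_hiton_pc` restrict phase, `tabu` maximize phase).
#' @param seed optional integer seed for the (rarely needed) stochastic
#'   parts of search.
#' @return an object of class `learn_config`.
#' @export
learn_config <- function(algorithm = "hc", alpha = 0.05, max_parents = 0,
                         max_sepset = 5, tabu_length = 10, restarts = 1,
                         restrict = "si_hiton_pc", maximize = "tabu",
                         seed = NULL) {
  algorithms <- c("hc", "tabu", "pc_stable", "gs", "iamb", "iamb_fdr",
                  "mmpc", "si_hiton_pc", "mmhc", "rsmax2")
  if (!algorithm %in% algorithms)
    stop("unknown algorithm '", algorithm, "'; available: ",
         paste(algorithms, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(algorithm = algorithm, alpha = alpha,
                 max_parents = max_parents, max_sepset = max_sepset,
                 tabu_length = tabu_length, restarts = restarts,
                 restrict = restrict, maximize = maximize, seed = seed),
            class = "learn_config")
}

#' Learn a network structure from data
#'
#' Runs one of the ten supported structure-learning algorithms on a
#' preprocessed feature table, honoring a blacklist (arcs never present)
#' and a whitelist (arcs always present). Score-based algorithms perform
#' greedy ascent of the Gaussian BIC score over add / delete / reverse
#' moves; constraint-based algorithms build a skeleton from
#' conditional-independence tests (the exact t-test on partial
#' correlations), orient v-structures and propagate orientations;
#' local-discovery algorithms return undirected parent-children graphs;
#' hybrid algorithms restrict the search space with a local-discovery
#' skeleton and then score-maximize within it.
#'
#' @param data a [feature_table()], matrix, or data.frame of numeric
#'   features (preprocessed; columns are the network nodes).
#' @param cfg a [learn_config()].
#' @param constraints a [constraint_lists()] or `NULL`.
#' @return a `bn_graph`; constraint-based outputs may contain undirected
#'   edges, local-discovery outputs contain only undirected edges.
#' @export
learn_structure <- function(data, cfg = learn_config(), constraints = NULL) {
  m <- as_feature_matrix(data)
  nodes <- colnames(m)
  if (length(nodes) > 56)
    stop("at most 56 nodes are supported")
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_lists"))
    unknown <- setdiff(c(constraints$blacklist, constraints$whitelist), nodes)
    if (length(unknown) > 0)
      stop("constraints refer to feature(s) absent from the data: ",
           paste(unknown, collapse = ", "))
  }
  cm <- constraint_amats(constraints, nodes)
  S <- mle_cov(m)
  amat <- learn_backend(S, nrow(m), cfg, cm$bl, cm$wl)
  as_bn_graph(amat, nodes)
}

# Core dispatcher working on the moment matrix; used directly by the
# bootstrap loop so the covariance of each resample is computed once.
learn_backend <- function(S, n, cfg, blm, wlm) {
  switch(cfg$algorithm,
    hc = hc_backend(S, n, cfg, blm, wlm, tabu = FALSE),
    tabu = hc_backend(S, n, cfg, blm, wlm, tabu = TRUE),
    pc_stable = pc_stable_backend(S, n, cfg, blm, wlm),
    gs = mb_backend(S, n, cfg, blm, wlm, variant = "gs"),
    iamb = mb_backend(S, n, cfg, blm, wlm, variant = "iamb"),
    iamb_fdr = mb_backend(S, n, cfg, blm, wlm, variant = "iamb_fdr"),
    mmpc = local_backend(S, n, cfg, blm, wlm, variant = "mmpc"),
    si_hiton_pc = local_backend(S, n, cfg, blm, wlm, variant = "si_hiton_pc"),
    mmhc = hybrid_backend(S, n, cfg, blm, wlm,
                          restrict = "mmpc", maximize = "hc"),
    rsmax2 = hybrid_backend(S, n, cfg, blm, wlm,
                            restrict = cfg$restrict, maximize = cfg$maximize),
    stop("unknown algorithm: ", cfg$algorithm))
}

# ---- score-based ----------------------------------------------------------

hc_backend <- function(S, n, cfg, blm, wlm, tabu) {
  p <- nrow(S)
  start <- wlm
  res <- cpp_hc(S, n, blm, wlm, start,
                as.integer(cfg$max_parents),
                if (tabu) as.integer(cfg$tabu_length) else 0L,
                as.integer(cfg$tabu_length), 2000L)
  if (!tabu && cfg$restarts > 0) {
    # restarts are deterministic given the config seed, so repeated learns
    # on the same data reproduce the same graph
    res <- with_local_seed(cfg$seed %||% 1L, function() {
      best <- res
      best_score <- amat_score(S, n, best)
      for (r in seq_len(cfg$restarts)) {
        pert <- perturb_amat(best, blm, wlm, p)
        cand <- cpp_hc(S, n, blm, wlm, pert, as.integer(cfg$max_parents),
                       0L, 0L, 2000L)
        sc <- amat_score(S, n, cand)
        if (sc > best_score + 1e-10) {
          best <- cand
          best_score <- sc
        }
      }
      best
    })
  }
  res
}

amat_score <- function(S, n, amat) {
  p <- nrow(amat)
  sum(vapply(seq_len(p), function(j) {
    cpp_node_score(S, n, j - 1L, which(amat[, j] == 1L) - 1L)
  }, numeric(1)))
}

# random perturbation for hc restarts: try to add a few random admissible
# arcs to the current optimum
perturb_amat <- function(amat, blm, wlm, p) {
  for (k in 1:4) {
    i <- sample.int(p, 1); j <- sample.int(p, 1)
    if (i == j || amat[i, j] == 1L || amat[j, i] == 1L ||
        blm[i, j] == 1L || wlm[j, i] == 1L)
      next
    if (cpp_path_exists(amat, j - 1L, i - 1L)) next
    amat[i, j] <- 1L
  }
  amat
}

# ---- hybrid ---------------------------------------------------------------

hybrid_backend <- function(S, n, cfg, blm, wlm, restrict, maximize) {
  skel <- switch(restrict,
    mmpc = local_backend(S, n, cfg, blm, wlm, variant = "mmpc"),
    si_hiton_pc = local_backend(S, n, cfg, blm, wlm, variant = "si_hiton_pc"),
    stop("unsupported restrict algorithm: ", restrict))
  adj <- skel == 1L | t(skel) == 1L
  # forbid arcs outside the restricted skeleton, on top of the blacklist;
  # whitelisted arcs stay admissible regardless
  forbid <- blm
  forbid[!adj] <- 1L
  forbid[wlm == 1L] <- 0L
  forbid[blm == 1L] <- 1L
  use_tabu <- identical(maximize, "tabu")
  cpp_hc(S, n, forbid, wlm, wlm, as.integer(cfg$max_parents),
         if (use_tabu) as.integer(cfg$tabu_length) else 0L,
         as.integer(cfg$tabu_length), 2000L)
}
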