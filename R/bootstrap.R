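# derive a child seed, kept inside the 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 9973 * as.numeric(k)) %% 2147483647)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fun()
}

#' Bootstrap arc strengths
#'
#' Resamples the dataset with replacement (each resample the same size as
#' the original), learns a network structure on every resample, and
#' tabulates for every unordered node pair the *strength* (fraction of
#' bootstrap networks containing the edge in either direction) and the
#' *direction* (fraction of edge-containing networks orienting it
#' `from -> to`; an undirected occurrence contributes half a vote to each
#' orientation). Whitelisted pairs therefore have strength 1 by
#' construction and blacklisted-pair strengths are 0. The default number of
#' resamples mirrors the reference workflow (10,000); smaller values are
#' appropriate for exploration.
#'
#' @param data a [feature_table()], matrix, or data.frame.
#' @param cfg a [learn_config()].
#' @param constraints a [constraint_lists()] or `NULL`.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer seed; the whole table is reproducible given the seed.
#' @return a `boot_strength` data.frame with columns `from`, `to`
#'   (lexicographic pair order), `strength`, `direction`, `algorithm`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_arc_strengths <- function(data, cfg = learn_config(),
                                    constraints = NULL, n_boot = 10000,
                                    seed = 1) {
  stopifnot(n_boot >= 1)
  m <- as_feature_matrix(data)
  nodes <- colnames(m)
  p <- length(nodes)
  n <- nrow(m)
  cm <- constraint_amats(constraints, nodes)
  edge_count <- matrix(0, p, p)  # upper triangle: pair inclusion counts
  dir_count <- matrix(0, p, p)   # upper triangle: votes for i -> j
  with_local_seed(seed, function() {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      ctr <- scale(mb, center = TRUE, scale = FALSE)
      S <- crossprod(ctr) / n
      amat <- learn_backend(S, n, cfg, cm$bl, cm$wl)
      dir <- amat == 1L & t(amat) == 0L
      und <- amat == 1L & t(amat) == 1L
      pres <- dir | t(dir) | und
      edge_count <<- edge_count + pres
      dir_count <<- dir_count + dir + 0.5 * und
    }
  })
  ij <- which(upper.tri(edge_count), arr.ind = TRUE)
  cnt <- edge_count[ij]
  dirv <- dir_count[ij]
  a <- nodes[ij[, 1]]
  b <- nodes[ij[, 2]]
  direction <- ifelse(cnt > 0, dirv / cnt, 0.5)
  # canonical pair order: alphabetically smaller node first
  flip <- a > b
  direction[flip] <- 1 - direction[flip]
  out <- data.frame(from = pmin(a, b), to = pmax(a, b),
                    strength = cnt / n_boot, direction = direction,
                    algorithm = cfg$algorithm, n_boot = n_boot, seed = seed,
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), ]
  rownames(out) <- NULL
  attr(out, "nodes") <- nodes
  class(out) <- c("boot_strength", "data.frame")
  out
}

#' Automatic arc-inclusion threshold for model averaging
#'
#' Estimates the strength threshold above which arcs enter the averaged
#' network, by minimizing the L1 distance between the empirical CDF of the
#' observed strengths and the ideal step CDF of a perfectly regularized
#' network in which every arc has strength 0 (absent) or 1 (present).
#' Candidate thresholds are the observed unique strengths; ties are broken
#' toward the larger threshold, yielding the sparser network. The estimate
#' is nominally close to 0.5 for well-separated strength distributions.
#'
#' @param strengths numeric vector of arc strengths in \[0, 1\].
#' @return the estimated threshold.
#' @export
optimal_inclusion_threshold <- function(strengths) {
  if (length(strengths) == 0) stop("empty strength vector")
  if (any(strengths < 0 | strengths > 1)) stop("strengths must lie in [0, 1]")
  u <- sort(unique(strengths))
  ecdf_vals <- vapply(u, function(v) mean(strengths <= v), numeric(1))
  # piecewise-constant segments of the empirical CDF over [0, 1]
  starts <- c(0, u)
  ends <- c(u, 1)
  fvals <- c(0, ecdf_vals)
  lens <- ends - starts
  l1_dist <- vapply(u, function(t) {
    a <- mean(strengths < t)  # ideal CDF: plateau at the noise fraction
    sum(lens * abs(fvals - a))
  }, numeric(1))
  best <- l1_dist <= min(l1_dist) + 1e-12
  max(u[best])
}

#' Averaged network from a bootstrap strength table
#'
#' Keeps the pairs whose strength reaches the threshold (estimated with
#' [optimal_inclusion_threshold()] when not supplied) and orients each by
#' majority vote: `from -> to` when `direction > 0.5`, the reverse when
#' `< 0.5`, undirected at exactly 0.5. If the directed part of the result
#' contains cycles (possible since arcs are selected marginally), the
#' weakest arc of each cycle is dropped with a message until the graph is
#' acyclic.
#'
#' @param strength_table a `boot_strength` table from
#'   [bootstrap_arc_strengths()].
#' @param threshold inclusion threshold in \[0, 1\], or `NULL` to estimate.
#' @return a `bn_graph` (possibly with undirected edges) with the used
#'   threshold in the `threshold` attribute.
#' @export
averaged_network <- function(strength_table, threshold = NULL) {
  nodes <- attr(strength_table, "nodes")
  if (is.null(nodes))
    nodes <- sort(unique(c(strength_table$from, strength_table$to)))
  if (is.null(threshold))
    threshold <- optimal_inclusion_threshold(strength_table$strength)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keep <- strength_table[strength_table$strength >= threshold &
                           strength_table$strength > 0, , drop = FALSE]
  g <- bn_graph(nodes)
  strength_of <- stats::setNames(keep$strength,
                                 paste(keep$from, keep$to, sep = "\r"))
  for (k in seq_len(nrow(keep))) {
    if (keep$direction[k] > 0.5) {
      g <- add_arc(g, keep$from[k], keep$to[k])
    } else if (keep$direction[k] < 0.5) {
      g <- add_arc(g, keep$to[k], keep$from[k])
    } else {
      g <- add_edge(g, keep$from[k], keep$to[k])
    }
  }
  # cycle repair: drop the weakest arc on a cycle until acyclic
  while (!is_acyclic(g)) {
    a <- arcs(g)
    on_cycle <- vapply(seq_len(nrow(a)), function(k) {
      gg <- g
      gg$amat[node_index(g, a[k, 1]), node_index(g, a[k, 2])] <- 0L
      cpp_path_exists(directed_amat(gg), node_index(g, a[k, 2]) - 1L,
                      node_index(g, a[k, 1]) - 1L)
    }, logical(1))
    cyc <- a[on_cycle, , drop = FALSE]
    key <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]),
                 sep = "\r")
    s <- strength_of[key]
    drop_k <- which.min(s)
    message("averaged_network: dropping arc ", cyc[drop_k, 1], " -> ",
            cyc[drop_k, 2], " (strength ", signif(s[drop_k], 3),
            ") to break a cycle")
    g$amat[node_index(g, cyc[drop_k, 1]), node_index(g, cyc[drop_k, 2])] <- 0L
  }
  attr(g, "threshold") <- threshold
  g
}
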