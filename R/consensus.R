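# Consensus across the algorithm ensemble: evidence aggregation, the
# node-level BIC threshold sweep, seed-whitelist selection with cycle
# exclusion, and the final constrained learning.

#' Aggregate the averaged networks of an algorithm ensemble
#'
#' Builds the edge-evidence table: for every edge detected by at least one
#' algorithm's averaged network, the number of detecting algorithms
#' (undirected-output algorithms count as detection without a direction
#' vote), whether the direction-voting algorithms all agree, the agreed
#' orientation if so, and the extremes (`min_p`, `max_p`) of the
#' arc-significance p-values evaluated within each detecting algorithm's
#' network.
#'
#' @param averaged_networks named list of `bn_graph`s sharing one node set
#'   (one per algorithm).
#' @param data the feature table the networks were learned from.
#' @return an `edge_evidence` data.frame with one row per detected edge:
#'   `from`, `to` (the agreed orientation, or the lexicographic pair order
#'   when direction is unresolved), `n_algorithms`, `direction_consistent`,
#'   `min_p`, `max_p`.
#' @export
aggregate_ensemble <- function(averaged_networks, data) {
  stopifnot(length(averaged_networks) >= 1)
  nodes <- averaged_networks[[1]]$nodes
  for (g in averaged_networks) {
    if (!identical(sort(g$nodes), sort(nodes)))
      stop("averaged networks must share a common node set")
  }
  m <- as_feature_matrix(data)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  rec <- new.env(parent = emptyenv())
  note <- function(a, b, orientation, p) {
    k <- pair_key(a, b)
    cur <- rec[[k]]
    if (is.null(cur))
      cur <- list(a = min(a, b), b = max(a, b), n = 0L,
                  votes = character(0), ps = numeric(0))
    cur$n <- cur$n + 1L
    if (!is.na(orientation)) cur$votes <- c(cur$votes, orientation)
    cur$ps <- c(cur$ps, p)
    rec[[k]] <- cur
  }
  for (g in averaged_networks) {
    a <- arcs(g)
    for (k in seq_len(nrow(a))) {
      p <- arc_significance(g, a[k, ], m)$p_value
      note(a[k, 1], a[k, 2], paste(a[k, 1], a[k, 2], sep = "\r"), p)
    }
    e <- undirected_edges(g)
    for (k in seq_len(nrow(e))) {
      # no orientation vote; significance from the plain pairwise test
      r <- partial_correlation(e[k, 1], e[k, 2], character(0), m)
      p <- exact_t_pvalue(r, nrow(m), 0)
      note(e[k, 1], e[k, 2], NA_character_, p)
    }
  }
  keys <- sort(ls(rec))
  rows <- lapply(keys, function(k) {
    cur <- rec[[k]]
    consistent <- length(unique(cur$votes)) == 1
    if (consistent) {
      ft <- strsplit(cur$votes[1], "\r", fixed = TRUE)[[1]]
    } else {
      ft <- c(cur$a, cur$b)
    }
    data.frame(from = ft[1], to = ft[2], n_algorithms = cur$n,
               direction_consistent = consistent,
               min_p = min(cur$ps), max_p = max(cur$ps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nodes") <- nodes
  class(out) <- c("edge_evidence", "data.frame")
  out
}

evidence_whitelist <- function(evidence, threshold, constraints,
                               p_select = c("min_p", "max_p")) {
  p_select <- match.arg(p_select)
  cand <- evidence[evidence$direction_consistent &
                     evidence[[p_select]] <= threshold, , drop = FALSE]
  wl <- as.matrix(cand[, c("from", "to")])
  if (!is.null(constraints) && nrow(constraints$blacklist) > 0 && nrow(wl) > 0) {
    bl_keys <- paste(constraints$blacklist[, 1], constraints$blacklist[, 2],
                     sep = "\r")
    wl <- wl[!(paste(wl[, 1], wl[, 2], sep = "\r") %in% bl_keys), ,
             drop = FALSE]
  }
  wl
}

#' Sweep significance thresholds to profile candidate whitelists
#'
#' For each threshold in an ascending grid, the candidate whitelist is the
#' set of direction-consistent evidence arcs whose significance beats the
#' threshold (arcs whose inferred direction varied among the algorithms are
#' left out), minus any blacklisted arc. A DAG is learned under that
#' whitelist with the final-learning search settings, and the node-level
#' L1-BIC and parent count of every node are recorded.
#'
#' @param evidence an `edge_evidence` table from [aggregate_ensemble()].
#' @param data the feature table.
#' @param constraints a [constraint_lists()] (its whitelist is ignored
#'   during the sweep) or `NULL`.
#' @param threshold_grid positive ascending thresholds (default 10
#'   log-spaced points from 1e-20 to 1e-2).
#' @param p_select which evidence p-value gates membership: `"min_p"`
#'   (default: an edge enters on its best evidence) or `"max_p"`.
#' @param cfg search configuration for the per-threshold DAG learning
#'   (default `mmhc`, matching the final learning step).
#' @return a `bic_sweep` object: data.frame with one row per
#'   (threshold, node): `threshold`, `node`, `n_arcs`, `bic`, plus the
#'   per-threshold whitelists and learned parent sets as attributes.
#' @export
sweep_whitelist <- function(evidence, data, constraints = NULL,
                            threshold_grid = 10^seq(-20, -2, length.out = 10),
                            p_select = "min_p",
                            cfg = learn_config("mmhc")) {
  stopifnot(all(threshold_grid > 0), !is.unsorted(threshold_grid))
  m <- as_feature_matrix(data)
  nodes <- colnames(m)
  rows <- list()
  wls <- list()
  parent_sets <- list()
  for (t in threshold_grid) {
    wl <- evidence_whitelist(evidence, t, constraints, p_select)
    cl <- constraint_lists(blacklist = if (is.null(constraints)) NULL
                                       else constraints$blacklist,
                           whitelist = wl)
    dag <- learn_structure(m, cfg, cl)
    key <- format(t, digits = 15)
    wls[[key]] <- wl
    parent_sets[[key]] <- stats::setNames(
      lapply(nodes, function(nd) parents_of(dag, nd)), nodes)
    for (nd in nodes) {
      rec <- node_l1_bic(nd, parents_of(dag, nd), m)
      rows[[length(rows) + 1L]] <-
        data.frame(threshold = t, node = nd, n_arcs = rec$n_arcs,
                   bic = rec$bic, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "whitelists") <- wls
  attr(out, "parent_sets") <- parent_sets
  attr(out, "evidence") <- evidence
  attr(out, "p_select") <- p_select
  class(out) <- c("bic_sweep", "data.frame")
  out
}

#' Select the consensus seed whitelist from a BIC sweep
#'
#' For each node, the parent set at its minimum node-level BIC is taken
#' (ties resolve to fewer arcs, then to the smaller threshold). The union
#' of these parental arcs is then admitted greedily in ascending
#' significance (p-value) order; any arc whose addition would create a
#' directed cycle with previously admitted arcs is skipped and reported.
#' The result - the consensus seed network - is therefore acyclic by
#' construction.
#'
#' @param sweep a `bic_sweep` from [sweep_whitelist()].
#' @return two-column character matrix (`from`, `to`) of whitelist arcs,
#'   with skipped cycle-forming arcs in the `excluded` attribute.
#' @export
select_consensus_seed <- function(sweep) {
  stopifnot(inherits(sweep, "bic_sweep"), nrow(sweep) > 0)
  evidence <- attr(sweep, "evidence")
  parent_sets <- attr(sweep, "parent_sets")
  nodes <- unique(sweep$node)
  # per node: parent set at min BIC (ties -> fewer arcs -> smaller threshold)
  chosen <- list()
  for (nd in nodes) {
    rows <- sweep[sweep$node == nd, , drop = FALSE]
    rows <- rows[order(rows$bic, rows$n_arcs, rows$threshold), , drop = FALSE]
    key <- format(rows$threshold[1], digits = 15)
    chosen[[nd]] <- parent_sets[[key]][[nd]]
  }
  cand <- do.call(rbind, lapply(nodes, function(nd) {
    pa <- chosen[[nd]]
    if (length(pa) == 0) return(NULL)
    cbind(from = pa, to = nd)
  }))
  if (is.null(cand) || nrow(cand) == 0) {
    out <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
    attr(out, "excluded") <- out
    return(out)
  }
  cand <- unique(cand)
  # attach evidence p-values for the admission order (strongest first)
  pv <- rep(1, nrow(cand))
  if (!is.null(evidence)) {
    key_ev <- paste(evidence$from, evidence$to, sep = "\r")
    ix <- match(paste(cand[, 1], cand[, 2], sep = "\r"), key_ev)
    pv[!is.na(ix)] <- evidence$min_p[ix[!is.na(ix)]]
  }
  ord <- order(pv, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  all_nodes <- unique(c(cand[, 1], cand[, 2], nodes))
  g <- bn_graph(all_nodes)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cycle_check(g, cand[k, 1], cand[k, 2])) {
      message("select_consensus_seed: excluding cycle-forming arc ",
              cand[k, 1], " -> ", cand[k, 2])
    } else {
      g <- add_arc(g, cand[k, 1], cand[k, 2])
      keep[k] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  excl <- cand[!keep, , drop = FALSE]
  attr(out, "excluded") <- excl[order(excl[, 1], excl[, 2]), , drop = FALSE]
  out
}

#' Final constrained learning
#'
#' The last step of the workflow: hybrid search (`mmhc` by default) under
#' the prior-knowledge blacklist and the consensus-seed whitelist, with
#' bootstrap resampling and model averaging. Arc strengths of the averaged
#' network serve as posterior inclusion probabilities for annotation.
#'
#' @param data the feature table.
#' @param constraints a [constraint_lists()] carrying the blacklist and the
#'   seed whitelist.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param cfg search configuration (default `mmhc`).
#' @return list with elements `strengths` (the `boot_strength` table) and
#'   `dag` (the averaged `bn_graph`).
#' @export
final_learning <- function(data, constraints, n_boot = 10000, seed = 1,
                           cfg = learn_config("mmhc")) {
  st <- bootstrap_arc_strengths(data, cfg, constraints, n_boot, seed)
  dag <- averaged_network(st)
  list(strengths = st, dag = dag)
}

#' Classify evidence edges against the final network
#'
#' Reproduces the four-way evidence coloring: `directed_seeded`
#' (direction-consistent and part of the consensus seed),
#' `undirected_seeded` (direction varied among algorithms but the edge is
#' in the seed), `undirected_only` (significant evidence without direction
#' agreement, not seeded), and `excluded`.
#'
#' @param evidence an `edge_evidence` table.
#' @param seed_whitelist the consensus-seed arc matrix from
#'   [select_consensus_seed()].
#' @param sig_threshold evidence significance cut for the
#'   `undirected_only` category (default 0.05).
#' @return the evidence table with an added `category` factor column.
#' @export
classify_edges <- function(evidence, seed_whitelist, sig_threshold = 0.05) {
  pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  seeded <- character(0)
  if (NROW(seed_whitelist) > 0)
    seeded <- pair(seed_whitelist[, 1], seed_whitelist[, 2])
  ev_pair <- pair(evidence$from, evidence$to)
  category <- ifelse(ev_pair %in% seeded,
                     ifelse(evidence$direction_consistent,
                            "directed_seeded", "undirected_seeded"),
                     ifelse(!evidence$direction_consistent &
                              evidence$min_p <= sig_threshold,
                            "undirected_only", "excluded"))
  evidence$category <- factor(category,
                              levels = c("directed_seeded",
                                         "undirected_seeded",
                                         "undirected_only", "excluded"))
  evidence
}
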