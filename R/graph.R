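#' Directed (and partially directed) graphs over feature nodes
#'
#' `bn_graph` is the graph container used throughout the package. Nodes are
#' the features of a table; directed arcs represent inferred causal
#' influences, while undirected edges represent adjacencies whose direction
#' could not be resolved (CPDAG and local-discovery outputs). Internally the
#' graph is stored as an adjacency matrix `amat` where `amat[i, j] == 1`
#' codes an arc i -> j; if both `amat[i, j]` and `amat[j, i]` are 1 the pair
#' is an undirected edge.
#'
#' @param nodes character vector of unique node names.
#' @param arcs two-column character matrix (or data.frame) of directed arcs,
#'   columns `from`, `to`. May be `NULL`.
#' @param edges two-column character matrix of undirected edges. May be
#'   `NULL`.
#' @return an object of class `bn_graph`.
#' @examples
#' g <- bn_graph(c("A", "B", "C"), arcs = rbind(c("A", "B"), c("B", "C")))
#' arcs(g)
#' @export
bn_graph <- function(nodes, arcs = NULL, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat), class = "bn_graph")
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.matrix(arcs)
    for (k in seq_len(nrow(arcs))) g <- add_arc(g, arcs[k, 1], arcs[k, 2])
  }
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    for (k in seq_len(nrow(edges))) g <- add_edge(g, edges[k, 1], edges[k, 2])
  }
  g
}

as_bn_graph <- function(amat, nodes = rownames(amat)) {
  structure(list(nodes = nodes,
                 amat = matrix(as.integer(amat), nrow(amat), ncol(amat),
                               dimnames = list(nodes, nodes))),
            class = "bn_graph")
}

node_index <- function(g, node) {
  i <- match(node, g$nodes)
  if (anyNA(i)) stop("unknown node(s): ", paste(node[is.na(i)], collapse = ", "))
  i
}

#' @export
print.bn_graph <- function(x, ...) {
  a <- arcs(x)
  e <- undirected_edges(x)
  cat("bn_graph with", length(x$nodes), "nodes,", nrow(a), "directed arcs,",
      nrow(e), "undirected edges\n")
  if (nrow(a) > 0)
    cat(paste0("  ", a[, 1], " -> ", a[, 2], collapse = "\n"), "\n")
  if (nrow(e) > 0)
    cat(paste0("  ", e[, 1], " -- ", e[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Add a directed arc to a graph
#' @param g a `bn_graph`.
#' @param from,to node names.
#' @export
add_arc <- function(g, from, to) {
  i <- node_index(g, from); j <- node_index(g, to)
  if (i == j) stop("self-loops are not allowed: ", from)
  if (g$amat[j, i] == 1L && g$amat[i, j] == 0L)
    stop("arc ", to, " -> ", from, " already present; remove it first")
  g$amat[i, j] <- 1L
  g$amat[j, i] <- 0L
  g
}

#' Add an undirected edge to a graph
#' @inheritParams add_arc
#' @export
add_edge <- function(g, from, to) {
  i <- node_index(g, from); j <- node_index(g, to)
  if (i == j) stop("self-loops are not allowed: ", from)
  g$amat[i, j] <- 1L
  g$amat[j, i] <- 1L
  g
}

#' Directed arcs of a graph
#'
#' @param g a `bn_graph`.
#' @return two-column character matrix (`from`, `to`), ordered
#'   lexicographically for reproducible output.
#' @export
arcs <- function(g) {
  idx <- which(g$amat == 1L & t(g$amat) == 0L, arr.ind = TRUE)
  out <- cbind(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Undirected edges of a graph
#'
#' @param g a `bn_graph`.
#' @return two-column character matrix, each unordered pair listed once
#'   (lexicographically smaller node first).
#' @export
undirected_edges <- function(g) {
  idx <- which(g$amat == 1L & t(g$amat) == 1L, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  out <- cbind(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Number of parents per node (directed arcs only)
#' @param g a `bn_graph`.
#' @export
parents_of <- function(g, node) {
  j <- node_index(g, node)
  g$nodes[g$amat[, j] == 1L & g$amat[j, ] == 0L]
}

directed_amat <- function(g) {
  a <- g$amat
  und <- a == 1L & t(a) == 1L
  a[und] <- 0L
  a
}

#' Test whether the directed part of a graph is acyclic
#' @param g a `bn_graph`.
#' @export
is_acyclic <- function(g) {
  a <- directed_amat(g)
  p <- nrow(a)
  if (p == 0) return(TRUE)
  # repeatedly strip sink-free reduction via topological peeling
  remaining <- rep(TRUE, p)
  indeg <- colSums(a)
  repeat {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0) break
    for (v in src) {
      remaining[v] <- FALSE
      ch <- which(a[v, ] == 1L)
      indeg[ch] <- indeg[ch] - 1L
    }
  }
  !any(remaining)
}

#' Would adding an arc create a directed cycle?
#'
#' Returns `TRUE` iff a directed path from `to` back to `from` already
#' exists among the directed arcs (undirected edges are ignored), or the
#' candidate is a self-loop.
#'
#' @param g a `bn_graph`.
#' @param from,to endpoints of the candidate arc `from -> to`.
#' @export
cycle_check <- function(g, from, to) {
  i <- node_index(g, from); j <- node_index(g, to)
  if (i == j) return(TRUE)
  cpp_path_exists(directed_amat(g), j - 1L, i - 1L)
}

#' Topological order of a DAG
#' @param g an acyclic `bn_graph` (directed arcs only).
#' @return node names in an order where every parent precedes its children.
#' @export
topological_order <- function(g) {
  a <- directed_amat(g)
  p <- nrow(a)
  indeg <- colSums(a)
  remaining <- rep(TRUE, p)
  ord <- integer(0)
  while (length(ord) < p) {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0) stop("graph is cyclic; no topological order")
    v <- src[1]
    ord <- c(ord, v)
    remaining[v] <- FALSE
    ch <- which(a[v, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
    indeg[v] <- NA_integer_
  }
  g$nodes[ord]
}

# v-structures (unshielded colliders) i -> k <- j with i, j non-adjacent;
# returns matrix with columns (i, k, j), i < j, as node indices.
find_v_structures <- function(amat) {
  p <- nrow(amat)
  out <- matrix(integer(0), 0, 3)
  dir <- amat == 1L & t(amat) == 0L
  adj <- amat == 1L | t(amat) == 1L
  for (k in seq_len(p)) {
    pa <- which(dir[, k])
    if (length(pa) < 2) next
    for (a in pa) for (b in pa) {
      if (a < b && !adj[a, b]) out <- rbind(out, c(a, k, b))
    }
  }
  out
}

# Orientation propagation on a partially directed graph (Meek's rules
# R1-R3), applied to fixpoint. amat codes: arc = (1,0), edge = (1,1).
meek_orient <- function(amat, forbid = NULL) {
  p <- nrow(amat)
  if (is.null(forbid)) forbid <- matrix(0L, p, p)
  can_orient <- function(i, j) {
    # orienting i -> j must not be blacklisted and not create a cycle
    if (forbid[i, j] == 1L) return(FALSE)
    tmp <- amat
    tmp[i, j] <- 1L; tmp[j, i] <- 0L
    und <- tmp == 1L & t(tmp) == 1L
    tmp[und] <- 0L
    !cpp_path_exists(tmp, j - 1L, i - 1L)
  }
  repeat {
    changed <- FALSE
    dir <- amat == 1L & t(amat) == 0L
    und <- amat == 1L & t(amat) == 1L
    adj <- amat == 1L | t(amat) == 1L
    for (b in seq_len(p)) for (c in seq_len(p)) {
      if (!und[b, c]) next
      oriented <- FALSE
      # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
      for (a in which(dir[, b])) {
        if (a != c && !adj[a, c] && can_orient(b, c)) {
          amat[b, c] <- 1L; amat[c, b] <- 0L
          changed <- TRUE; oriented <- TRUE; break
        }
      }
      if (oriented) next
      # R2: b -> a -> c and b - c  =>  b -> c
      for (a in which(dir[b, ])) {
        if (dir[a, c] && can_orient(b, c)) {
          amat[b, c] <- 1L; amat[c, b] <- 0L
          changed <- TRUE; oriented <- TRUE; break
        }
      }
      if (oriented) next
      # R3: b - a1, b - a2, a1 -> c, a2 -> c, a1, a2 non-adjacent  =>  b -> c
      cand <- which(und[b, ] & dir[, c])
      if (length(cand) >= 2) {
        for (a1 in cand) for (a2 in cand) {
          if (a1 < a2 && !adj[a1, a2] && can_orient(b, c)) {
            amat[b, c] <- 1L; amat[c, b] <- 0L
            changed <- TRUE; oriented <- TRUE
            break
          }
        }
      }
    }
    if (!changed) break
  }
  amat
}

#' Completed partially directed acyclic graph (CPDAG) of a DAG
#'
#' Collapses a DAG to its Markov equivalence class: compelled arcs (those
#' shared by every DAG with the same skeleton and v-structures) stay
#' directed, reversible arcs become undirected. Computed by keeping the
#' v-structure orientations and propagating with Meek's rules.
#'
#' @param g an acyclic, fully directed `bn_graph`.
#' @return a `bn_graph` possibly containing undirected edges.
#' @export
to_cpdag <- function(g) {
  if (nrow(undirected_edges(g)) > 0)
    stop("to_cpdag() expects a fully directed graph")
  if (!is_acyclic(g)) stop("to_cpdag() expects an acyclic graph")
  a <- g$amat
  skel <- matrix(0L, nrow(a), ncol(a), dimnames = dimnames(a))
  skel[a == 1L | t(a) == 1L] <- 1L  # all edges undirected
  vs <- find_v_structures(a)
  if (nrow(vs) > 0) {
    for (k in seq_len(nrow(vs))) {
      i <- vs[k, 1]; c <- vs[k, 2]; j <- vs[k, 3]
      skel[i, c] <- 1L; skel[c, i] <- 0L
      skel[j, c] <- 1L; skel[c, j] <- 0L
    }
  }
  as_bn_graph(meek_orient(skel), g$nodes)
}
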