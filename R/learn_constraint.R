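# Constraint-based structure learning: PC-stable and the Markov-blanket
# family (GS, IAMB, IAMB-FDR). All tests are exact-t tests on partial
# correlations computed from the moment matrix.

ci_pvalue <- function(S, n, x, y, Z) {
  cpp_pcor_test(S, n, x - 1L, y - 1L, as.integer(Z) - 1L)$p
}

# subsets of `set` with exactly `size` elements; deterministic order.
# (combn() expands a scalar set to seq_len(), hence the guard.)
subsets_of_size <- function(set, size) {
  if (size == 0) return(list(integer(0)))
  if (length(set) < size) return(list())
  if (length(set) == size) return(list(set))
  cm <- utils::combn(set, size)
  lapply(seq_len(ncol(cm)), function(k) cm[, k])
}

# search for a separating set for (x, y) among subsets (size <= max_sepset)
# of the adjacency sets of x and of y; returns NULL or the subset found
find_sepset <- function(S, n, x, y, adj_x, adj_y, alpha, max_sepset) {
  pools <- list(setdiff(adj_x, y), setdiff(adj_y, x))
  tried <- character(0)
  for (pool in pools) {
    for (sz in 0:min(max_sepset, length(pool))) {
      for (Z in subsets_of_size(pool, sz)) {
        key <- paste(sort(Z), collapse = ",")
        if (key %in% tried) next
        tried <- c(tried, key)
        if (n - sz - 2 < 1) next
        if (ci_pvalue(S, n, x, y, Z) > alpha) return(Z)
      }
    }
  }
  NULL
}

# orientation phase shared by the constraint-based algorithms:
# adjacency matrix -> partially directed graph via whitelist arcs,
# v-structures (collider rule on unshielded triples) and Meek propagation.
# sepset_lookup(i, j) must return the separating set (or NULL to trigger
# a search).
orient_skeleton <- function(S, n, adj, blm, wlm, alpha, max_sepset,
                            sepset_lookup = NULL) {
  p <- nrow(adj)
  amat <- matrix(0L, p, p)
  amat[adj] <- 1L
  amat[t(adj)] <- 1L  # symmetric: all edges undirected initially
  # whitelist arcs are fixed, directed
  wl_idx <- which(wlm == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(wl_idx))) {
    i <- wl_idx[k, 1]; j <- wl_idx[k, 2]
    amat[i, j] <- 1L
    if (wlm[j, i] == 0L) amat[j, i] <- 0L
  }
  adj_full <- amat == 1L | t(amat) == 1L
  get_sepset <- function(i, j) {
    if (!is.null(sepset_lookup)) {
      s <- sepset_lookup(i, j)
      if (!is.null(s)) return(s)
    }
    find_sepset(S, n, i, j, which(adj_full[i, ]), which(adj_full[j, ]),
                alpha, max_sepset)
  }
  # v-structures: unshielded triples i - k - j with i, j non-adjacent and
  # k outside their separating set
  for (k in seq_len(p)) {
    nb <- which(adj_full[k, ])
    if (length(nb) < 2) next
    for (i in nb) for (j in nb) {
      if (i >= j || adj_full[i, j]) next
      sep <- get_sepset(i, j)
      if (is.null(sep) || k %in% sep) next
      # orient i -> k and j -> k where constraints permit and no prior
      # opposite orientation exists
      for (a in c(i, j)) {
        if (blm[a, k] == 1L) next          # forbidden orientation
        if (wlm[k, a] == 1L) next          # fixed opposite arc
        if (amat[k, a] == 1L && amat[a, k] == 0L) next # already k -> a
        amat[a, k] <- 1L
        amat[k, a] <- 0L
      }
    }
  }
  meek_orient(amat, forbid = blm)
}

# ---- PC-stable ------------------------------------------------------------

pc_stable_backend <- function(S, n, cfg, blm, wlm) {
  p <- nrow(S)
  alpha <- cfg$alpha
  wpair <- wlm == 1L | t(wlm) == 1L
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  adj[blm == 1L & t(blm) == 1L & !wpair] <- FALSE
  sepsets <- vector("list", p * p)
  key <- function(i, j) (min(i, j) - 1L) * p + max(i, j)
  l <- 0L
  repeat {
    snapshot <- adj  # adjacency sets frozen for this level (the "stable" fix)
    any_pool <- FALSE
    for (i in seq_len(p)) {
      for (j in which(snapshot[i, ])) {
        if (!adj[i, j] || wpair[i, j]) next
        pool <- setdiff(which(snapshot[i, ]), j)
        if (length(pool) < l) next
        any_pool <- TRUE
        if (n - l - 2 < 1) next
        for (Z in subsets_of_size(pool, l)) {
          if (ci_pvalue(S, n, i, j, Z) > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepsets[[key(i, j)]] <- Z
            break
          }
        }
      }
    }
    l <- l + 1L
    if (!any_pool || l > cfg$max_sepset) break
  }
  orient_skeleton(S, n, adj, blm, wlm, alpha, cfg$max_sepset,
                  sepset_lookup = function(i, j) sepsets[[key(i, j)]])
}

# ---- Markov-blanket family ------------------------------------------------

# grow-shrink style Markov-blanket discovery for one target
learn_mb <- function(S, n, y, p, alpha, variant) {
  mb <- integer(0)
  cand <- setdiff(seq_len(p), y)
  # grow
  repeat {
    pool <- setdiff(cand, mb)
    pool <- pool[n - length(mb) - 2 >= 1]
    if (length(pool) == 0) break
    pv <- vapply(pool, function(x) ci_pvalue(S, n, x, y, mb), numeric(1))
    added <- FALSE
    if (variant == "gs") {
      hit <- which(pv < alpha)
      if (length(hit) > 0) {
        mb <- c(mb, pool[hit[1]])  # first admissible, fixed order
        added <- TRUE
      }
    } else if (variant == "iamb") {
      best <- which.min(pv)
      if (pv[best] < alpha) {
        mb <- c(mb, pool[best])
        added <- TRUE
      }
    } else { # iamb_fdr: admit against a Benjamini-Hochberg-adjusted level
      padj <- stats::p.adjust(pv, method = "BH")
      best <- which.min(padj)
      if (padj[best] < alpha) {
        mb <- c(mb, pool[best])
        added <- TRUE
      }
    }
    if (!added) break
  }
  # shrink
  repeat {
    removed <- FALSE
    for (x in mb) {
      Z <- setdiff(mb, x)
      if (n - length(Z) - 2 < 1) next
      if (ci_pvalue(S, n, x, y, Z) > alpha) {
        mb <- setdiff(mb, x)
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  sort(mb)
}

mb_backend <- function(S, n, cfg, blm, wlm, variant) {
  p <- nrow(S)
  alpha <- cfg$alpha
  mbs <- lapply(seq_len(p), function(y) learn_mb(S, n, y, p, alpha, variant))
  # neighbours: x ~ y iff no subset of the smaller of MB(y)\{x}, MB(x)\{y}
  # separates them
  nb <- matrix(FALSE, p, p)
  for (y in seq_len(p)) {
    for (x in mbs[[y]]) {
      d1 <- setdiff(mbs[[y]], x)
      d2 <- setdiff(mbs[[x]], y)
      D <- if (length(d1) <= length(d2)) d1 else d2
      wp <- cpp_worst_pvalue(S, n, x - 1L, y - 1L, as.integer(D) - 1L,
                             as.integer(min(cfg$max_sepset, length(D))),
                             alpha)
      if (wp <= alpha) nb[x, y] <- TRUE
    }
  }
  adj <- nb & t(nb)  # AND symmetrization
  wpair <- wlm == 1L | t(wlm) == 1L
  adj[wpair] <- TRUE
  adj[blm == 1L & t(blm) == 1L & !wpair] <- FALSE
  diag(adj) <- FALSE
  orient_skeleton(S, n, adj, blm, wlm, alpha, cfg$max_sepset)
}
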