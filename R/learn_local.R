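# Local discovery of undirected parent-children graphs: MMPC (max-min
# parents and children) and SI-HITON-PC. Both return a symmetric (AND-rule)
# adjacency coded as undirected edges; orientation is left to the hybrid
# searchers or to the ensemble consensus.

# max-p of x _||_ y | Z over subsets Z of cpc (the "min association")
worst_p <- function(S, n, x, y, cpc, max_sepset, alpha) {
  cpp_worst_pvalue(S, n, x - 1L, y - 1L, as.integer(cpc) - 1L,
                   as.integer(min(max_sepset, length(cpc))), alpha)
}

mmpc_target <- function(S, n, y, p, alpha, max_sepset, forced, excluded) {
  cpc <- forced
  alive <- setdiff(seq_len(p), c(y, cpc, excluded))
  # forward: admit the candidate with the strongest minimum association
  repeat {
    if (length(alive) == 0) break
    wp <- vapply(alive, function(x)
      worst_p(S, n, x, y, cpc, max_sepset, alpha), numeric(1))
    alive <- alive[wp <= alpha]  # separable candidates drop out for good
    wp <- wp[wp <= alpha]
    if (length(alive) == 0) break
    pick <- which.min(wp)  # ties resolve to the lowest index (fixed order)
    cpc <- c(cpc, alive[pick])
    alive <- alive[-pick]
  }
  # backward: remove members separable given the rest
  for (x in setdiff(cpc, forced)) {
    if (worst_p(S, n, x, y, setdiff(cpc, x), max_sepset, alpha) > alpha)
      cpc <- setdiff(cpc, x)
  }
  sort(cpc)
}

hiton_target <- function(S, n, y, p, alpha, max_sepset, forced, excluded) {
  cand <- setdiff(seq_len(p), c(y, forced, excluded))
  marg <- vapply(cand, function(x) ci_pvalue(S, n, x, y, integer(0)),
                 numeric(1))
  cand <- cand[marg < alpha]
  marg <- marg[marg < alpha]
  cand <- cand[order(marg, cand)]  # strongest marginal association first
  cpc <- forced
  for (x in cand) {
    cpc <- c(cpc, x)
    # interleaved elimination after each inclusion
    repeat {
      dropped <- FALSE
      for (z in setdiff(cpc, forced)) {
        if (worst_p(S, n, z, y, setdiff(cpc, z), max_sepset, alpha) > alpha) {
          cpc <- setdiff(cpc, z)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }
  sort(cpc)
}

local_backend <- function(S, n, cfg, blm, wlm, variant) {
  p <- nrow(S)
  wpair <- wlm == 1L | t(wlm) == 1L
  bpair <- blm == 1L & t(blm) == 1L & !wpair  # pair fully forbidden
  target_fun <- if (variant == "mmpc") mmpc_target else hiton_target
  nb <- matrix(FALSE, p, p)
  for (y in seq_len(p)) {
    forced <- which(wpair[, y])
    excluded <- which(bpair[, y])
    cpc <- target_fun(S, n, y, p, cfg$alpha, cfg$max_sepset, forced, excluded)
    nb[cpc, y] <- TRUE
  }
  adj <- (nb & t(nb)) | wpair  # AND rule; whitelisted pairs always adjacent
  diag(adj) <- FALSE
  amat <- matrix(0L, p, p)
  amat[adj] <- 1L
  amat[t(adj)] <- 1L  # undirected output
  amat
}
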