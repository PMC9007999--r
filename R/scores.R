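#' @useDynLib consensusbn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# MLE covariance matrix (cross-products / n) with names; the moment matrix
# all Gaussian tests and scores are computed from.
mle_cov <- function(data) {
  m <- as_feature_matrix(data)
  n <- nrow(m)
  ctr <- scale(m, center = TRUE, scale = FALSE)
  S <- crossprod(ctr) / n
  dimnames(S) <- list(colnames(m), colnames(m))
  S
}

check_constant <- function(data, cols) {
  m <- as_feature_matrix(data)
  bad <- cols[vapply(cols, function(f) stats::var(m[, f]) == 0, logical(1))]
  if (length(bad) > 0)
    stop("constant column(s) in test/score design: ",
         paste(bad, collapse = ", "))
}

#' Partial correlation given a conditioning set
#'
#' The Pearson correlation of the residuals of `x` and `y` after
#' least-squares projection (with intercept) onto the columns in `z`.
#' With `z` empty this is the plain Pearson correlation.
#'
#' @param x,y feature names.
#' @param z character vector of conditioning features (may be empty).
#' @param data a [feature_table()], matrix, or data.frame.
#' @return the partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z = character(0), data) {
  m <- as_feature_matrix(data)
  miss <- setdiff(c(x, y, z), colnames(m))
  if (length(miss) > 0) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  if (nrow(m) <= length(z) + 2)
    stop("need n_obs > |Z| + 2 observations")
  check_constant(m, c(x, y))
  S <- mle_cov(m)
  idx <- function(f) match(f, colnames(m)) - 1L
  res <- tryCatch(
    cpp_pcor_test(S, nrow(m), idx(x), idx(y), vapply(z, idx, integer(1))),
    error = function(e) stop("singular conditioning design; collinear ",
                             "columns among: ", paste(z, collapse = ", "),
                             call. = FALSE))
  res$r
}

#' Two-sided p-value of the exact t-test for a correlation coefficient
#'
#' `t = r * sqrt(df) / sqrt(1 - r^2)` with `df = n_obs - cond_size - 2`,
#' referred to a Student-t distribution. `r = +/-1` underflows to the
#' smallest positive double rather than returning 0.
#'
#' @param r (partial) correlation.
#' @param n_obs number of observations.
#' @param cond_size size of the conditioning set.
#' @export
exact_t_pvalue <- function(r, n_obs, cond_size = 0) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (n_obs - cond_size - 2 < 1)
    stop("degrees of freedom n_obs - cond_size - 2 must be >= 1")
  cpp_exact_t_pvalue(r, n_obs, as.integer(cond_size))
}

#' Gaussian network score of a node given a parent set
#'
#' The decomposable score driving score-based search: the profiled Gaussian
#' log-likelihood of `node | parents` minus the BIC penalty
#' `(k / 2) * log(n_obs)` with `k = |parents| + 2` (intercept and residual
#' variance). Higher is better; the score of a network is the sum over its
#' nodes. The residual variance is floored at 1e-12 so noiseless synthetic
#' data cannot produce infinite likelihoods.
#'
#' @param node feature name.
#' @param parents character vector of parent features (may be empty).
#' @param data a [feature_table()], matrix, or data.frame.
#' @export
gaussian_score <- function(node, parents = character(0), data) {
  m <- as_feature_matrix(data)
  miss <- setdiff(c(node, parents), colnames(m))
  if (length(miss) > 0) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  S <- mle_cov(m)
  idx <- function(f) match(f, colnames(m)) - 1L
  s <- cpp_node_score(S, nrow(m), idx(node),
                      vapply(parents, idx, integer(1)))
  if (!is.finite(s)) stop("singular design for node '", node, "' with ",
                          "parents: ", paste(parents, collapse = ", "))
  s
}

#' Node-level L1 Bayesian information criterion
#'
#' The complexity / accuracy trade-off used to select the consensus
#' whitelist: `BIC_j = n_arcs * log10(n_obs) + sum_i |Yhat_ij - Y_ij|`,
#' where `Yhat` is the least-squares linear-Gaussian prediction of node `j`
#' from its parents (the sample mean when the parent set is empty),
#' `n_arcs` the number of parental arcs and `n_obs` the number of samples.
#' Lower is better; the L1 loss rewards fit while each extra parent costs
#' `log10(n_obs)`.
#'
#' @inheritParams gaussian_score
#' @return a one-row data.frame (`node`, `n_arcs`, `n_obs`, `l1_loss`,
#'   `bic`) with the parent set in the `parents` attribute.
#' @export
node_l1_bic <- function(node, parents = character(0), data) {
  m <- as_feature_matrix(data)
  miss <- setdiff(c(node, parents), colnames(m))
  if (length(miss) > 0) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  y <- m[, node]
  n <- length(y)
  if (length(parents) == 0) {
    yhat <- rep(mean(y), n)
  } else {
    X <- cbind(1, m[, parents, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X))
      stop("singular design: collinear parents among ",
           paste(parents, collapse = ", "))
    yhat <- fit$fitted.values
  }
  l1 <- sum(abs(yhat - y))
  out <- data.frame(node = node, n_arcs = length(parents), n_obs = n,
                    l1_loss = l1,
                    bic = length(parents) * log10(n) + l1)
  attr(out, "parents") <- parents
  out
}

#' Significance of an arc within a network
#'
#' The "edge strength" diagnostic: the partial correlation between the two
#' endpoints of an arc given the rest of the network - operationally, given
#' the child's other parents - with its exact-t p-value.
#'
#' @param dag a `bn_graph` containing the arc.
#' @param arc length-2 character vector `c(from, to)`.
#' @param data a [feature_table()], matrix, or data.frame.
#' @return a one-row data.frame (`from`, `to`, `r`, `cond_size`, `n_obs`,
#'   `p_value`).
#' @export
arc_significance <- function(dag, arc, data) {
  from <- arc[1]; to <- arc[2]
  a <- arcs(dag)
  if (!any(a[, 1] == from & a[, 2] == to))
    stop("arc ", from, " -> ", to, " is not in the graph")
  z <- setdiff(parents_of(dag, to), from)
  m <- as_feature_matrix(data)
  r <- partial_correlation(from, to, z, m)
  p <- exact_t_pvalue(r, nrow(m), length(z))
  data.frame(from = from, to = to, r = r, cond_size = length(z),
             n_obs = nrow(m), p_value = p)
}
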