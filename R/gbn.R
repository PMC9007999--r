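# Linear-Gaussian Bayesian networks on a fixed DAG: maximum-likelihood fit,
# forward (logic) sampling, conditional-probability queries by rejection
# filtering, and quantile contrasts.

SD_FLOOR <- 1e-12

#' Fit a linear-Gaussian model to a DAG by maximum likelihood
#'
#' Every node is modelled as Gaussian with mean linear in its parents:
#' ordinary least squares of the node on its parents with intercept, and
#' residual standard deviation estimated by maximum likelihood (divide by
#' n). The intercept is the average value of the node with all parental
#' values set to zero; the sign of each coefficient says whether a parent
#' promotes (positive) or inhibits (negative) the node. Root nodes get
#' their sample mean and population standard deviation. Binary sample
#' attributes (declared `attribute01` in a [feature_table()]) that are
#' roots are modelled as Bernoulli with their empirical frequency, so that
#' sampling reproduces their two-point mass.
#'
#' @param dag an acyclic, fully directed `bn_graph`.
#' @param data a [feature_table()] (attribute columns honored), matrix, or
#'   data.frame; must contain every node of `dag`.
#' @return a `fitted_network`: the DAG plus one conditional distribution
#'   per node.
#' @export
fit_linear_gaussian <- function(dag, data) {
  if (!is_acyclic(dag)) stop("the graph must be acyclic")
  if (nrow(undirected_edges(dag)) > 0)
    stop("the graph must be fully directed")
  m <- as_feature_matrix(data)
  miss <- setdiff(dag$nodes, colnames(m))
  if (length(miss) > 0)
    stop("data lacks node(s): ", paste(miss, collapse = ", "))
  kind <- if (inherits(data, "feature_table")) data$column_kind else
    stats::setNames(rep("continuous", ncol(m)), colnames(m))
  n <- nrow(m)
  cpds <- list()
  for (nd in dag$nodes) {
    pa <- parents_of(dag, nd)
    if (length(pa) == 0 && identical(unname(kind[nd]), "attribute01")) {
      cpds[[nd]] <- list(node = nd, parents = character(0),
                         type = "bernoulli", prob = mean(m[, nd]))
      next
    }
    if (length(pa) == 0) {
      cpds[[nd]] <- list(node = nd, parents = character(0),
                         type = "gaussian", intercept = mean(m[, nd]),
                         coefficients = numeric(0),
                         sd = max(stats::sd(m[, nd]) * sqrt((n - 1) / n),
                                  SD_FLOOR))
      next
    }
    X <- cbind(`(Intercept)` = 1, m[, pa, drop = FALSE])
    fit <- stats::lm.fit(X, m[, nd])
    if (fit$rank < ncol(X))
      stop("singular design for node '", nd, "': collinear parents among ",
           paste(pa, collapse = ", "))
    sd_mle <- sqrt(sum(fit$residuals^2) / n)
    cpds[[nd]] <- list(node = nd, parents = pa, type = "gaussian",
                       intercept = unname(fit$coefficients[1]),
                       coefficients = fit$coefficients[-1],
                       sd = max(sd_mle, SD_FLOOR))
  }
  structure(list(dag = dag, cpds = cpds, n_obs = n), class = "fitted_network")
}

#' @export
print.fitted_network <- function(x, ...) {
  cat("fitted_network:", length(x$dag$nodes), "nodes,",
      nrow(arcs(x$dag)), "arcs, fit on", x$n_obs, "samples\n")
  invisible(x)
}

#' Forward ("logic") sampling of a fitted network
#'
#' Draws joint samples by ancestral sampling in topological order: roots
#' from their marginal (Bernoulli for binary attributes, Gaussian
#' otherwise), children from their linear-Gaussian conditionals given the
#' already-sampled parents. The sample table is deterministic given the
#' seed.
#'
#' @param net a `fitted_network`.
#' @param n number of samples (default 1e5).
#' @param seed integer seed.
#' @return a data.frame of `n` joint samples (one column per node).
#' @export
logic_sample <- function(net, n = 1e5, seed = 1) {
  stopifnot(inherits(net, "fitted_network"), n >= 1)
  ord <- topological_order(net$dag)
  out <- matrix(NA_real_, n, length(ord), dimnames = list(NULL, ord))
  with_local_seed(seed, function() {
    for (nd in ord) {
      cpd <- net$cpds[[nd]]
      if (cpd$type == "bernoulli") {
        out[, nd] <<- stats::rbinom(n, 1, cpd$prob)
      } else {
        mu <- rep(cpd$intercept, n)
        if (length(cpd$parents) > 0)
          mu <- mu + out[, cpd$parents, drop = FALSE] %*% cpd$coefficients
        noise <- if (cpd$sd > SD_FLOOR) stats::rnorm(n, 0, cpd$sd) else 0
        out[, nd] <<- mu + noise
      }
    }
  })
  as.data.frame(out)
}

#' Specification of a conditional-probability query
#'
#' @param evidence character vector of predicates such as
#'   `"Cancer < 0.05"` or `"Cancer > 0.95"`; supported comparators are
#'   `<`, `<=`, `>`, `>=`, `==`.
#' @param report features to summarize (default: all non-evidence nodes).
#' @param trend optional feature (e.g. the oncogene) against which a
#'   least-squares trend slope is computed for every report feature.
#' @param n_samples number of logic samples (default 1e5).
#' @export
query_spec <- function(evidence = character(0), report = NULL, trend = NULL,
                       n_samples = 1e5) {
  stopifnot(n_samples >= 1)
  parsed <- lapply(evidence, function(e) {
    mt <- regmatches(e, regexec(
      "^\\s*([^<>=!\\s]+)\\s*(<=|>=|==|<|>)\\s*([-+0-9.eE]+)\\s*$", e,
      perl = TRUE))[[1]]
    if (length(mt) != 4) stop("cannot parse evidence predicate: '", e, "'")
    list(feature = mt[2], op = mt[3], bound = as.numeric(mt[4]))
  })
  structure(list(evidence = parsed, report = report, trend = trend,
                 n_samples = n_samples), class = "query_spec")
}

#' Conditional-probability query by logic sampling
#'
#' Draws `n_samples` joint samples, filters them by all evidence
#' predicates (rejection sampling), and summarizes the survivors: mean and
#' standard deviation of each report feature, plus - when a trend feature
#' is given - the least-squares slope of each report feature against it,
#' computed both on the conditional survivors and on the unconditional
#' samples.
#'
#' @param net a `fitted_network`.
#' @param spec a [query_spec()].
#' @param seed integer seed.
#' @return list with `summary` (data.frame), `n_survivors`, and
#'   `samples` (the filtered sample table).
#' @export
conditional_query <- function(net, spec, seed = 1) {
  stopifnot(inherits(net, "fitted_network"), inherits(spec, "query_spec"))
  for (pr in spec$evidence) {
    if (!pr$feature %in% net$dag$nodes)
      stop("evidence references unknown node: ", pr$feature)
  }
  samples <- logic_sample(net, spec$n_samples, seed)
  keep <- rep(TRUE, nrow(samples))
  for (pr in spec$evidence) {
    x <- samples[[pr$feature]]
    keep <- keep & switch(pr$op,
                          "<" = x < pr$bound, "<=" = x <= pr$bound,
                          ">" = x > pr$bound, ">=" = x >= pr$bound,
                          "==" = x == pr$bound)
  }
  surv <- samples[keep, , drop = FALSE]
  if (nrow(surv) == 0)
    stop("no samples satisfy the evidence; the query has empty support")
  if (nrow(surv) < 100)
    warning("only ", nrow(surv), " samples satisfy the evidence; ",
            "summaries are unreliable")
  ev_feats <- vapply(spec$evidence, `[[`, character(1), "feature")
  report <- spec$report
  if (is.null(report)) report <- setdiff(net$dag$nodes, ev_feats)
  summ <- data.frame(feature = report,
                     mean = vapply(report, function(f) mean(surv[[f]]),
                                   numeric(1)),
                     sd = vapply(report, function(f) stats::sd(surv[[f]]),
                                 numeric(1)),
                     row.names = NULL)
  if (!is.null(spec$trend)) {
    slope <- function(df, f) {
      if (f == spec$trend) return(NA_real_)
      unname(stats::coef(stats::lm.fit(
        cbind(1, df[[spec$trend]]), df[[f]]))[2])
    }
    summ$trend_slope_conditional <- vapply(report, slope, numeric(1),
                                           df = surv)
    summ$trend_slope_unconditional <- vapply(report, slope, numeric(1),
                                             df = samples)
  }
  list(summary = summ, n_survivors = nrow(surv), samples = surv)
}

#' Contrast the extreme quantiles of a key feature
#'
#' Splits the samples into `n_quantiles` rank-based groups of near-equal
#' size (ties broken by stable sample order) along `key_feature`, and
#' reports for each feature the difference in means between the top and the
#' bottom group. With the oncogene as key, the bottom quantile mimics a
#' knock-out and the top quantile a wild-type population, so the difference
#' predicts the change in cell-type abundance attributable to oncogene
#' expression.
#'
#' @param data a [feature_table()], matrix, or data.frame.
#' @param key_feature the feature defining the quantiles.
#' @param n_quantiles number of groups (default 5).
#' @param report_features features to contrast (default: all others).
#' @return data.frame with `feature`, `delta` (top mean minus bottom mean),
#'   `mean_bottom`, `mean_top`, `n_bottom`, `n_top`.
#' @export
quantile_contrast <- function(data, key_feature, n_quantiles = 5,
                              report_features = NULL) {
  m <- as_feature_matrix(data)
  if (!key_feature %in% colnames(m)) stop("unknown feature: ", key_feature)
  if (n_quantiles < 2) stop("n_quantiles must be >= 2")
  key <- m[, key_feature]
  if (length(unique(key)) < 2)
    stop("all values of '", key_feature, "' are identical")
  n <- length(key)
  ord <- order(key)  # stable: ties keep sample order
  sizes <- diff(round(seq(0, n, length.out = n_quantiles + 1)))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_quantiles), times = sizes)
  if (is.null(report_features))
    report_features <- setdiff(colnames(m), key_feature)
  bot <- grp == 1L
  top <- grp == n_quantiles
  data.frame(
    feature = report_features,
    delta = vapply(report_features, function(f)
      mean(m[top, f]) - mean(m[bot, f]), numeric(1)),
    mean_bottom = vapply(report_features, function(f) mean(m[bot, f]),
                         numeric(1)),
    mean_top = vapply(report_features, function(f) mean(m[top, f]),
                      numeric(1)),
    n_bottom = sum(bot), n_top = sum(top), row.names = NULL)
}

#' Annotate a fitted network with effect sizes and inclusion probabilities
#'
#' Combines the fitted linear-Gaussian parameters with bootstrap arc
#' strengths: every arc is annotated with its coefficient, its effect sign
#' (`promote` / `inhibit`), and its posterior inclusion probability (the
#' bootstrap strength, 1 for whitelisted arcs); every node with its
#' intercept. The annotated graph serializes to JSON, GraphML, or DOT via
#' [write_annotated_network()] and [export_graph()].
#'
#' @param net a `fitted_network`.
#' @param strengths a `boot_strength` table covering every arc of the
#'   network.
#' @return an `annotated_network`: list with `nodes` and `arcs`
#'   data.frames.
#' @export
annotate_network <- function(net, strengths) {
  stopifnot(inherits(net, "fitted_network"))
  a <- arcs(net$dag)
  skey <- paste(pmin(strengths$from, strengths$to),
                pmax(strengths$from, strengths$to), sep = "\r")
  rows <- lapply(seq_len(nrow(a)), function(k) {
    from <- a[k, 1]; to <- a[k, 2]
    ix <- match(paste(min(from, to), max(from, to), sep = "\r"), skey)
    if (is.na(ix))
      stop("no bootstrap strength recorded for arc ", from, " -> ", to)
    coef <- unname(net$cpds[[to]]$coefficients[from])
    data.frame(from = from, to = to, coefficient = coef,
               effect = ifelse(coef >= 0, "promote", "inhibit"),
               inclusion_probability = strengths$strength[ix],
               stringsAsFactors = FALSE)
  })
  arcs_df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(from = character(0), to = character(0),
               coefficient = numeric(0), effect = character(0),
               inclusion_probability = numeric(0))
  nodes_df <- data.frame(
    node = net$dag$nodes,
    intercept = vapply(net$dag$nodes, function(nd) {
      cpd <- net$cpds[[nd]]
      if (cpd$type == "bernoulli") cpd$prob else cpd$intercept
    }, numeric(1)),
    row.names = NULL)
  structure(list(nodes = nodes_df, arcs = arcs_df),
            class = "annotated_network")
}
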