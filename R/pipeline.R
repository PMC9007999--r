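# Whole-workflow orchestration: configuration, the four-step consensus
# pipeline, and the artifact bundle it writes.

# tiny FNV-1a hash of a character scalar, for provenance stamps
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Collects every setting of the four-step workflow. All randomness flows
#' from the seeds recorded here: each ensemble algorithm gets a seed
#' derived deterministically from `ensemble$seed`, and the final learning
#' uses `final$seed`.
#'
#' @param input path to a CSV/TSV feature table, or a [feature_table()] /
#'   matrix directly.
#' @param roles a [node_roles()] object, or a list in config-file form:
#'   `list(root = ..., leaf = ..., quasi_root = list(node = parents))`.
#' @param preprocess a [preprocess_config()]; set to `NULL` if the input is
#'   already normalized.
#' @param ensemble list: `algorithms` (character vector), `n_boot`,
#'   `alpha`, `seed`.
#' @param consensus list: `threshold_grid`, `p_select` (`"min_p"` or
#'   `"max_p"`).
#' @param final list: `algorithm`, `n_boot`, `seed`.
#' @param queries optional named list of [query_spec()]s to run against the
#'   fitted network.
#' @param out_dir optional output directory for the artifact bundle.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input, roles = node_roles(),
                            preprocess = preprocess_config(),
                            ensemble = list(), consensus = list(),
                            final = list(), queries = list(),
                            out_dir = NULL) {
  ens <- utils::modifyList(
    list(algorithms = c("hc", "tabu", "pc_stable", "gs", "iamb", "iamb_fdr",
                        "mmpc", "si_hiton_pc", "mmhc", "rsmax2"),
         n_boot = 10000, alpha = 0.05, seed = 1), ensemble)
  cons <- utils::modifyList(
    list(threshold_grid = 10^seq(-20, -2, length.out = 10),
         p_select = "min_p"), consensus)
  fin <- utils::modifyList(
    list(algorithm = "mmhc", n_boot = 10000, seed = 1), final)
  if (is.list(roles) && !inherits(roles, "node_roles"))
    roles <- node_roles(root = roles$root %||% character(0),
                        leaf = roles$leaf %||% character(0),
                        quasi_root = roles$quasi_root %||% list())
  stopifnot(ens$seed == as.integer(ens$seed), fin$seed == as.integer(fin$seed))
  structure(list(input = input, roles = roles, preprocess = preprocess,
                 ensemble = ens, consensus = cons, final = fin,
                 queries = queries, out_dir = out_dir),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML (or JSON)
#'
#' @param path config file; the structure mirrors the arguments of
#'   [pipeline_config()], with the roles block written as
#'   `roles: {root: [...], leaf: [...], quasi_root: {node: [parents]}}`.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pre <- if (is.null(cfg$preprocess)) preprocess_config() else
    do.call(preprocess_config, cfg$preprocess)
  pipeline_config(input = cfg$input, roles = cfg$roles %||% list(),
                  preprocess = pre, ensemble = cfg$ensemble %||% list(),
                  consensus = cfg$consensus %||% list(),
                  final = cfg$final %||% list(),
                  out_dir = cfg$out_dir)
}

#' Run the four-step consensus workflow
#'
#' Executes, in order: (1) load and preprocess the feature table and build
#' the role-based blacklist; (2) learn an averaged network per ensemble
#' algorithm by bootstrap resampling; (3) aggregate the ensemble into the
#' edge-evidence table, sweep significance thresholds, and select the
#' consensus seed whitelist at the node-level BIC minima with cycle
#' exclusion; (4) final constrained learning (bootstrap + averaging),
#' linear-Gaussian fit, annotation, and any configured conditional
#' queries. Re-running with an identical configuration reproduces the
#' outputs byte for byte.
#'
#' @param cfg a [pipeline_config()] or path to a YAML/JSON config file.
#' @return (invisibly) the artifact bundle: a list with the normalized
#'   table, blacklist, per-algorithm strength tables and averaged
#'   networks, evidence, sweep, whitelist, final strengths and DAG, fitted
#'   and annotated network, query results, and the run log.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- list(config_hash = fnv1a_hash(jsonlite::toJSON(
    list(ensemble = cfg$ensemble, consensus = cfg$consensus,
         final = cfg$final), auto_unbox = TRUE)),
    seeds = list())
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # step 1: features + blacklist
  table <- step("load", {
    if (is.character(cfg$input)) load_feature_table(cfg$input)
    else if (inherits(cfg$input, "feature_table")) cfg$input
    else feature_table(cfg$input)
  })
  norm <- step("preprocess", {
    if (is.null(cfg$preprocess) || isTRUE(table$normalized)) table
    else preprocess_features(table, cfg$preprocess)
  })
  nodes <- norm$feature_names
  bl <- step("blacklist", build_blacklist(nodes, cfg$roles))
  constraints <- constraint_lists(blacklist = bl)

  # step 2: ensemble of averaged networks
  ens <- cfg$ensemble
  strengths <- list()
  averaged <- list()
  step("ensemble", for (k in seq_along(ens$algorithms)) {
    alg <- ens$algorithms[k]
    lc <- learn_config(alg, alpha = ens$alpha)
    sd_k <- derive_seed(ens$seed, k)
    log$seeds[[paste0("ensemble_", alg)]] <- sd_k
    strengths[[alg]] <- bootstrap_arc_strengths(norm, lc, constraints,
                                                n_boot = ens$n_boot,
                                                seed = sd_k)
    averaged[[alg]] <- averaged_network(strengths[[alg]])
  })

  # step 3: consensus seed
  evidence <- step("evidence", aggregate_ensemble(averaged, norm))
  sweep <- step("sweep", sweep_whitelist(
    evidence, norm, constraints,
    threshold_grid = cfg$consensus$threshold_grid,
    p_select = cfg$consensus$p_select,
    cfg = learn_config(cfg$final$algorithm)))
  whitelist <- step("seed", select_consensus_seed(sweep))
  final_constraints <- constraint_lists(blacklist = bl, whitelist = whitelist)

  # step 4: final learning + parameter fit + queries
  log$seeds$final <- cfg$final$seed
  fin <- step("final", final_learning(norm, final_constraints,
                                      n_boot = cfg$final$n_boot,
                                      seed = cfg$final$seed,
                                      cfg = learn_config(cfg$final$algorithm)))
  # the fitted model uses the directed part of the averaged network
  final_dag <- fin$dag
  und <- undirected_edges(final_dag)
  if (nrow(und) > 0) {
    for (k in seq_len(nrow(und)))
      final_dag$amat[node_index(final_dag, und[k, 2]),
                     node_index(final_dag, und[k, 1])] <- 0L
  }
  fitted <- step("fit", fit_linear_gaussian(final_dag, norm))
  annotated <- step("annotate", annotate_network(fitted, fin$strengths))
  query_results <- lapply(cfg$queries, function(qs)
    step("query", conditional_query(fitted, qs, seed = cfg$final$seed)))

  bundle <- list(table = norm, blacklist = bl, strengths = strengths,
                 averaged = averaged, evidence = evidence, sweep = sweep,
                 whitelist = whitelist, final = fin, fitted = fitted,
                 annotated = annotated, queries = query_results,
                 log = log)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  invisible(bundle)
}

# write the 9-file artifact bundle
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)
  write_feature_table(bundle$table, f("normalized_table.csv"))
  utils::write.csv(as.data.frame(bundle$blacklist), f("blacklist.csv"),
                   row.names = FALSE)
  all_str <- do.call(rbind, lapply(bundle$strengths, as.data.frame))
  utils::write.csv(all_str, f("boot_strengths.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$evidence), f("evidence.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$sweep), f("bic_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$whitelist), f("whitelist.csv"),
                   row.names = FALSE)
  export_graph(bundle$final$dag, f("final_dag.graphml"))
  write_annotated_network(bundle$annotated, f("fitted_network.json"))
  jsonlite::write_json(bundle$log, f("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
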