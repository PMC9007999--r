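#' Node role maps encoding prior causal knowledge
#'
#' Roles translate biological prior knowledge into structural constraints:
#' a *root* (e.g. the "Cancer" attribute: oncogenesis causes everything
#' downstream, nothing causes it) admits no incoming arcs; a *leaf* (e.g.
#' "CD8 T cells", or heavily zero-inflated features) admits no outgoing
#' arcs; a *quasi-root* (e.g. the oncogene "CCN4", expressed by malignant
#' cells) admits incoming arcs only from an explicit set of allowed parents
#' (typically the root). All other nodes are *free*.
#'
#' @param root,leaf character vectors of node names (may be empty).
#' @param quasi_root named list: `list(node = c(allowed, parents))`.
#' @return an object of class `node_roles`.
#' @examples
#' node_roles(root = "Cancer", leaf = c("CD8_T_cells", "CD4_T_cells"),
#'            quasi_root = list(CCN4 = "Cancer"))
#' @export
node_roles <- function(root = character(), leaf = character(),
                       quasi_root = list()) {
  root <- as.character(root); leaf <- as.character(leaf)
  if (length(quasi_root) > 0 && is.null(names(quasi_root)))
    stop("quasi_root must be a named list: list(node = allowed_parents)")
  for (q in names(quasi_root)) {
    if (length(quasi_root[[q]]) == 0)
      stop("quasi_root node ", q, " needs a non-empty allowed-parent set")
  }
  all_named <- c(root, leaf, names(quasi_root))
  if (anyDuplicated(all_named))
    stop("each node may carry at most one role; duplicated: ",
         paste(unique(all_named[duplicated(all_named)]), collapse = ", "))
  structure(list(root = root, leaf = leaf, quasi_root = quasi_root),
            class = "node_roles")
}

#' Build the blacklist implied by a role map
#'
#' Applies three rules and returns their union, deduplicated and sorted
#' lexicographically (parent, then child) for byte-reproducible output:
#' * every arc *into* a root is forbidden;
#' * every arc *out of* a leaf is forbidden;
#' * every arc into a quasi-root from outside its allowed-parent set is
#'   forbidden.
#'
#' @param nodes character vector of all node names.
#' @param roles a [node_roles()] object.
#' @return two-column character matrix (`from`, `to`) of forbidden arcs.
#' @export
build_blacklist <- function(nodes, roles) {
  known <- c(roles$root, roles$leaf, names(roles$quasi_root),
             unlist(roles$quasi_root, use.names = FALSE))
  unknown <- setdiff(known, nodes)
  if (length(unknown) > 0)
    stop("role refers to unknown node(s): ", paste(unknown, collapse = ", "))
  from <- character(0); to <- character(0)
  for (r in roles$root) {
    src <- setdiff(nodes, r)
    from <- c(from, src); to <- c(to, rep(r, length(src)))
  }
  for (l in roles$leaf) {
    dst <- setdiff(nodes, l)
    from <- c(from, rep(l, length(dst))); to <- c(to, dst)
  }
  for (q in names(roles$quasi_root)) {
    src <- setdiff(nodes, c(q, roles$quasi_root[[q]]))
    from <- c(from, src); to <- c(to, rep(q, length(src)))
  }
  bl <- unique(cbind(from = from, to = to))
  bl[order(bl[, 1], bl[, 2]), , drop = FALSE]
}

#' Bundle a blacklist and a whitelist, with consistency checks
#'
#' @param blacklist,whitelist two-column character matrices (`from`, `to`);
#'   either may be `NULL` or empty.
#' @param nodes optional node universe for validation.
#' @return an object of class `constraint_lists`.
#' @export
constraint_lists <- function(blacklist = NULL, whitelist = NULL,
                             nodes = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0)
      return(matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to"))))
    x <- as.matrix(x)[, 1:2, drop = FALSE]
    colnames(x) <- c("from", "to")
    x <- unique(x)
    x[order(x[, 1], x[, 2]), , drop = FALSE]
  }
  bl <- norm(blacklist); wl <- norm(whitelist)
  if (!is.null(nodes)) {
    unknown <- setdiff(c(bl, wl), nodes)
    if (length(unknown) > 0)
      stop("constraint refers to unknown node(s): ",
           paste(unknown, collapse = ", "))
  }
  if (nrow(bl) > 0 && nrow(wl) > 0) {
    keys <- function(m) paste(m[, 1], m[, 2], sep = "\r")
    clash <- intersect(keys(bl), keys(wl))
    if (length(clash) > 0)
      stop("arc(s) both blacklisted and whitelisted: ",
           paste(gsub("\r", " -> ", clash), collapse = ", "))
  }
  if (nrow(wl) > 0) {
    keys <- paste(wl[, 1], wl[, 2], sep = "\r")
    rkeys <- paste(wl[, 2], wl[, 1], sep = "\r")
    if (any(keys %in% rkeys))
      stop("whitelist on its own must be acyclic (contains a 2-cycle)")
    g <- bn_graph(unique(c(wl)), arcs = wl)
    if (!is_acyclic(g)) stop("whitelist on its own must be acyclic")
  }
  structure(list(blacklist = bl, whitelist = wl), class = "constraint_lists")
}

# constraint matrices (0/1, p x p) in the node order of `nodes`
constraint_amats <- function(constraints, nodes) {
  p <- length(nodes)
  bl <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  wl <- bl
  if (is.null(constraints)) return(list(bl = bl, wl = wl))
  fill <- function(m, pairs) {
    if (nrow(pairs) > 0) {
      i <- match(pairs[, 1], nodes); j <- match(pairs[, 2], nodes)
      keep <- !is.na(i) & !is.na(j)
      m[cbind(i[keep], j[keep])] <- 1L
    }
    m
  }
  list(bl = fill(bl, constraints$blacklist),
       wl = fill(wl, constraints$whitelist))
}
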