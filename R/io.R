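# File formats: feature tables (CSV/TSV), graph export/import (GraphML,
# DOT, JSON, arc CSV), annotated networks (JSON).

#' Load a feature table from CSV or TSV
#'
#' Expects a header row of feature names with the first column holding
#' sample identifiers. Cells must be numeric; a non-numeric cell aborts
#' with its row and column named. Columns whose values are all in
#' \{0, 1\} are treated as binary sample attributes unless
#' `attribute_cols` overrides the detection.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param attribute_cols optional character vector naming the
#'   `attribute01` columns (disables autodetection).
#' @return a [feature_table()].
#' @export
load_feature_table <- function(path, attribute_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("expected a sample-ID column plus feature columns")
  ids <- as.character(df[[1]])
  feat <- df[, -1, drop = FALSE]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      suppressWarnings(conv <- as.numeric(feat[[j]]))
      bad <- which(is.na(conv) & !is.na(feat[[j]]))
      if (length(bad) > 0)
        stop("non-numeric value '", feat[[j]][bad[1]], "' at row ", bad[1],
             " (sample '", ids[bad[1]], "'), column '", names(feat)[j], "'")
      feat[[j]] <- conv
    }
  }
  m <- as.matrix(feat)
  if (is.null(attribute_cols)) {
    attribute_cols <- colnames(m)[apply(m, 2, function(x)
      all(!is.na(x)) && all(x %in% c(0, 1)))]
  }
  kind <- stats::setNames(
    ifelse(colnames(m) %in% attribute_cols, "attribute01", "continuous"),
    colnames(m))
  feature_table(m, sample_ids = ids, column_kind = kind)
}

#' Write a feature table to CSV
#' @param table a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_ids, table$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

graph_formats <- c("graphml", "dot", "json", "csv_arcs")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a graph to GraphML, DOT, JSON, or arc CSV
#'
#' @param g a `bn_graph`.
#' @param path output path.
#' @param format one of `"graphml"`, `"dot"`, `"json"`, `"csv_arcs"`;
#'   default inferred from the file extension.
#' @return the path, invisibly.
#' @export
export_graph <- function(g, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", dot = "dot", gv = "dot",
                     json = "json", csv = "csv_arcs", ext)
  }
  if (!format %in% graph_formats)
    stop("unknown format '", format, "'; supported: ",
         paste(graph_formats, collapse = ", "))
  a <- arcs(g)
  e <- undirected_edges(g)
  if (format == "graphml") {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="G" edgedefault="directed">',
      paste0('    <node id="', xml_escape(g$nodes), '"/>'),
      if (nrow(a) > 0)
        paste0('    <edge source="', xml_escape(a[, 1]), '" target="',
               xml_escape(a[, 2]), '"/>'),
      if (nrow(e) > 0)
        paste0('    <edge source="', xml_escape(e[, 1]), '" target="',
               xml_escape(e[, 2]), '" directed="false"/>'),
      '  </graph>',
      '</graphml>')
    writeLines(lines, path)
  } else if (format == "dot") {
    lines <- c("digraph G {",
               paste0('  "', g$nodes, '";'),
               if (nrow(a) > 0) paste0('  "', a[, 1], '" -> "', a[, 2], '";'),
               if (nrow(e) > 0) paste0('  "', e[, 1], '" -> "', e[, 2],
                                       '" [dir=none];'),
               "}")
    writeLines(lines, path)
  } else if (format == "json") {
    jsonlite::write_json(
      list(nodes = g$nodes,
           arcs = if (nrow(a) > 0) as.data.frame(a) else list(),
           edges = if (nrow(e) > 0) as.data.frame(e) else list()),
      path, auto_unbox = FALSE, pretty = TRUE)
  } else { # csv_arcs
    df <- rbind(
      if (nrow(a) > 0) data.frame(from = a[, 1], to = a[, 2],
                                  type = "directed"),
      if (nrow(e) > 0) data.frame(from = e[, 1], to = e[, 2],
                                  type = "undirected"))
    if (is.null(df)) df <- data.frame(from = character(0), to = character(0),
                                      type = character(0))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Import a graph written by [export_graph()]
#'
#' @param path input path.
#' @param format one of `"graphml"`, `"dot"`, `"json"`, `"csv_arcs"`;
#'   default inferred from the file extension.
#' @return a `bn_graph`.
#' @export
import_graph <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", dot = "dot", gv = "dot",
                     json = "json", csv = "csv_arcs", ext)
  }
  if (!format %in% graph_formats)
    stop("unknown format '", format, "'; supported: ",
         paste(graph_formats, collapse = ", "))
  if (format == "graphml") {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
    edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
    src <- xml2::xml_attr(edges, "source")
    tgt <- xml2::xml_attr(edges, "target")
    undir <- !is.na(xml2::xml_attr(edges, "directed")) &
      xml2::xml_attr(edges, "directed") == "false"
    bn_graph(nodes,
             arcs = cbind(src[!undir], tgt[!undir]),
             edges = cbind(src[undir], tgt[undir]))
  } else if (format == "dot") {
    lines <- readLines(path)
    nodem <- regmatches(lines, regexec('^\\s*"([^"]+)";\\s*$', lines))
    nodes <- vapply(nodem[lengths(nodem) == 2], `[`, character(1), 2)
    em <- regmatches(lines, regexec(
      '^\\s*"([^"]+)"\\s*->\\s*"([^"]+)"\\s*(\\[dir=none\\])?;\\s*$', lines))
    em <- em[lengths(em) == 4]
    src <- vapply(em, `[`, character(1), 2)
    tgt <- vapply(em, `[`, character(1), 3)
    undir <- vapply(em, `[`, character(1), 4) != ""
    bn_graph(unique(c(nodes, src, tgt)),
             arcs = cbind(src[!undir], tgt[!undir]),
             edges = cbind(src[undir], tgt[undir]))
  } else if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    bn_graph(x$nodes,
             arcs = if (length(x$arcs) > 0) as.matrix(x$arcs) else NULL,
             edges = if (length(x$edges) > 0) as.matrix(x$edges) else NULL)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    bn_graph(unique(c(df$from, df$to)),
             arcs = as.matrix(df[df$type == "directed", c("from", "to")]),
             edges = as.matrix(df[df$type == "undirected", c("from", "to")]))
  }
}

#' Write / read an annotated network as JSON
#'
#' @param x an `annotated_network` from [annotate_network()].
#' @param path file path.
#' @export
write_annotated_network <- function(x, path) {
  stopifnot(inherits(x, "annotated_network"))
  jsonlite::write_json(list(nodes = x$nodes, arcs = x$arcs), path,
                       auto_unbox = FALSE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotated_network
#' @export
read_annotated_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  arcs <- as.data.frame(x$arcs)
  if (nrow(arcs) == 0)
    arcs <- data.frame(from = character(0), to = character(0),
                       coefficient = numeric(0), effect = character(0),
                       inclusion_probability = numeric(0))
  structure(list(nodes = as.data.frame(x$nodes), arcs = arcs),
            class = "annotated_network")
}
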