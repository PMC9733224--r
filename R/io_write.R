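#' Write or read a signed network
#'
#' GraphML output (through igraph) carries node attribute `taxon_id` and
#' edge attributes `sign`, `weight`, `stability`; the edge-list TSV has
#' columns `node_u`, `node_v`, `sign`, `weight`, `stability` with the
#' lexicographically smaller id first.  Isolated nodes are preserved in
#' GraphML; the TSV writes a companion `*.nodes.tsv` with the full node
#' set so the round trip is exact.
#'
#' @param net a [signed_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [signed_network()].
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path)
    readr::write_tsv(tibble(node = net$nodes,
                            time_point = net$time_point,
                            condition = net$condition),
                     nodes_companion_path(path))
  }
  invisible(path)
}

nodes_companion_path <- function(path) {
  sub("(\\.tsv)?$", ".nodes.tsv", path)[1]
}

#' @rdname write_network
#' @param time_point,condition stratum labels for `read_network()` when the
#'   file does not carry them (GraphML does).
#' @export
read_network <- function(path, format = c("graphml", "edgelist_tsv"),
                         time_point = NA_integer_,
                         condition = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::vertex_attr(g, "taxon_id")
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- tibble(node_u = nodes[el[, 1L]], node_v = nodes[el[, 2L]],
                    sign = as.double(igraph::edge_attr(g, "sign") %||%
                                       double()),
                    weight = as.double(igraph::edge_attr(g, "weight") %||%
                                         double()),
                    stability = as.double(igraph::edge_attr(g, "stability") %||%
                                            double()))
    tp <- igraph::graph_attr(g, "time_point")
    cond <- igraph::graph_attr(g, "condition")
    signed_network(nodes, edges,
                   time_point = if (is.null(tp)) time_point else tp,
                   condition = if (is.null(cond)) condition else cond)
  } else {
    edges <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = "ccddd")
    npath <- nodes_companion_path(path)
    if (file.exists(npath)) {
      ninfo <- readr::read_tsv(npath, show_col_types = FALSE,
                               col_types = readr::cols(
                                 node = readr::col_character(),
                                 time_point = readr::col_integer(),
                                 condition = readr::col_character()))
      nodes <- ninfo$node
      if (is.na(time_point) && nrow(ninfo)) time_point <- ninfo$time_point[1L]
      if (is.na(condition) && nrow(ninfo)) condition <- ninfo$condition[1L]
    } else {
      nodes <- sort(unique(c(edges$node_u, edges$node_v)))
    }
    signed_network(nodes, edges, time_point = time_point,
                   condition = condition)
  }
}

#' Convert a signed network to an igraph object
#' @param net a [signed_network()].
#' @return an igraph graph with the same nodes, edges and attributes.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "taxon_id", value = net$nodes)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges)) {
    idx <- rbind(match(net$edges$node_u, net$nodes),
                 match(net$edges$node_v, net$nodes))
    g <- igraph::add_edges(g, as.vector(idx))
    g <- igraph::set_edge_attr(g, "sign", value = net$edges$sign)
    g <- igraph::set_edge_attr(g, "weight", value = net$edges$weight)
    g <- igraph::set_edge_attr(g, "stability", value = net$edges$stability)
  }
  g <- igraph::set_graph_attr(g, "time_point", net$time_point)
  igraph::set_graph_attr(g, "condition", net$condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write or read a persistence report
#'
#' The JSON document has one top-level key per condition, each holding the
#' node table, edge table, stable pairs and summary counts.  Companion
#' TSVs (`*.nodes.tsv`, `*.edges.tsv`) are written next to the JSON.
#'
#' @param report a [persistence_report()] or a named list of them (one per
#'   condition).
#' @param path output JSON path.
#' @return `path`, invisibly; `read_persistence_report()` returns the named
#'   list of reports.
#' @export
write_persistence_report <- function(report, path) {
  reports <- as_report_list(report)
  payload <- purrr::map(reports, function(r) {
    list(condition = r$condition,
         time_points = r$time_points,
         nodes = r$nodes, edges = r$edges, stable_pairs = r$stable_pairs,
         summary = r$summary)
  })
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  nodes <- purrr::map_dfr(reports, ~ dplyr::mutate(.x$nodes,
                                                   condition = .x$condition,
                                                   .before = 1L))
  edges <- purrr::map_dfr(reports, ~ dplyr::mutate(.x$edges,
                                                   condition = .x$condition,
                                                   .before = 1L))
  readr::write_tsv(nodes, sub("\\.json$", ".nodes.tsv", path))
  readr::write_tsv(edges, sub("\\.json$", ".edges.tsv", path))
  invisible(path)
}

as_report_list <- function(report) {
  if (inherits(report, "persistence_report")) {
    stats::setNames(list(report), report$condition)
  } else {
    stats::setNames(report, purrr::map_chr(report, "condition"))
  }
}

#' @rdname write_persistence_report
#' @export
read_persistence_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(raw, function(r) {
    structure(list(condition = r$condition,
                   time_points = as.integer(r$time_points),
                   nodes = restore_tbl(r$nodes, c(
                     node = "c", presence_pattern = "c", n_transitions = "i",
                     classification = "c", transits_whole_experiment = "l")),
                   edges = restore_tbl(r$edges, c(
                     node_u = "c", node_v = "c", time_point = "i",
                     sign = "d", classification = "c", terminal = "l")),
                   stable_pairs = restore_tbl(r$stable_pairs, c(
                     node_u = "c", node_v = "c", sign = "d",
                     t_start = "i", t_end = "i", run_length = "i")),
                   summary = as_tibble(as.data.frame(r$summary))),
              class = "persistence_report")
  })
}

# rebuild a typed tibble from json columns (possibly empty)
restore_tbl <- function(cols, spec) {
  out <- purrr::imap(spec, function(type, nm) {
    v <- cols[[nm]]
    if (is.null(v)) v <- logical(0)
    switch(type, c = as.character(v), i = as.integer(v),
           d = as.double(v), l = as.logical(v))
  })
  as_tibble(out)
}
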