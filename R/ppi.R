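new_ppi_graph <- function(g, disease_flags = NULL) {
  deg <- igraph::degree(g)
  structure(list(
    graph = g,
    nodes = tibble::tibble(
      accession = igraph::V(g)$name,
      degree = as.integer(deg),
      disease_flag = if (is.null(disease_flags)) NA else
        igraph::V(g)$name %in% disease_flags
    )
  ), class = "ppi_graph")
}

#' Build the induced protein-protein interaction network on a query set
#'
#' Keeps only interactions whose two endpoints both belong to the query set
#' ("non-adding" construction: no neighbour expansion beyond the query),
#' drops self-loops, and collapses duplicate/reversed edges. Query proteins
#' without any retained interaction appear as isolated nodes.
#'
#' @param edges Edge tibble with columns `from`, `to` (see [read_sif()] /
#'   [read_edge_tsv()]).
#' @param query Character vector of query accessions (nonempty).
#' @return An object of class `"ppi_graph"` wrapping an [igraph] graph, with
#'   a `nodes` tibble (`accession`, `degree`, `disease_flag`).
#' @export
build_induced_network <- function(edges, query) {
  if (length(query) == 0) abort("`query` must be nonempty")
  stopifnot(all(c("from", "to") %in% names(edges)))
  query <- unique(query)
  e <- dplyr::filter(edges, .data$from %in% query & .data$to %in% query &
                       .data$from != .data$to)
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = sort(query))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new_ppi_graph(g)
}

#' Remove orphan (degree-zero) nodes
#'
#' @param graph A `ppi_graph`.
#' @return List with `graph` (orphan-free `ppi_graph`) and `n_removed`.
#' @export
remove_orphans <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  orphans <- graph$nodes$accession[graph$nodes$degree == 0]
  g <- igraph::delete_vertices(graph$graph, orphans)
  out <- new_ppi_graph(g)
  if (!all(is.na(graph$nodes$disease_flag))) {
    out$nodes$disease_flag <- graph$nodes$disease_flag[
      match(out$nodes$accession, graph$nodes$accession)]
  }
  list(graph = out, n_removed = length(orphans))
}

#' Identify hub proteins
#'
#' Hubs are nodes whose degree (number of unique interaction partners)
#' reaches `hub_min_degree` (inclusive).
#'
#' @param graph A `ppi_graph`.
#' @param hub_min_degree Degree threshold (default 30).
#' @return Tibble (`accession`, `degree`) sorted by decreasing degree, ties
#'   lexicographic.
#' @export
find_hubs <- function(graph, hub_min_degree = 30) {
  stopifnot(inherits(graph, "ppi_graph"))
  graph$nodes |>
    dplyr::filter(.data$degree >= hub_min_degree) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$accession) |>
    dplyr::select("accession", "degree")
}

#' Flag disease-associated nodes
#'
#' Marks the network nodes found in a disease-association catalogue and
#' computes the disease percentage over both the current node set and an
#' optional reference query set (the two can differ after orphan removal).
#'
#' @param graph A `ppi_graph`.
#' @param disease_set Character vector of disease-associated accessions.
#' @param query Optional reference set over which to also report the
#'   percentage.
#' @return The `ppi_graph` with `disease_flag` set and attributes
#'   `pct_disease_nodes` (over current nodes) and `pct_disease_query` (over
#'   `query`, if given), both rounded to 2 decimals.
#' @export
flag_disease_nodes <- function(graph, disease_set, query = NULL) {
  stopifnot(inherits(graph, "ppi_graph"))
  graph$nodes$disease_flag <- graph$nodes$accession %in% disease_set
  n <- nrow(graph$nodes)
  attr(graph, "pct_disease_nodes") <- if (n == 0) NA_real_ else
    round(100 * sum(graph$nodes$disease_flag) / n, 2)
  if (!is.null(query)) {
    query <- unique(query)
    attr(graph, "pct_disease_query") <-
      round(100 * length(intersect(query, disease_set)) / length(query), 2)
  }
  graph
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("PPI graph: %d nodes, %d edges\n",
              nrow(x$nodes), igraph::ecount(x$graph)))
  if (!all(is.na(x$nodes$disease_flag))) {
    cat(sprintf("  %d disease-flagged nodes (%.2f%%)\n",
                sum(x$nodes$disease_flag, na.rm = TRUE),
                attr(x, "pct_disease_nodes") %||% NA))
  }
  invisible(x)
}

#' @export
tidy.ppi_graph <- function(x, hub_min_degree = 30, ...) {
  x$nodes |>
    dplyr::mutate(hub = .data$degree >= hub_min_degree) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$accession)
}

#' @export
glance.ppi_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = as.integer(igraph::ecount(x$graph)),
    n_orphans = sum(x$nodes$degree == 0),
    max_degree = if (nrow(x$nodes)) max(x$nodes$degree) else NA_integer_,
    pct_disease = attr(x, "pct_disease_nodes") %||% NA_real_
  )
}

#' Edge list of a PPI graph
#'
#' @param graph A `ppi_graph`.
#' @return Tibble (`from`, `to`).
#' @export
ppi_edges <- function(graph) {
  e <- igraph::as_edgelist(graph$graph)
  tibble::tibble(from = e[, 1], to = e[, 2])
}
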