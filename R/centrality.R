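# Module graph construction and hub-gene calling from degree and
# betweenness centrality.

#' Build an unweighted module graph by thresholding the adjacency
#'
#' Nodes are the module probes; an (undirected, unweighted) edge joins i and
#' j iff a_ij >= edge_threshold. No self-loops.
#'
#' @param network a `coexpr_network` or adjacency matrix.
#' @param member_probes node set (probe ids).
#' @param edge_threshold threshold in (0, 1] on the soft-threshold adjacency.
#' @return an igraph undirected graph.
#' @export
build_graph <- function(network, member_probes, edge_threshold = 0.1) {
  stopifnot(edge_threshold > 0, edge_threshold <= 1)
  a <- if (inherits(network, "coexpr_network")) network$adjacency else network
  a <- a[member_probes, member_probes, drop = FALSE]
  adj <- (a >= edge_threshold)
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Node degrees of a module graph
#' @param graph igraph graph.
#' @return named integer vector.
#' @export
node_degree <- function(graph) igraph::degree(graph)

#' Betweenness centrality (unweighted, raw counts)
#'
#' Shortest-path betweenness with unordered pairs counted once and
#' endpoints excluded; disconnected pairs contribute nothing. Raw
#' (unnormalized) values, matching hub cutoffs stated on raw counts.
#'
#' @param graph igraph graph.
#' @return named numeric vector.
#' @export
node_betweenness <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, weights = NA, normalized = FALSE)
}

#' Per-node centrality table for a module graph
#' @param graph igraph graph.
#' @param degree_min,betweenness_min hub thresholds (inclusive conjunction);
#'   defaults 250 and 2500.
#' @return data.frame: node, degree, betweenness, hub.
#' @export
centrality_table <- function(graph, degree_min = 250,
                             betweenness_min = 2500) {
  deg <- node_degree(graph)
  btw <- node_betweenness(graph)
  data.frame(node = names(deg), degree = as.integer(deg),
             betweenness = as.numeric(btw),
             hub = deg >= degree_min & btw >= betweenness_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call hub genes from a centrality table
#'
#' A node is a hub iff degree >= degree_min AND betweenness >=
#' betweenness_min (both inclusive).
#'
#' @param table data.frame with `node`, `degree`, `betweenness`.
#' @param degree_min,betweenness_min thresholds (>= 0).
#' @return character vector of hub node names.
#' @export
select_hubs <- function(table, degree_min = 250, betweenness_min = 2500) {
  stopifnot(degree_min >= 0, betweenness_min >= 0)
  table$node[table$degree >= degree_min &
               table$betweenness >= betweenness_min]
}

#' Write a module graph as an edge-list TSV (SIF-compatible)
#' @param graph igraph graph.
#' @param path output path.
#' @param sif if TRUE write "source<TAB>pp<TAB>target".
#' @export
write_graph_edges <- function(graph, path, sif = FALSE) {
  e <- igraph::as_edgelist(graph)
  df <- if (sif)
    data.frame(source = e[, 1], interaction = "pp", target = e[, 2])
  else data.frame(source = e[, 1], target = e[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
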