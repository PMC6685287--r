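#' Build an interaction graph with a cached hop-distance oracle
#'
#' Wraps an undirected, unweighted igraph built from a two-column edge list
#' (a functional-interaction gene network, or a GO graph whose is_a/part_of
#' edges are treated as undirected). Hop distances are computed per source
#' node by breadth-first search on demand and cached, so repeated queries
#' return identical values at no extra cost.
#'
#' @param edges Data frame whose first two columns are node ids of the edge
#'   endpoints. Duplicate edges (in either orientation) and self-loops are
#'   dropped.
#' @return An object of class `interaction_graph`.
#'
#' @examples
#' g <- interaction_graph(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' graph_distance(g, "g1", "g3")
#' @export
interaction_graph <- function(edges) {
  edges <- as.data.frame(edges)[, 1:2]
  edges[] <- lapply(edges, as.character)
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
  ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE)
  structure(
    list(graph = ig,
         nodes = igraph::V(ig)$name,
         cache = new.env(parent = emptyenv())),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("<interaction_graph> ", length(x$nodes), " nodes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

graph_has_node <- function(g, ids) ids %in% g$nodes

dist_row <- function(g, from) {
  row <- g$cache[[from]]
  if (is.null(row)) {
    row <- as.vector(igraph::distances(g$graph, v = from, mode = "all"))
    names(row) <- g$nodes
    assign(from, row, envir = g$cache)
  }
  row
}

#' Hop distance between two nodes
#'
#' @param g An [interaction_graph()].
#' @param from,to Node ids.
#' @return Non-negative integer hop count, or `Inf` when unreachable.
#' @export
graph_distance <- function(g, from, to) {
  if (!graph_has_node(g, from) || !graph_has_node(g, to)) {
    abort("node not present in graph.")
  }
  unname(dist_row(g, from)[to])
}

# Pairwise hop-distance matrix between two node sets (rows = from).
dist_block <- function(g, from, to) {
  out <- matrix(Inf, length(from), length(to), dimnames = list(from, to))
  for (x in from) out[x, ] <- dist_row(g, x)[to]
  out
}

# Drop set members absent from the graph, warning with the drug/set label.
mapped_set <- function(ids, g, label = "set") {
  keep <- graph_has_node(g, ids)
  if (!all(keep)) {
    warn(paste0(label, ": dropped ", sum(!keep),
                " id(s) absent from the graph."))
  }
  ids[keep]
}
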