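# Core graph representation. Neuronal networks are held as undirected simple
# igraph objects over opaque string node identifiers (neuron body IDs can
# exceed 32-bit integer range, so IDs are never treated as numbers). Directed
# synapse records are collapsed to undirected links; duplicates and self-loops
# are dropped with their counts recorded on the graph.

#' Build a neuronal network graph from an edge table
#'
#' Constructs an undirected simple graph from a two-column table of connected
#' node pairs. Self-loops and duplicate pairs (in either orientation) are
#' silently removed; the removal counts are stored as the graph attributes
#' `dropped_self_loops` and `dropped_duplicates`.
#'
#' @param edges a two-column character matrix or data frame; each row is one
#'   connected pair of nodes.
#' @param nodes optional character vector of node IDs to include even when
#'   isolated (must contain every endpoint in `edges`).
#' @return An undirected simple `igraph` graph with character vertex names.
#' @examples
#' g <- neuron_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' igraph::vcount(g)
#' @export
neuron_graph <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have exactly two columns (source, target)")
  }
  storage.mode(edges) <- "character"
  self <- edges[, 1L] == edges[, 2L]
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  key <- paste(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L]), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  verts <- unique(c(edges[, 1L], edges[, 2L], as.character(nodes)))
  if (!all(c(edges) %in% verts)) stop("`nodes` must cover all edge endpoints")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "dropped_self_loops", n_self)
  igraph::set_graph_attr(g, "dropped_duplicates", n_dup)
}

check_nodes <- function(g, v) {
  missing <- setdiff(v, igraph::V(g)$name)
  if (length(missing)) {
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Degree of a node
#'
#' @param g an `igraph` graph with named vertices.
#' @param v a node ID present in `g`.
#' @return Number of distinct neighbors of `v`.
#' @export
node_degree <- function(g, v) {
  check_nodes(g, v)
  unname(igraph::degree(g, v))
}

#' Connected components as node sets, largest first
#'
#' Components are returned as sorted character vectors, ordered by decreasing
#' size; ties are broken by the lexicographically smallest member ID.
#'
#' @param g an `igraph` graph with named vertices.
#' @return A list of character vectors partitioning the node set.
#' @export
graph_components <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  sets <- split(igraph::V(g)$name, comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-lengths(sets), vapply(sets, `[`, character(1), 1L))
  unname(sets[ord])
}

#' Induced subgraph on a node set
#'
#' @param g an `igraph` graph with named vertices.
#' @param s character vector of node IDs, all present in `g`.
#' @return The subgraph of `g` induced on `s` (all edges of `g` with both
#'   endpoints in `s`).
#' @export
subgraph_of <- function(g, s) {
  s <- as.character(s)
  check_nodes(g, s)
  igraph::induced_subgraph(g, s)
}

#' Closed k-hop neighborhood of a node (scan window)
#'
#' The window around a node of interest contains the node itself, its
#' adjacent neighbors, and all neighbors of those neighbors out to
#' `radius` steps — i.e. every node within shortest-path distance `radius`.
#' The induced subgraph on the result is always connected.
#'
#' @param g an `igraph` graph with named vertices.
#' @param v the center node ID.
#' @param radius neighborhood radius in hops (default 2, the scan window).
#' @return Sorted character vector of member node IDs (always includes `v`).
#' @export
ego_window <- function(g, v, radius = 2) {
  check_nodes(g, v)
  stopifnot(radius >= 1)
  sort(igraph::ego(g, order = radius, nodes = v)[[1]]$name)
}
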