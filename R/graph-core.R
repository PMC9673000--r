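# Graph primitives: degrees, degree distribution, BFS distances and
# shortest-path counting on the directed multigraph. Degree counts edge
# multiplicity; path semantics collapse parallel edges (one hop per edge).

# Integer edge endpoints and a CSR adjacency for the C++ kernels.
# symmetrize = TRUE adds reversed edges (undirected path semantics).
graph_index <- function(graph, symmetrize = FALSE) {
  ids <- graph$nodes$id
  n <- length(ids)
  from <- match(graph$edges$from, ids)
  to <- match(graph$edges$to, ids)
  if (anyNA(from) || anyNA(to))
    stop("graph has dangling edges; run validate_graph() first")
  if (symmetrize) {
    tmp <- c(from, to); to <- c(to, from); from <- tmp
  }
  # collapse parallel edges for path semantics
  keep <- !duplicated(from * (n + 1) + to)
  fs <- from[keep]; ts <- to[keep]
  o <- order(fs, ts)
  fs <- fs[o]; ts <- ts[o]
  offsets <- c(0L, cumsum(tabulate(fs, nbins = n)))
  list(ids = ids, n = n, from = from, to = to,
       offsets = as.integer(offsets), targets = as.integer(ts - 1L))
}

#' Total degree of nodes
#'
#' The degree of a node is the number of relationships coming into or out
#' of it (in-degree plus out-degree), counting parallel typed edges with
#' their multiplicity. Self-loops contribute 2.
#'
#' @param graph A [malpractice_graph()].
#' @param node Optional node id (or vector of ids); by default all nodes.
#' @return Named integer vector of total degrees.
#' @export
#' @examples
#' g <- generate_random_graph(10, 0.2, seed = 1)
#' total_degree(g)
total_degree <- function(graph, node = NULL) {
  stopifnot(inherits(graph, "malpractice_graph"))
  ids <- graph$nodes$id
  n <- length(ids)
  deg <- tabulate(match(graph$edges$from, ids), nbins = n) +
    tabulate(match(graph$edges$to, ids), nbins = n)
  names(deg) <- ids
  if (is.null(node)) return(deg)
  if (!all(node %in% ids)) {
    stop("unknown node: ", paste(setdiff(node, ids), collapse = ", "))
  }
  deg[node]
}

#' Degree distribution of a graph
#'
#' Histogram of total degrees over all nodes, together with the raw degree
#' sequence used by the distribution-fitting stage.
#'
#' @param graph A [malpractice_graph()].
#' @return An object of class `degree_distribution`: a list with `counts`
#'   (named integer vector, names are degree values), `n_nodes`, and
#'   `sequence` (the per-node degree sequence, named by node id).
#' @export
#' @examples
#' dd <- degree_distribution(generate_pa_graph(100, 2, seed = 1))
#' head(dd$counts)
degree_distribution <- function(graph) {
  deg <- total_degree(graph)
  tab <- table(deg)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, n_nodes = length(deg), sequence = deg),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution> %d nodes, degrees %s..%s, median %g\n",
              x$n_nodes, names(x$counts)[1],
              names(x$counts)[length(x$counts)],
              stats::median(x$sequence)))
  invisible(x)
}

#' Degree sequence of a graph
#'
#' @param graph A [malpractice_graph()].
#' @return Unnamed integer vector of total degrees (one per node), the
#'   plain-text exchange format of the distribution-fitting stage.
#' @export
degree_sequence <- function(graph) {
  unname(total_degree(graph))
}

#' Single-source shortest path lengths
#'
#' Breadth-first distances from `source` following edge direction; each
#' edge counts one hop regardless of multiplicity. Unreachable nodes are
#' absent from the result (never coded as 0): the closeness convention that
#' maps unreachable pairs to a zero contribution is applied only in the
#' centrality layer.
#'
#' @param graph A [malpractice_graph()].
#' @param source Node id.
#' @param directed Follow edge direction (default) or treat edges as
#'   undirected.
#' @return Named integer vector of hop counts for every reachable node,
#'   including `source` at distance 0.
#' @export
#' @examples
#' g <- malpractice_graph(data.frame(id = c("a", "b", "c")),
#'                        data.frame(from = c("a", "b"), to = c("b", "c")))
#' shortest_paths_from(g, "a")
shortest_paths_from <- function(graph, source, directed = TRUE) {
  stopifnot(inherits(graph, "malpractice_graph"))
  gi <- graph_index(graph, symmetrize = !directed)
  s <- match(source, gi$ids)
  if (is.na(s)) stop("unknown source node: ", source)
  d <- cpp_bfs_dist(gi$offsets, gi$targets, gi$n, s - 1L)
  names(d) <- gi$ids
  d[d >= 0]
}

#' Count shortest paths between two nodes
#'
#' Geodesic length and the number of distinct shortest directed paths from
#' `a` to `b`, by layered breadth-first counting on the simple digraph
#' (parallel edges collapse to one).
#'
#' @param graph A [malpractice_graph()].
#' @param a,b Distinct node ids.
#' @param directed Follow edge direction (default) or not.
#' @return A list with `length` (integer hops, `Inf` when unreachable) and
#'   `count` (number of distinct shortest paths; 0 when unreachable).
#' @export
#' @examples
#' g <- malpractice_graph(data.frame(id = c("a", "b", "c", "d")),
#'   data.frame(from = c("a", "a", "b", "c"), to = c("b", "c", "d", "d")))
#' count_shortest_paths(g, "a", "d")  # diamond: length 2, 2 paths
count_shortest_paths <- function(graph, a, b, directed = TRUE) {
  stopifnot(inherits(graph, "malpractice_graph"))
  if (identical(a, b)) stop("a and b must be distinct nodes")
  gi <- graph_index(graph, symmetrize = !directed)
  ia <- match(a, gi$ids); ib <- match(b, gi$ids)
  if (is.na(ia)) stop("unknown node: ", a)
  if (is.na(ib)) stop("unknown node: ", b)
  res <- cpp_count_paths(gi$offsets, gi$targets, gi$n, ia - 1L, ib - 1L)
  list(length = if (res[1] < 0) Inf else as.integer(res[1]),
       count = res[2])
}
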