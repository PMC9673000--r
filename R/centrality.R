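# The four hub metrics, implemented exactly under the conventions of the
# malpractice network study: degree centrality d_i/(N-1) on total degree;
# closeness (N-1)/sum_j D_ij with unreachable pairs contributing 0 to the
# sum; unnormalized directed betweenness over ordered pairs; and the
# classic unnormalized PageRank recurrence PR(i) = (1-d) + d * sum over
# in-neighbours of PR(T)/C(T).

centrality_scores <- function(metric, scores, params = list()) {
  structure(list(metric = metric, scores = scores, params = params),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("<centrality_scores> metric=%s over %d nodes\n",
              x$metric, length(x$scores)))
  top <- sort(x$scores, decreasing = TRUE)
  print(utils::head(top, 5))
  invisible(x)
}

#' Degree centrality
#'
#' `D(i) = d_i / (N - 1)` where `d_i` is the total degree (incoming plus
#' outgoing relationships, with multiplicity) and `N` the number of nodes.
#'
#' @param graph A [malpractice_graph()] with at least two nodes.
#' @return A `centrality_scores` object (metric `"degree"`).
#' @export
#' @examples
#' g <- generate_pa_graph(50, 2, seed = 1)
#' degree_centrality(g)
degree_centrality <- function(graph) {
  stopifnot(inherits(graph, "malpractice_graph"))
  n <- n_nodes(graph)
  if (n < 2) stop("degree centrality requires at least 2 nodes")
  centrality_scores("degree", total_degree(graph) / (n - 1))
}

#' Closeness centrality
#'
#' `C(i) = (N - 1) / sum_j D_ij` where `D_ij` is the shortest directed path
#' length from `i` to `j` and an unreachable pair contributes 0 to the sum
#' (the convention of the malpractice network study, applied literally).
#' A node that reaches no other node receives score 0. Note that on
#' disconnected graphs this convention can yield scores above 1 because a
#' node reaching only few, close nodes divides `N - 1` by a small sum; the
#' `harmonic` variant (`sum_j 1/D_ij / (N - 1)`) is offered for sanity
#' comparisons and is bounded by 1.
#'
#' @param graph A [malpractice_graph()] with at least two nodes.
#' @param directed Follow edge direction (default).
#' @param harmonic Use harmonic closeness instead of the literal
#'   convention.
#' @return A `centrality_scores` object (metric `"closeness"` or
#'   `"harmonic_closeness"`).
#' @export
closeness_centrality <- function(graph, directed = TRUE, harmonic = FALSE) {
  stopifnot(inherits(graph, "malpractice_graph"))
  n <- n_nodes(graph)
  if (n < 2) stop("closeness centrality requires at least 2 nodes")
  gi <- graph_index(graph, symmetrize = !directed)
  sums <- cpp_distance_sums(gi$offsets, gi$targets, gi$n)
  if (harmonic) {
    sc <- sums$harmonic / (n - 1)
    metric <- "harmonic_closeness"
  } else {
    sc <- ifelse(sums$sum > 0, (n - 1) / sums$sum, 0)
    metric <- "closeness"
  }
  names(sc) <- gi$ids
  centrality_scores(metric, sc,
                    params = list(directed = directed, harmonic = harmonic))
}

#' Betweenness centrality
#'
#' `B(i) = sum over ordered pairs (a, b), a != b != i, of g_ab(i)/g_ab`
#' where `g_ab` counts shortest directed paths from `a` to `b` and
#' `g_ab(i)` those passing through `i`; pairs with no path contribute 0.
#' Scores are unnormalized. Computed by Brandes' dependency accumulation;
#' geodesics are counted on the simple digraph (parallel edges collapse).
#'
#' @param graph A [malpractice_graph()].
#' @param directed Follow edge direction (default).
#' @return A `centrality_scores` object (metric `"betweenness"`).
#' @export
#' @examples
#' g <- malpractice_graph(data.frame(id = c("a", "b", "c")),
#'   data.frame(from = c("a", "b"), to = c("b", "c")))
#' betweenness_centrality(g)$scores  # b bridges the sole a->c geodesic
betweenness_centrality <- function(graph, directed = TRUE) {
  stopifnot(inherits(graph, "malpractice_graph"))
  gi <- graph_index(graph, symmetrize = !directed)
  bc <- cpp_betweenness(gi$offsets, gi$targets, gi$n)
  names(bc) <- gi$ids
  centrality_scores("betweenness", bc, params = list(directed = directed))
}

#' PageRank centrality
#'
#' Fixed-point iteration of the unnormalized recurrence
#' `PR(i) = (1 - d) + d * (PR(T1)/C(T1) + ... + PR(Tn)/C(Tn))`, where
#' `T1..Tn` are the pages linking to `i`, `C(T)` is the number of links
#' going out of `T` (parallel edges counted), and `d` is the damping
#' factor, 0.85 by default. Dangling nodes (zero out-degree) distribute
#' their rank uniformly over all nodes. Iteration stops when the maximum
#' absolute score change falls below `tol`; on any graph the converged
#' scores sum to `N`.
#'
#' @param graph A [malpractice_graph()].
#' @param d Damping factor in `[0, 1]` (default 0.85).
#' @param tol Convergence tolerance on the max score change (default 1e-8).
#' @param max_iter Iteration cap (default 200); non-convergence raises an
#'   error carrying the last iterate in `attr(, "last")`.
#' @param directed Follow edge direction (default).
#' @param init Optional starting vector (length `N`, positive); defaults
#'   to all ones. On strongly connected graphs the fixed point does not
#'   depend on the start.
#' @return A `centrality_scores` object (metric `"pagerank"`) whose
#'   `params` record `d`, `tol` and the iterations used.
#' @export
#' @examples
#' g <- generate_pa_graph(50, 2, seed = 1)
#' pr <- pagerank(g)
#' sum(pr$scores)  # == number of nodes
pagerank <- function(graph, d = 0.85, tol = 1e-8, max_iter = 200,
                     directed = TRUE, init = NULL) {
  stopifnot(inherits(graph, "malpractice_graph"))
  stopifnot(d >= 0, d <= 1, tol > 0, max_iter >= 1)
  ids <- graph$nodes$id
  n <- length(ids)
  if (n < 1) stop("pagerank requires at least one node")
  from <- match(graph$edges$from, ids)
  to <- match(graph$edges$to, ids)
  if (anyNA(from) || anyNA(to))
    stop("graph has dangling edges; run validate_graph() first")
  if (!directed) {
    tmp <- c(from, to); to <- c(to, from); from <- tmp
  }
  outdeg <- tabulate(from, nbins = n)  # C(T): multiplicity counted
  dangling <- outdeg == 0
  # M[i, j] = multiplicity(j -> i) / C(j)
  M <- if (length(from))
    Matrix::sparseMatrix(i = to, j = from, x = 1 / outdeg[from],
                         dims = c(n, n))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(n, n))
  x <- if (is.null(init)) rep(1, n) else {
    stopifnot(length(init) == n, all(init > 0))
    as.numeric(init)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xn <- as.numeric((1 - d) + d * (M %*% x + sum(x[dangling]) / n))
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
    if (iter >= max_iter) {
      e <- simpleError(sprintf(
        "pagerank did not converge in %d iterations (last change %.3g)",
        max_iter, delta))
      attr(e, "last") <- setNames(x, ids)
      stop(e)
    }
  }
  centrality_scores("pagerank", setNames(x, ids),
                    params = list(d = d, tol = tol, iterations = iter,
                                  directed = directed))
}

#' Subgraph of errors and their chronological order links
#'
#' The subnetwork induced by `E` nodes and `Order` relationships, on which
#' hub errors are ranked.
#'
#' @param graph A [malpractice_graph()].
#' @return A [malpractice_graph()] containing only `E` nodes and `Order`
#'   edges.
#' @export
error_subgraph <- function(graph) {
  stopifnot(inherits(graph, "malpractice_graph"))
  nodes <- graph$nodes[!is.na(graph$nodes$kind) & graph$nodes$kind == "E", ,
                       drop = FALSE]
  edges <- graph$edges[!is.na(graph$edges$relation) &
                         graph$edges$relation == "Order", , drop = FALSE]
  edges <- edges[edges$from %in% nodes$id & edges$to %in% nodes$id, ,
                 drop = FALSE]
  malpractice_graph(nodes, edges)
}

# recompute a metric (same parameters) on another graph
recompute_metric <- function(scores, graph) {
  p <- scores$params
  switch(scores$metric,
         degree = degree_centrality(graph),
         closeness = closeness_centrality(graph,
                                          directed = p$directed %||% TRUE),
         harmonic_closeness = closeness_centrality(
           graph, directed = p$directed %||% TRUE, harmonic = TRUE),
         betweenness = betweenness_centrality(graph,
                                              directed = p$directed %||% TRUE),
         pagerank = pagerank(graph, d = p$d %||% 0.85,
                             tol = p$tol %||% 1e-8,
                             directed = p$directed %||% TRUE),
         stop("unknown metric: ", scores$metric))
}

#' Rank hub nodes
#'
#' Top-`k` nodes by a centrality score, descending, ties broken by
#' lexicographic node id so tables are deterministic. With
#' `restrict = "error_subgraph"` the metric is recomputed on the subgraph
#' induced by `E` nodes and `Order` edges (see [error_subgraph()]) before
#' ranking, mirroring how hub errors are reported separately from the
#' overall graph.
#'
#' @param scores A `centrality_scores` object.
#' @param k Table depth (default 10).
#' @param restrict `NULL` (rank all scored nodes), `"error_subgraph"`, or a
#'   character vector of node kinds to keep (requires `graph`).
#' @param graph The graph the scores came from; required when `restrict`
#'   is used.
#' @return A `hub_table`: data frame with columns `rank`, `id`, `kind`,
#'   `score`, carrying the metric in `attr(, "metric")`. An empty
#'   restriction set yields an empty table.
#' @export
#' @examples
#' g <- generate_pa_graph(50, 2, seed = 1)
#' rank_hubs(degree_centrality(g), k = 5)
rank_hubs <- function(scores, k = 10, restrict = NULL, graph = NULL) {
  stopifnot(inherits(scores, "centrality_scores"), k >= 1)
  kind_of <- NULL
  if (!is.null(restrict)) {
    if (is.null(graph))
      stop("restrict requires the graph the scores came from")
    if (identical(restrict, "error_subgraph")) {
      sub <- error_subgraph(graph)
      if (n_nodes(sub) == 0) {
        out <- data.frame(rank = integer(), id = character(),
                          kind = character(), score = numeric())
        attr(out, "metric") <- scores$metric
        class(out) <- c("hub_table", "data.frame")
        return(out)
      }
      scores <- if (n_nodes(sub) >= 2 || scores$metric %in%
                      c("betweenness", "pagerank"))
        recompute_metric(scores, sub)
      else centrality_scores(scores$metric,
                             setNames(numeric(n_nodes(sub)), sub$nodes$id))
      kind_of <- setNames(sub$nodes$kind, sub$nodes$id)
    } else {
      keep <- graph$nodes$id[graph$nodes$kind %in% restrict]
      scores <- centrality_scores(scores$metric,
                                  scores$scores[names(scores$scores) %in% keep],
                                  scores$params)
    }
  }
  if (!is.null(graph) && is.null(kind_of))
    kind_of <- setNames(graph$nodes$kind, graph$nodes$id)
  sc <- scores$scores
  if (length(sc) == 0) {
    out <- data.frame(rank = integer(), id = character(),
                      kind = character(), score = numeric())
  } else {
    o <- order(-sc, names(sc))
    top <- utils::head(o, k)
    out <- data.frame(
      rank = seq_along(top),
      id = names(sc)[top],
      kind = if (is.null(kind_of)) NA_character_ else
        unname(kind_of[names(sc)[top]]),
      score = unname(sc[top]),
      stringsAsFactors = FALSE)
  }
  attr(out, "metric") <- scores$metric
  attr(out, "k") <- k
  class(out) <- c("hub_table", "data.frame")
  out
}
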