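# Brute-force oracles, independent of the package's C++ kernels: dense
# Floyd-Warshall distances and exhaustive geodesic enumeration by
# backtracking over those distances.

# quick typed/untyped graph builder: edges as a 2-column matrix of ids
mk_graph <- function(ids, edges, kinds = NULL, relations = NULL) {
  nodes <- data.frame(id = ids)
  if (!is.null(kinds)) nodes$kind <- kinds
  ed <- if (is.null(edges) || nrow(edges) == 0)
    data.frame(from = character(), to = character())
  else data.frame(from = edges[, 1], to = edges[, 2])
  if (!is.null(relations)) ed$relation <- relations
  malpractice_graph(nodes, ed)
}

# all-pairs hop distances on the simple digraph (Inf when unreachable)
fw_distances <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  f <- match(graph$edges$from, ids)
  t <- match(graph$edges$to, ids)
  D[cbind(f, t)] <- pmin(D[cbind(f, t)], 1)
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

in_neighbours <- function(graph) {
  ids <- graph$nodes$id
  f <- match(graph$edges$from, ids)
  t <- match(graph$edges$to, ids)
  keep <- !duplicated(paste(f, t))
  f <- f[keep]; t <- t[keep]
  lapply(seq_along(ids), function(i) f[t == i])
}

# every shortest path from a to b (indices), as a list of index vectors
enumerate_geodesics <- function(D, inn, a, b) {
  if (!is.finite(D[a, b])) return(list())
  backtrack <- function(v) {
    if (v == a) return(list(a))
    out <- list()
    for (u in inn[[v]]) {
      if (is.finite(D[a, u]) && D[a, u] == D[a, v] - 1) {
        for (p in backtrack(u)) out[[length(out) + 1]] <- c(p, v)
      }
    }
    out
  }
  backtrack(b)
}

# betweenness by exhaustive geodesic enumeration over ordered pairs
bf_betweenness <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  D <- fw_distances(graph)
  inn <- in_neighbours(graph)
  B <- numeric(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b || !is.finite(D[a, b])) next
    paths <- enumerate_geodesics(D, inn, a, b)
    g <- length(paths)
    if (g == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(a, b))
      B[interior] <- B[interior] + 1 / g
    }
  }
  names(B) <- ids
  B
}

bf_count_paths <- function(graph, a, b) {
  ids <- graph$nodes$id
  D <- fw_distances(graph)
  ia <- match(a, ids); ib <- match(b, ids)
  paths <- enumerate_geodesics(D, in_neighbours(graph), ia, ib)
  list(length = if (is.finite(D[ia, ib])) D[ia, ib] else Inf,
       count = length(paths))
}
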