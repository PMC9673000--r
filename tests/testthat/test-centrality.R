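star5 <- function() mk_graph(c("c0", "l1", "l2", "l3", "l4"),
                             cbind("c0", c("l1", "l2", "l3", "l4")))
path3 <- function() mk_graph(c("a", "b", "c"),
                             rbind(c("a", "b"), c("b", "c")))
cycle_graph <- function(n) {
  ids <- sprintf("n%02d", seq_len(n))
  mk_graph(ids, cbind(ids, ids[c(2:n, 1)]))
}
complete4 <- function() {
  ids <- c("a", "b", "c", "d")
  e <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  e <- e[e$from != e$to, ]
  malpractice_graph(data.frame(id = ids), e)
}

test_that("degree centrality matches its closed forms", {
  sc <- degree_centrality(star5())$scores
  expect_equal(unname(sc["c0"]), 1)
  expect_equal(unname(sc["l1"]), 1 / 4)
  expect_equal(unname(degree_centrality(cycle_graph(3))$scores),
               rep(1, 3))
  expect_error(degree_centrality(mk_graph("a", NULL)), "at least 2")
  # oracle: d_i / (N - 1) recomputed from raw counts on a multigraph
  g <- generate_mmnc(mmnc_gen_params(n_cases = 50, seed = 6))
  sc <- degree_centrality(g)$scores
  expect_equal(sc, total_degree(g) / (n_nodes(g) - 1))
})

test_that("closeness follows the printed unreachable-contributes-0 convention", {
  sc <- closeness_centrality(star5())$scores
  expect_equal(unname(sc["c0"]), 1)        # 4 / (1+1+1+1)
  expect_equal(unname(sc["l1"]), 0)        # leaves reach nothing
  expect_equal(unname(closeness_centrality(path3())$scores["a"]), 2 / 3)
  # two disjoint directed edges: the literal convention exceeds 1
  g <- mk_graph(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  expect_equal(unname(closeness_centrality(g)$scores["a"]), 3)
  # harmonic variant stays in [0, 1]
  h <- closeness_centrality(g, harmonic = TRUE)$scores
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(unname(h["a"]), 1 / 3)
})

test_that("betweenness matches hand cases", {
  expect_equal(unname(betweenness_centrality(path3())$scores),
               c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(complete4())$scores),
               rep(0, 4))
})

test_that("betweenness equals exhaustive geodesic enumeration on random digraphs", {
  for (seed in 1:8) {
    g <- generate_random_graph(12 + seed, 0.12, seed = seed)
    expect_equal(betweenness_centrality(g)$scores, bf_betweenness(g),
                 tolerance = 1e-10)
  }
})

test_that("betweenness agrees with an independent library implementation", {
  for (seed in 1:4) {
    g <- generate_random_graph(40, 0.06, seed = seed * 7)
    ours <- betweenness_centrality(g)$scores
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        vertices = g$nodes$id)
    theirs <- igraph::betweenness(ig, directed = TRUE)
    expect_equal(ours[names(theirs)], theirs, tolerance = 1e-10)
  }
})

test_that("pagerank honours the printed recurrence and its fixed points", {
  # d = 0 collapses every score to 1
  g <- generate_random_graph(30, 0.1, seed = 2)
  expect_equal(unname(pagerank(g, d = 0)$scores), rep(1, 30))
  # directed cycle: symmetric fixed point of 1 at any damping
  expect_equal(unname(pagerank(cycle_graph(7), d = 0.85)$scores),
               rep(1, 7), tolerance = 1e-7)
  # default damping is recorded
  expect_equal(pagerank(cycle_graph(3))$params$d, 0.85)
  # scores sum to N even with dangling nodes
  g <- mk_graph(c("a", "b", "dangling"),
                rbind(c("a", "b"), c("b", "a"), c("a", "dangling")))
  expect_equal(sum(pagerank(g)$scores), 3, tolerance = 1e-6)
  # non-convergence carries the last iterate (a cycle started at the
  # all-ones fixed point converges instantly, so start elsewhere)
  err <- tryCatch(pagerank(cycle_graph(10), max_iter = 1,
                           init = seq(0.1, 1, length.out = 10)),
                  error = function(e) e)
  expect_match(conditionMessage(err), "did not converge")
  expect_length(attr(err, "last"), 10)
})

test_that("pagerank fixed point is independent of initialization on strongly connected graphs", {
  ids <- sprintf("n%d", 1:12)
  e <- rbind(cbind(ids, ids[c(2:12, 1)]),          # cycle
             cbind(ids[c(1, 4, 7)], ids[c(6, 9, 2)]),  # chords
             cbind(ids[1], ids[2]))                # a parallel edge
  g <- mk_graph(ids, e)
  tol <- 1e-10
  p1 <- pagerank(g, tol = tol)$scores
  p2 <- pagerank(g, tol = tol, init = rep(1 / 12, 12))$scores
  expect_equal(p1, p2, tolerance = 10 * tol)
  expect_equal(sum(p1), 12, tolerance = 10 * tol)
})

test_that("all four metrics are invariant under node relabeling", {
  g <- generate_random_graph(25, 0.12, seed = 4)
  ren <- function(x) paste0("zz_", x)
  g2 <- g
  g2$nodes$id <- ren(g$nodes$id)
  g2$edges$from <- ren(g$edges$from)
  g2$edges$to <- ren(g$edges$to)
  for (f in list(degree_centrality, closeness_centrality,
                 betweenness_centrality, pagerank)) {
    s1 <- f(g)$scores
    s2 <- f(g2)$scores
    expect_equal(unname(s2[ren(names(s1))]), unname(s1), tolerance = 1e-9)
  }
})

test_that("on a directed cycle all four metrics are constant across nodes", {
  g <- cycle_graph(9)
  for (f in list(degree_centrality, closeness_centrality,
                 betweenness_centrality, pagerank)) {
    s <- f(g)$scores
    expect_lt(diff(range(s)), 1e-7)
  }
})

test_that("hub tables rank deterministically and honour restriction", {
  sc <- degree_centrality(star5())
  tb <- rank_hubs(sc, k = 2)
  expect_equal(tb$id, c("c0", "l1"))  # center, then smallest-id leaf
  expect_equal(tb$rank, 1:2)
  tb1 <- rank_hubs(sc, k = 1)
  expect_equal(tb1$id, "c0")
  expect_true(all(diff(rank_hubs(sc, k = 5)$score) <= 0))

  g <- generate_mmnc(mmnc_gen_params(n_cases = 60, seed = 8))
  tb <- rank_hubs(betweenness_centrality(g), k = 10,
                  restrict = "error_subgraph", graph = g)
  expect_true(all(tb$kind == "E"))
  # scores were recomputed on the induced subgraph, not filtered
  sub <- error_subgraph(g)
  expect_true(all(!is.na(g$nodes$kind[match(tb$id, g$nodes$id)])))
  expect_equal(tb$score[1],
               max(betweenness_centrality(sub)$scores))

  # restriction to an absent kind gives an empty table, not an error
  gu <- generate_pa_graph(10, 1, seed = 1)
  tbe <- rank_hubs(degree_centrality(gu), k = 3,
                   restrict = "error_subgraph", graph = gu)
  expect_equal(nrow(tbe), 0)
})
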