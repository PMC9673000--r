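test_that("generator parameter validation catches infeasible settings", {
  expect_error(mmnc_gen_params(n_hospitals = 0), "n_hospitals")
  expect_error(mmnc_gen_params(error_rate = 1.2), "error_rate")
  expect_error(mmnc_gen_params(n_disease_groups = 30), "23")
  expect_error(mmnc_gen_params(outcome_probs = c(0.5, 0.5, 0, 0, 0.1)),
               "summing to 1")
  expect_error(generate_pa_graph(3, 3), "exceed")
  expect_error(generate_random_graph(5, 1.5), "p <= 1")
  expect_error(sample_power_law(10, alpha = 0.9), "alpha")
  expect_error(sample_exponential_tail(10, lambda = -1), "lambda")
  expect_error(sample_lognormal_tail(10, 0, sigma = 0), "sigma")
})

test_that("every generator is a pure function of parameters and seed", {
  p <- mmnc_gen_params(n_cases = 120, seed = 7)
  expect_identical(generate_mmnc(p), generate_mmnc(p))
  expect_identical(generate_pa_graph(200, 3, seed = 4),
                   generate_pa_graph(200, 3, seed = 4))
  expect_identical(generate_random_graph(100, 0.05, seed = 4),
                   generate_random_graph(100, 0.05, seed = 4))
  expect_identical(sample_power_law(500, 2.5, seed = 2),
                   sample_power_law(500, 2.5, seed = 2))
  # different seeds give different draws but identical shapes
  g1 <- generate_pa_graph(100, 2, seed = 1)
  g2 <- generate_pa_graph(100, 2, seed = 2)
  expect_equal(n_nodes(g1), n_nodes(g2))
  expect_false(identical(g1$edges, g2$edges))
})

test_that("a single all-error case has the exact link cardinalities", {
  g <- generate_mmnc(mmnc_gen_params(n_cases = 1, error_rate = 1, seed = 1))
  rel <- table(g$edges$relation)
  expect_equal(unname(rel[["Sue"]]), 2)
  expect_equal(unname(rel[["Cause"]]), 1)
  expect_gte(rel[["Error"]], 1)
  expect_equal(nrow(validate_graph(g)), 0)
  expect_true(all(case_cardinality_checks(g)))
})

test_that("generated networks always satisfy the schema and cardinalities", {
  for (p in list(mmnc_gen_params(n_cases = 80, seed = 1),
                 mmnc_gen_params(n_cases = 150, error_rate = 0, seed = 2),
                 mmnc_gen_params(n_cases = 60, attachment_strength = 0,
                                 seed = 3),
                 mmnc_gen_params(n_cases = 50, n_hospitals = 2,
                                 n_specialties = 2, seed = 4))) {
    g <- generate_mmnc(p)
    expect_equal(nrow(validate_graph(g)), 0)
    expect_true(all(case_cardinality_checks(g)))
  }
})

test_that("preferential attachment concentrates relationships on few hubs", {
  g <- generate_mmnc(mmnc_gen_params(n_cases = 5000, seed = 13))
  deg <- sort(total_degree(g), decreasing = TRUE)
  top <- ceiling(0.01 * length(deg))
  expect_gte(sum(deg[seq_len(top)]) / sum(deg), 0.25)
})

test_that("the attachment process is rich-get-richer relative to uniform", {
  skewed <- generate_mmnc(mmnc_gen_params(n_cases = 2000,
                                          attachment_strength = 2,
                                          seed = 5))
  uniform <- generate_mmnc(mmnc_gen_params(n_cases = 2000,
                                           attachment_strength = 0,
                                           seed = 5))
  top_share <- function(g) {
    d <- sort(total_degree(g), decreasing = TRUE)
    h <- d[names(d) %in% g$nodes$id[g$nodes$kind == "H"]]
    sum(h[1:5]) / sum(h)
  }
  expect_gt(top_share(skewed), top_share(uniform))
})

test_that("the growth process yields the expected edge counts", {
  g <- generate_pa_graph(10, 1, seed = 1)
  expect_equal(n_relationships(g), 9)  # a tree on 10 nodes
  g3 <- generate_pa_graph(100, 3, seed = 1)
  # each new node beyond the seed core attaches min(m, existing) edges
  expect_equal(n_relationships(g3), 1 + 2 + 3 * 97)
})

test_that("the random digraph matches its binomial edge expectation", {
  expect_equal(n_relationships(generate_random_graph(50, 0, seed = 1)), 0)
  expect_equal(n_relationships(generate_random_graph(4, 1, seed = 1)), 12)
  n <- 3000; p <- 0.002
  g <- generate_random_graph(n, p, seed = 5)
  md <- mean(total_degree(g))
  se <- 2 * sqrt(n * (n - 1) * p * (1 - p)) / n
  expect_lt(abs(md - 2 * p * (n - 1)), 3 * se)
})

test_that("the continuous power-law sampler matches its closed forms", {
  n <- 50000
  x <- sample_power_law(n, alpha = 2, xmin = 1, discrete = FALSE, seed = 1)
  expect_gte(min(x), 1)
  # median = xmin * 2^(1/(alpha-1)) = 2
  expect_lt(abs(median(x) - 2) / 2, 0.05)
  # empirical CCDF within the 1% KS band of (x/xmin)^(1-alpha)
  x <- sort(sample_power_law(1e5, alpha = 2.5, xmin = 3, discrete = FALSE,
                             seed = 2))
  Fm <- 1 - (x / 3)^(1 - 2.5)
  i <- seq_along(x)
  ks <- max(abs(Fm - i / 1e5), abs(Fm - (i - 1) / 1e5))
  expect_lt(ks, 1.63 / sqrt(1e5))
})

test_that("the discrete power-law sampler reproduces the zeta mass at k = 1", {
  x <- sample_power_law(50000, alpha = 2.5, xmin = 1, seed = 3)
  expect_true(all(x >= 1), all(x == floor(x)))
  expect_lt(abs(mean(x == 1) - 1 / hurwitz_zeta(2.5, 1)), 0.01)
})

test_that("truncated exponential and log-normal samplers behave", {
  n <- 20000
  x <- sample_exponential_tail(n, lambda = 0.5, xmin = 0, seed = 1)
  expect_lt(abs(mean(x) - 2), 3 * 2 / sqrt(n))
  x <- sample_exponential_tail(1000, lambda = 2, xmin = 5, seed = 2)
  expect_gte(min(x), 5)
  # sigma -> 0 degenerates to exp(mu)
  x <- sample_lognormal_tail(100, mu = 1, sigma = 1e-8, seed = 3)
  expect_equal(x, rep(exp(1), 100), tolerance = 1e-5)
  x <- sample_lognormal_tail(1000, mu = 0, sigma = 1, xmin = 2, seed = 4)
  expect_gte(min(x), 2)
})
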