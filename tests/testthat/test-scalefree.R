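test_that("hurwitz_zeta matches independent references", {
  skip_if_not_installed("pracma")
  # zeta(a, q) = zeta_Riemann(a) - sum_{k < q} k^(-a)
  for (a in c(1.5, 2.5, 3.2)) for (q in c(1, 2, 137)) {
    ref <- pracma::zeta(a) - if (q > 1) sum((1:(q - 1))^(-a)) else 0
    expect_equal(hurwitz_zeta(a, q), ref, tolerance = 1e-10)
  }
  expect_equal(hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-10)
  # brute-force summation where truncation error is negligible
  expect_equal(hurwitz_zeta(3.2, 5), sum((5 + 0:2e6)^(-3.2)),
               tolerance = 1e-8)
})

test_that("the continuous exponent MLE has its closed-form properties", {
  # all x = e * xmin makes sum(log(x/xmin)) = n, so alpha-hat = 2
  x <- rep(exp(1) * 5, 50)
  expect_equal(mle_alpha(x, xmin = 5, discrete = FALSE), 2)
  # scale equivariance
  x <- sample_power_law(2000, 2.5, 1, discrete = FALSE, seed = 1)
  a1 <- mle_alpha(x, 1, discrete = FALSE)
  a2 <- mle_alpha(x * 7, 7, discrete = FALSE)
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(mle_alpha(c(2), 1), "at least 2")
})

test_that("exponent recovery at n = 50,000 is within the asymptotic band", {
  # continuous: SE = (alpha - 1)/sqrt(n) ~ 0.0067
  x <- sample_power_law(50000, 2.5, 1, discrete = FALSE, seed = 3)
  expect_lt(abs(mle_alpha(x, 1, discrete = FALSE) - 2.5), 0.03)
  # discrete, exact zeta likelihood
  x <- sample_power_law(50000, 2.5, 1, discrete = TRUE, seed = 3)
  expect_lt(abs(mle_alpha(x, 1, discrete = TRUE) - 2.5), 0.05)
  # the shifted approximation is accurate at large thresholds
  x <- sample_power_law(20000, 2.5, 20, discrete = TRUE, seed = 4)
  expect_lt(abs(mle_alpha(x, 20, method = "approx") - 2.5), 0.06)
  # degenerate tail raises
  expect_error(mle_alpha(rep(5, 20), 5, discrete = TRUE, method = "exact"),
               "degenerate")
})

test_that("ks_distance is small for quantile-matched samples and finds gross misfit", {
  n <- 200
  alpha <- 2.5
  # sample placed exactly at the model quantiles (i - 0.5)/n
  x <- 1 * (1 - (seq_len(n) - 0.5) / n)^(-1 / (alpha - 1))
  fit <- structure(list(family = "power_law", xmin = 1,
                        params = c(alpha = alpha), n_tail = n,
                        loglik = NA_real_, ks = NA_real_, n = n,
                        discrete = FALSE),
                   class = "tail_fit")
  expect_lte(ks_distance(x, fit), 0.5 / n + 1e-12)
  # constant sample vs a continuous model: at least the CDF step bound
  xc <- rep(2, 50)
  gap <- 1 - (2 / 1)^(1 - alpha)
  expect_gte(ks_distance(xc, fit), 1 - gap - 1e-12)
  expect_error(ks_distance(c(0.1, 0.5), fit), "empty tail")
})

test_that("threshold search finds the true cutoff", {
  # clean power law: xmin should stay at the bottom
  x <- sample_power_law(50000, 2.5, 1, seed = 3)
  fit <- fit_power_law(x)
  expect_lte(fit$xmin, 3)
  expect_lt(abs(fit$params[["alpha"]] - 2.5), 0.08)
  # exponential body below 20 spliced with a power-law tail above
  body <- ceiling(sample_exponential_tail(7000, 0.25, 0, seed = 5))
  body <- body[body >= 1 & body < 20]
  tail <- sample_power_law(3000, 2.5, 20, seed = 6)
  fit <- fit_power_law(c(body, tail))
  expect_gte(fit$xmin, 10)
  expect_lte(fit$xmin, 30)
})

test_that("fit_power_law agrees with an independent library implementation", {
  x <- sample_power_law(20000, 2.4, 5, seed = 9)
  ours <- fit_power_law(x)
  theirs <- igraph::fit_power_law(x, implementation = "plfit")
  expect_equal(ours$params[["alpha"]], theirs$alpha, tolerance = 0.05)
  expect_equal(ours$xmin, theirs$xmin, tolerance = 2)
})

test_that("alternative-family MLEs recover truth", {
  # exponential closed form: lambda = 1/(mean - xmin), exactly
  x <- c(4, 5, 7)  # mean 16/3 at xmin 4 -> lambda = 3/4
  f <- fit_exponential(x, xmin = 4)
  expect_equal(f$params[["lambda"]], 1 / (mean(x) - 4))
  n <- 50000
  x <- sample_exponential_tail(n, 0.5, xmin = 2, seed = 7)
  f <- fit_exponential(x, xmin = 2)
  expect_lt(abs(f$params[["lambda"]] - 0.5), 3 * 0.5 / sqrt(n))
  # log-normal numeric MLE
  x <- sample_lognormal_tail(n, mu = 1, sigma = 0.8, seed = 8)
  f <- fit_lognormal(x, xmin = 0)
  expect_lt(abs(f$params[["mu"]] - 1), 0.03)
  expect_lt(abs(f$params[["sigma"]] - 0.8), 0.03)
  # truncated recovery
  x <- sample_lognormal_tail(n, mu = 1, sigma = 0.8, xmin = 3, seed = 9)
  f <- fit_lognormal(x, xmin = 3)
  expect_lt(abs(f$params[["mu"]] - 1), 0.1)
  expect_lt(abs(f$params[["sigma"]] - 0.8), 0.05)
  # degenerate tails raise
  expect_error(fit_lognormal(rep(3, 30), xmin = 3), "degenerate|zero variance")
  expect_error(fit_exponential(rep(3, 30), xmin = 3), "degenerate")
})

test_that("the bootstrap accepts a correctly specified model and rejects a wrong one", {
  x <- sample_power_law(1000, 2.5, 1, seed = 21)
  fit <- fit_power_law(x)
  gof <- bootstrap_gof(x, fit, n_reps = 100, seed = 22)
  expect_gt(gof$p_value, 0.05)
  expect_equal(gof$n_reps, 100)
  expect_lte(gof$n_fail_to_reject, gof$n_reps)
  # Poisson-like degrees from a random graph are not power-law
  deg <- degree_sequence(generate_random_graph(3000, 3 / 2999, seed = 23))
  deg <- deg[deg >= 1]
  fit <- fit_power_law(deg)
  gof <- bootstrap_gof(deg, fit, n_reps = 100, seed = 24)
  expect_lt(gof$p_value, 0.05)
  expect_error(bootstrap_gof(x, fit, n_reps = 0), "n_reps")
})

test_that("bootstrap p-values are reproducible under a fixed seed", {
  x <- sample_power_law(500, 2.5, 1, seed = 31)
  fit <- fit_power_law(x)
  g1 <- bootstrap_gof(x, fit, n_reps = 40, seed = 5)
  g2 <- bootstrap_gof(x, fit, n_reps = 40, seed = 5)
  expect_identical(g1$ks_replicates, g2$ks_replicates)
})

test_that("the likelihood ratio identifies the generating family", {
  x <- sample_power_law(20000, 2.5, 1, seed = 11)
  pl <- fit_power_law(x, xmin = 1)
  ex <- fit_exponential(x, xmin = 1)
  r <- likelihood_ratio(x, pl, ex)
  expect_gt(r$log_ratio, 0)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$favored, "power_law")

  y <- round(sample_exponential_tail(20000, 0.3, xmin = 1, seed = 12))
  y <- y[y >= 1]
  pl <- fit_power_law(y, xmin = 1)
  ex <- fit_exponential(y, xmin = 1)
  r <- likelihood_ratio(y, pl, ex)
  expect_lt(r$log_ratio, 0)
  expect_lt(r$p_value, 0.01)

  # identical fits: R = 0, p = 1
  r <- likelihood_ratio(x, pl, pl)
  expect_equal(r$log_ratio, 0)
  expect_equal(r$p_value, 1)
  # mismatched thresholds error without refit, work with it
  ex5 <- fit_exponential(x, xmin = 5)
  expect_error(likelihood_ratio(x, pl, ex5), "different xmin")
  r <- likelihood_ratio(x, pl, ex5, refit = TRUE)
  expect_gt(r$log_ratio, 0)
})

test_that("classification separates growth networks from random ones", {
  deg <- degree_sequence(generate_pa_graph(3000, 3, seed = 41))
  v <- classify_network(deg, n_reps = 100, seed = 42)
  expect_equal(v$verdict, "scale_free")
  expect_s3_class(v$power_law, "tail_fit")
  expect_s3_class(v$gof, "gof_result")

  deg <- degree_sequence(generate_random_graph(3000, 3 / 2999, seed = 43))
  v <- classify_network(deg[deg >= 1], n_reps = 100, seed = 44)
  expect_equal(v$verdict, "not_scale_free")

  # a verdict is always produced, even for hopeless input
  v <- suppressWarnings(classify_network(rep(1, 30), n_reps = 10, seed = 1))
  expect_true(v$verdict %in% c("scale_free", "not_scale_free",
                               "inconclusive"))
})
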