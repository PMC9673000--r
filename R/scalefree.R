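# Scale-free vs alternatives for a degree sequence: maximum-likelihood
# power-law fitting with KS-minimizing threshold selection, semi-parametric
# bootstrap goodness-of-fit, exponential / log-normal tail fits, and a
# Vuong-style normalized likelihood-ratio comparison.
#
# Discrete power-law quantities use the Hurwitz zeta normalization
# zeta(alpha, xmin) = sum_{k >= xmin} k^-alpha.

#' Hurwitz zeta function
#'
#' `zeta(a, q) = sum_{j >= 0} (q + j)^(-a)` for `a > 1`, computed by
#' Euler-Maclaurin summation; normalizes the discrete power-law
#' distribution truncated at `q`.
#'
#' @param a Exponent, `> 1` (scalar).
#' @param q Shift, `> 0` (vectorized).
#' @return Numeric vector of `zeta(a, q)` values.
#' @export
#' @examples
#' hurwitz_zeta(2, 1)  # pi^2 / 6
hurwitz_zeta <- function(a, q) {
  stopifnot(a > 1, all(q > 0))
  M <- 15L
  s <- numeric(length(q))
  for (j in 0:(M - 1L)) s <- s + (q + j)^(-a)
  qM <- q + M
  s + qM^(1 - a) / (a - 1) + 0.5 * qM^(-a) + a * qM^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * qM^(-a - 3) / 720
}

# sorted-sample sufficient statistics reused across candidate thresholds:
# unique values, counts, and suffix sums of counts, values and log-values
sample_stats <- function(x) {
  xs <- sort(x)
  r <- rle(xs)
  uq <- r$values
  cnt <- r$lengths
  list(n = length(xs), uq = uq, cnt = cnt,
       ntail = rev(cumsum(rev(cnt))),
       ssum = rev(cumsum(rev(cnt * uq))),
       slog = rev(cumsum(rev(cnt * log(uq)))))
}

#' Maximum-likelihood power-law exponent
#'
#' Continuous data: `alpha = 1 + n_tail / sum(log(x_i / xmin))` (exact
#' MLE). Discrete data: either the shifted-threshold approximation
#' `alpha = 1 + n_tail / sum(log(x_i / (xmin - 1/2)))` or exact
#' maximization of the zeta likelihood. The approximation is accurate for
#' `xmin >= 10` but substantially biased at small thresholds (about -0.5
#' at `xmin = 1` for `alpha = 2.5`), so the default `"auto"` method uses
#' the exact estimator below `xmin = 10` and the approximation above.
#'
#' @param x Numeric sample (degree sequence).
#' @param xmin Lower threshold; the tail is `x >= xmin`.
#' @param discrete Integer-valued model (default `TRUE`).
#' @param method `"auto"`, `"exact"` or `"approx"` (discrete only).
#' @return The estimated exponent (`> 1`).
#' @export
#' @examples
#' x <- sample_power_law(2000, alpha = 2.5, xmin = 1, seed = 1)
#' mle_alpha(x, xmin = 1)
mle_alpha <- function(x, xmin, discrete = TRUE,
                      method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  tail <- x[x >= xmin]
  n <- length(tail)
  if (n < 2) stop("need at least 2 observations >= xmin")
  slog <- sum(log(tail))
  if (!discrete) return(1 + n / (slog - n * log(xmin)))
  if (method == "auto") method <- if (xmin < 10) "exact" else "approx"
  if (method == "approx") {
    denom <- slog - n * log(xmin - 0.5)
    if (denom <= 0) stop("degenerate tail: all values at xmin")
    return(1 + n / denom)
  }
  if (all(tail == xmin))
    stop("degenerate tail: all values equal xmin, zeta likelihood diverges")
  nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slog
  optimize(nll, c(1 + 1e-6, 50))$minimum
}

# conditional survival function of the tail (x >= xmin), computed on the
# survival scale so that far-tail evaluations never cancel
tail_surv <- function(v, family, xmin, params) {
  switch(family,
    power_law = (v / xmin)^(1 - params[["alpha"]]),
    exponential = exp(-params[["lambda"]] * (v - xmin)),
    lognormal = {
      S <- function(z) plnorm(z, params[["mu"]], params[["sigma"]],
                              lower.tail = FALSE)
      S(pmax(v, xmin)) / S(xmin)
    },
    stop("unknown family: ", family))
}

# conditional model CDF of the tail; for a discrete (unit-binned) model
# the CDF at integer k covers the whole bin [k, k+1)
tail_cdf <- function(v, family, xmin, params, discrete = FALSE) {
  if (discrete) {
    if (family == "power_law") {
      a <- params[["alpha"]]
      return(1 - hurwitz_zeta(a, v + 1) / hurwitz_zeta(a, xmin))
    }
    return(1 - tail_surv(v + 1, family, xmin, params))
  }
  1 - tail_surv(v, family, xmin, params)
}

# unit-bin probability mass P(X = k | X >= xmin) of a discrete model
tail_pmf <- function(v, family, xmin, params) {
  if (family == "power_law") {
    a <- params[["alpha"]]
    return(v^(-a) / hurwitz_zeta(a, xmin))
  }
  tail_surv(v, family, xmin, params) -
    tail_surv(v + 1, family, xmin, params)
}

# exact sup-distance between the empirical tail CDF and the model tail CDF
# from unique values v, their counts and the tail size; for discrete models
# the supremum inside gaps is attained just below each observed value,
# covered by the F(v) - pmf(v) comparison against the previous step.
ks_from_counts <- function(v, cnt, ntail, family, xmin, params, discrete) {
  Fv <- tail_cdf(v, family, xmin, params, discrete)
  hi <- cumsum(cnt) / ntail
  lo <- c(0, hi[-length(hi)])
  if (discrete) {
    pmf <- tail_pmf(v, family, xmin, params)
    max(abs(Fv - hi), abs(Fv - pmf - lo))
  } else {
    max(abs(Fv - hi), abs(Fv - lo))
  }
}

# tail-conditional log-likelihood from sufficient statistics
tail_loglik <- function(family, xmin, params, n, ssum, slog, tail = NULL,
                        discrete = FALSE) {
  switch(family,
    power_law = {
      a <- params[["alpha"]]
      if (discrete) -n * log(hurwitz_zeta(a, xmin)) - a * slog
      else n * log(a - 1) - n * log(xmin) - a * (slog - n * log(xmin))
    },
    exponential = {
      l <- params[["lambda"]]
      n * log(l) - l * (ssum - n * xmin)
    },
    lognormal = {
      mu <- params[["mu"]]; sg <- params[["sigma"]]
      if (discrete)
        sum(log(pmax(tail_pmf(tail, "lognormal", xmin, params), 1e-300)))
      else
        sum(dlnorm(tail, mu, sg, log = TRUE)) -
          n * plnorm(xmin, mu, sg, lower.tail = FALSE, log.p = TRUE)
    },
    stop("unknown family: ", family))
}

tail_fit <- function(family, xmin, params, n_tail, loglik, ks, n,
                     discrete = FALSE) {
  stopifnot(ks >= 0, ks <= 1, n_tail <= n)
  structure(list(family = family, xmin = xmin, params = params,
                 n_tail = n_tail, loglik = loglik, ks = ks, n = n,
                 discrete = discrete),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("<tail_fit> %s%s: xmin=%g, %s, n_tail=%d/%d, KS=%.6f\n",
              x$family, if (x$discrete) " (discrete)" else "",
              x$xmin,
              paste(sprintf("%s=%.6f", names(x$params), x$params),
                    collapse = ", "),
              x$n_tail, x$n, x$ks))
  invisible(x)
}

# family-specific parameter estimate at a fixed threshold; `st` are
# sample_stats, i indexes the first unique value >= xmin
estimate_params <- function(family, xmin, n, ssum, slog, tail, discrete,
                            method) {
  switch(family,
    power_law = {
      if (!discrete) {
        c(alpha = 1 + n / (slog - n * log(xmin)))
      } else {
        m <- method
        if (m == "auto") m <- if (xmin < 10) "exact" else "approx"
        if (m == "approx") {
          denom <- slog - n * log(xmin - 0.5)
          if (denom <= 0) stop("degenerate tail at xmin = ", xmin)
          c(alpha = 1 + n / denom)
        } else {
          if (n * log(xmin) >= slog - 1e-12)
            stop("degenerate tail at xmin = ", xmin)
          nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slog
          c(alpha = optimize(nll, c(1 + 1e-6, 50))$minimum)
        }
      }
    },
    exponential = {
      m <- ssum / n - xmin
      if (m <= 0) stop("degenerate tail: zero mean excess at xmin = ", xmin)
      c(lambda = 1 / m)
    },
    lognormal = {
      lx <- log(tail)
      if (length(tail) < 3) stop("lognormal fit needs >= 3 tail values")
      s0 <- sd(lx)
      if (!is.finite(s0) || s0 < 1e-10)
        stop("degenerate tail: zero variance, lognormal fit is singular")
      nll <- function(p) {
        pr <- c(mu = p[1], sigma = exp(p[2]))
        v <- if (discrete)
          -sum(log(pmax(tail_pmf(tail, "lognormal", xmin, pr), 1e-300)))
        else
          -(sum(dlnorm(tail, pr[1], pr[2], log = TRUE)) -
              length(tail) * plnorm(xmin, pr[1], pr[2],
                                    lower.tail = FALSE, log.p = TRUE))
        if (!is.finite(v)) 1e300 else v
      }
      # truncation pulls the optimum away from the tail's log-moments, so
      # try several starts and polish the best with BFGS
      starts <- list(c(mean(lx), log(s0)),
                     c(mean(lx) - 2 * s0, log(2 * s0)),
                     c(min(lx) - 1, log(max(2 * s0, 1))))
      best <- NULL
      for (s in starts) {
        o <- tryCatch(optim(s, nll, method = "Nelder-Mead",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
        if (!is.null(o) && (is.null(best) || o$value < best$value))
          best <- o
      }
      if (is.null(best)) stop("lognormal fit failed at xmin = ", xmin)
      o <- tryCatch(optim(best$par, nll, method = "BFGS"),
                    error = function(e) best)
      if (o$value > best$value) o <- best
      c(mu = o$par[1], sigma = exp(o$par[2]))
    },
    stop("unknown family: ", family))
}

# shared fitting engine: estimate parameters at each candidate threshold,
# keep the fit with smallest KS distance (smallest xmin on ties).
# Candidates keep at least min_tail observations and min_distinct distinct
# values in the tail: on discrete data a tail spanning a handful of support
# points makes the KS distance (and hence the threshold choice) meaningless,
# letting the search escape into the far tail of any distribution.
fit_tail <- function(x, family, discrete = FALSE, xmin = NULL,
                     min_tail = 10, min_distinct = 10, method = "auto",
                     max_candidates = Inf) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 observations to fit")
  if (family %in% c("power_law", "lognormal") && any(x <= 0))
    stop(family, " fit requires positive values")
  st <- sample_stats(x)
  if (length(st$uq) < 10 && is.null(xmin))
    warning("fewer than 10 distinct values; threshold search is unstable")
  # integer samples get the unit-binned (discrete) log-normal model: the
  # continuous truncated MLE degenerates (mu -> -Inf) on heavy count data
  if (family == "lognormal") discrete <- all(x == floor(x))

  if (!is.null(xmin)) {
    idx <- match(TRUE, st$uq >= xmin)
    if (is.na(idx)) stop("no observations >= xmin")
    cand_xmin <- xmin
    cand_idx <- idx
  } else {
    lo <- if (family == "power_law" && discrete) 1 else 0
    n_uq <- length(st$uq)
    distinct_tail <- n_uq - seq_len(n_uq) + 1
    admissible <- st$uq > lo - 1e-12
    if (family == "power_law" && discrete) admissible <- admissible & st$uq >= 1
    ok <- admissible & st$ntail >= max(min_tail, 2) &
      distinct_tail >= min_distinct
    if (!any(ok)) ok <- admissible & st$ntail >= max(min_tail, 2)
    if (!any(ok)) {
      ok <- admissible & st$ntail >= 2
      if (!any(ok)) stop("no admissible threshold candidates")
      warning("tail size cap n_tail >= ", max(min_tail, 2),
              " left no candidates; relaxed to n_tail >= 2")
    }
    cand_idx <- which(ok)
    if (is.finite(max_candidates) && length(cand_idx) > max_candidates) {
      keep <- unique(round(seq(1, length(cand_idx),
                               length.out = max_candidates)))
      cand_idx <- cand_idx[keep]
    }
    cand_xmin <- st$uq[cand_idx]
  }

  best <- NULL
  for (j in seq_along(cand_idx)) {
    i <- cand_idx[j]
    xm <- cand_xmin[j]
    n_t <- st$ntail[i]
    v <- st$uq[i:length(st$uq)]
    cn <- st$cnt[i:length(st$cnt)]
    tl <- if (family == "lognormal") rep(v, cn) else NULL
    pars <- tryCatch(
      estimate_params(family, xm, n_t, st$ssum[i], st$slog[i], tl,
                      discrete, method),
      error = function(e) NULL)
    if (is.null(pars)) next
    ks <- ks_from_counts(v, cn, n_t, family, xm, pars,
                         discrete && family != "exponential")
    if (is.null(best) || ks < best$ks) {
      ll <- tail_loglik(family, xm, pars, n_t, st$ssum[i], st$slog[i],
                        tail = if (family == "lognormal") tl else NULL,
                        discrete = discrete)
      best <- list(xmin = xm, params = pars, n_tail = n_t,
                   loglik = ll, ks = ks)
    }
  }
  if (is.null(best))
    stop("no admissible ", family, " fit (degenerate tails at every ",
         "candidate threshold)")
  tail_fit(family, best$xmin, best$params, best$n_tail, best$loglik,
           best$ks, st$n,
           discrete = discrete && family %in% c("power_law", "lognormal"))
}

#' Fit a power-law tail
#'
#' For each candidate threshold among the sorted unique sample values
#' (capped so that at least `min_tail` observations remain in the tail),
#' estimates the exponent by maximum likelihood (see [mle_alpha()]) and
#' the Kolmogorov-Smirnov distance between the empirical and fitted tail;
#' returns the fit minimizing the KS distance, preferring the smallest
#' threshold on ties.
#'
#' @param x Numeric sample (degree sequence).
#' @param discrete Integer-valued model (default `TRUE`).
#' @param xmin Optional fixed threshold; skips the search.
#' @param min_tail Smallest admissible tail size during the threshold
#'   search (default 10; estimates below that are unstable).
#' @param min_distinct Smallest number of distinct tail values a candidate
#'   threshold may leave (default 10): on degree data a tail spanning a
#'   handful of support points makes the KS distance uninformative and
#'   lets the search escape into the far tail of any distribution.
#' @param method Discrete exponent estimator, see [mle_alpha()].
#' @return A `tail_fit` object with fields `family`, `xmin`, `params`
#'   (`alpha`), `n_tail`, `loglik`, `ks`.
#' @export
#' @examples
#' x <- sample_power_law(5000, alpha = 2.5, xmin = 1, seed = 1)
#' fit_power_law(x)
fit_power_law <- function(x, discrete = TRUE, xmin = NULL, min_tail = 10,
                          min_distinct = 10, method = "auto") {
  fit_tail(x, "power_law", discrete = discrete, xmin = xmin,
           min_tail = min_tail, min_distinct = min_distinct,
           method = method)
}

#' Fit an exponential tail
#'
#' Left-truncated exponential MLE `lambda = 1 / (mean(tail) - xmin)`. With
#' `xmin = NULL` the threshold is chosen by the same KS-minimizing search
#' as [fit_power_law()].
#'
#' @inheritParams fit_power_law
#' @return A `tail_fit` object (`params` holds `lambda`).
#' @export
fit_exponential <- function(x, xmin = NULL, min_tail = 10,
                            min_distinct = 10) {
  fit_tail(x, "exponential", xmin = xmin, min_tail = min_tail,
           min_distinct = min_distinct)
}

#' Fit a log-normal tail
#'
#' Numerical MLE of `(mu, sigma)` for the log-normal distribution
#' left-truncated at `xmin` (Nelder-Mead on the truncated likelihood,
#' started at the tail's log-moments). With `xmin = NULL` the threshold is
#' chosen by the KS-minimizing search.
#'
#' @inheritParams fit_power_law
#' @param max_candidates Cap on the number of thresholds examined during
#'   the search (quantile-spaced thinning); each candidate costs one
#'   numerical optimization.
#' @return A `tail_fit` object (`params` holds `mu` and `sigma`).
#' @export
fit_lognormal <- function(x, xmin = NULL, min_tail = 10,
                          min_distinct = 10, max_candidates = Inf) {
  fit_tail(x, "lognormal", xmin = xmin, min_tail = min_tail,
           min_distinct = min_distinct, max_candidates = max_candidates)
}

#' Kolmogorov-Smirnov distance between a sample tail and a fitted model
#'
#' Maximum absolute difference between the empirical CDF of the tail
#' (`x >= xmin`) and the fitted model CDF, both conditioned on the tail.
#' The supremum is evaluated exactly (both CDF steps at every observed
#' value, and for discrete models the gap just below each support point).
#'
#' @param x Numeric sample.
#' @param fit A `tail_fit`.
#' @return KS distance in `[0, 1]`.
#' @export
ks_distance <- function(x, fit) {
  stopifnot(inherits(fit, "tail_fit"))
  tail <- sort(x[x >= fit$xmin])
  if (length(tail) == 0) stop("empty tail: no observations >= xmin")
  r <- rle(tail)
  ks_from_counts(r$values, r$lengths, length(tail), fit$family, fit$xmin,
                 fit$params, fit$discrete)
}

# draw n values from the fitted tail model
sample_fitted_tail <- function(fit, n) {
  p <- fit$params
  switch(fit$family,
    power_law = {
      if (fit$discrete) rpl_discrete(n, p[["alpha"]], fit$xmin)
      else fit$xmin * (1 - runif(n))^(-1 / (p[["alpha"]] - 1))
    },
    exponential = fit$xmin + rexp(n, p[["lambda"]]),
    lognormal = {
      p0 <- if (fit$xmin > 0) plnorm(fit$xmin, p[["mu"]], p[["sigma"]]) else 0
      x <- qlnorm(p0 + runif(n) * (1 - p0), p[["mu"]], p[["sigma"]])
      if (fit$discrete) pmax(floor(x), fit$xmin) else x
    })
}

gof_result <- function(n_reps, p_value, n_fail_to_reject, ks_observed,
                       ks_replicates, seed) {
  structure(list(n_reps = n_reps, p_value = p_value,
                 n_fail_to_reject = n_fail_to_reject,
                 ks_observed = ks_observed, ks_replicates = ks_replicates,
                 seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "<gof_result> %d bootstrap replicates: p = %.4f (KS_obs = %.5f); %d/%d replicates individually fail to reject at 0.05\n",
    x$n_reps, x$p_value, x$ks_observed, x$n_fail_to_reject, x$n_reps))
  invisible(x)
}

#' Semi-parametric bootstrap goodness-of-fit test
#'
#' Calibrates the plausibility of a fitted tail model following the
#' Clauset-Shalizi-Newman recipe: each replicate draws `n` values - with
#' probability `n_tail / n` from the fitted tail model, otherwise
#' uniformly from the empirical body below the threshold - refits the same
#' family including a fresh threshold search, and records the replicate KS
#' distance. The p-value is the fraction of replicates whose KS distance
#' is at least the observed one; large p means the model is plausible.
#' `n_fail_to_reject` additionally counts replicates whose refit KS
#' distance falls below the asymptotic level-0.05 critical value
#' `1.358 / sqrt(n_tail)`, the per-replicate reading of a "failed to
#' reject" tally.
#'
#' @param x Numeric sample the fit was obtained from.
#' @param fit A `tail_fit` for `x`.
#' @param n_reps Number of bootstrap replicates (default 2500).
#' @param seed Optional seed for the replicate stream.
#' @param min_tail Tail-size cap passed to the per-replicate refit.
#' @param max_candidates Candidate-threshold cap for the per-replicate
#'   refit (mainly for the log-normal family, where each candidate costs a
#'   numerical optimization).
#' @return A `gof_result` with `n_reps`, `p_value`, `n_fail_to_reject`,
#'   the observed KS distance and the per-replicate KS distances.
#' @export
#' @examples
#' x <- sample_power_law(300, alpha = 2.5, xmin = 1, seed = 1)
#' fit <- fit_power_law(x)
#' bootstrap_gof(x, fit, n_reps = 50, seed = 2)
bootstrap_gof <- function(x, fit, n_reps = 2500, seed = NULL,
                          min_tail = 10, max_candidates = Inf) {
  stopifnot(inherits(fit, "tail_fit"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  x <- as.numeric(x)
  n <- length(x)
  body <- x[x < fit$xmin]
  ptail <- fit$n_tail / n
  ks_rep <- rep(NA_real_, n_reps)
  nt_rep <- rep(NA_integer_, n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      k <- rbinom(1, n, ptail)
      if (length(body) == 0) k <- n
      synth <- c(sample_fitted_tail(fit, k),
                 if (n - k > 0) sample(body, n - k, replace = TRUE))
      rf <- tryCatch(
        suppressWarnings(
          fit_tail(synth, fit$family, discrete = fit$discrete,
                   min_tail = min_tail, max_candidates = max_candidates)),
        error = function(e) NULL)
      if (!is.null(rf)) {
        ks_rep[r] <- rf$ks
        nt_rep[r] <- rf$n_tail
      }
    }
  })
  ok <- !is.na(ks_rep)
  if (!any(ok)) stop("all bootstrap replicates failed to refit")
  p <- mean(ks_rep[ok] >= fit$ks)
  nfail <- sum(ks_rep[ok] < 1.358 / sqrt(nt_rep[ok]))
  gof_result(n_reps, p, nfail, fit$ks, ks_rep, seed)
}

# pointwise log probability mass of the tail under a fit; for integer data
# continuous families are discretized to P(k <= X < k+1 | X >= xmin) so
# that families are compared on the same scale
pointwise_logmass <- function(tail, fit, discretize) {
  p <- fit$params
  if (fit$discrete || discretize)
    return(log(pmax(tail_pmf(tail, fit$family, fit$xmin, p), 1e-300)))
  switch(fit$family,
    power_law = log(p[["alpha"]] - 1) - log(fit$xmin) -
      p[["alpha"]] * log(tail / fit$xmin),
    exponential = log(p[["lambda"]]) - p[["lambda"]] * (tail - fit$xmin),
    lognormal = dlnorm(tail, p[["mu"]], p[["sigma"]], log = TRUE) -
      plnorm(fit$xmin, p[["mu"]], p[["sigma"]], lower.tail = FALSE,
             log.p = TRUE))
}

lrt_result <- function(log_ratio, normalized, p_value, families) {
  favored <- if (abs(log_ratio) < 1e-12) "none"
  else if (log_ratio > 0) families[1] else families[2]
  structure(list(log_ratio = log_ratio, normalized = normalized,
                 p_value = p_value, families = families, favored = favored),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "<lrt_result> %s vs %s: R = %.4f (normalized %.4f, p = %.4g); favored: %s\n",
    x$families[1], x$families[2], x$log_ratio, x$normalized, x$p_value,
    x$favored))
  invisible(x)
}

#' Likelihood-ratio comparison of two tail fits
#'
#' Vuong-style normalized log-likelihood ratio over the common tail:
#' `R = sum_i [log pA(x_i) - log pB(x_i)]`, normalized by
#' `sd(pointwise ratios) * sqrt(n_tail)`, with a two-sided normal
#' p-value. Positive `R` favors `fitA`; a small p-value makes the sign
#' meaningful. Both fits must share the same threshold; with
#' `refit = TRUE`, `fitB` is refitted at `fitA`'s threshold first. When
#' `fitA` is a discrete power law and the tail is integer-valued,
#' continuous competitors are discretized to unit probability masses so
#' the comparison is like for like.
#'
#' @param x Numeric sample both fits refer to.
#' @param fitA,fitB `tail_fit` objects.
#' @param refit Refit `fitB`'s family at `fitA`'s threshold when the
#'   thresholds differ (default `FALSE`: differing thresholds are an
#'   error).
#' @return An `lrt_result` with `log_ratio`, `normalized`, `p_value` and
#'   the favored family.
#' @export
likelihood_ratio <- function(x, fitA, fitB, refit = FALSE) {
  stopifnot(inherits(fitA, "tail_fit"), inherits(fitB, "tail_fit"))
  if (!isTRUE(all.equal(fitA$xmin, fitB$xmin))) {
    if (!refit)
      stop("fits have different xmin (", fitA$xmin, " vs ", fitB$xmin,
           "); pass refit = TRUE to refit fitB at fitA's threshold")
    fitB <- fit_tail(x, fitB$family, discrete = fitB$discrete,
                     xmin = fitA$xmin)
  }
  tail <- x[x >= fitA$xmin]
  n <- length(tail)
  # when one fit is a unit-binned count model and the tail is integer,
  # compare both on the probability-mass scale
  discretize <- (fitA$discrete || fitB$discrete) && all(tail == floor(tail))
  lA <- pointwise_logmass(tail, fitA, discretize = discretize)
  lB <- pointwise_logmass(tail, fitB, discretize = discretize)
  li <- lA - lB
  R <- sum(li)
  s <- sd(li)
  if (!is.finite(s) || s < 1e-12) {
    return(lrt_result(0, 0, 1, c(fitA$family, fitB$family)))
  }
  z <- R / (s * sqrt(n))
  lrt_result(R, z, 2 * pnorm(-abs(z)), c(fitA$family, fitB$family))
}

#' Classify a degree sequence as scale-free or not
#'
#' Runs the full decision procedure: power-law fit with threshold search,
#' semi-parametric bootstrap goodness-of-fit, exponential and log-normal
#' fits at the power-law threshold, and likelihood-ratio comparisons. The
#' verdict is `"scale_free"` when the bootstrap p-value is at least 0.1
#' and no alternative family is significantly favored (likelihood-ratio
#' p < 0.05 with the ratio pointing at the alternative);
#' `"not_scale_free"` when the bootstrap p-value is below 0.1 or an
#' alternative wins; `"inconclusive"` when the power-law fit itself is
#' degenerate (e.g. too few distinct tail values to test).
#'
#' @param x Degree sequence (positive integers).
#' @param n_reps Bootstrap replicates (default 2500).
#' @param seed Optional seed driving the bootstrap.
#' @param discrete Fit the discrete power law (default `TRUE`).
#' @param min_tail Tail-size cap for threshold searches.
#' @return A `network_verdict`: list with `verdict`, the three `tail_fit`s
#'   (`power_law`, `exponential`, `lognormal`), `gof`, and the two
#'   `lrt_result`s (`lrt_exponential`, `lrt_lognormal`).
#' @export
#' @examples
#' deg <- degree_sequence(generate_pa_graph(800, 3, seed = 1))
#' classify_network(deg[deg > 0], n_reps = 50, seed = 2)$verdict
classify_network <- function(x, n_reps = 2500, seed = NULL,
                             discrete = TRUE, min_tail = 10) {
  x <- as.numeric(x)
  pl <- tryCatch(fit_power_law(x, discrete = discrete, min_tail = min_tail),
                 error = function(e) e)
  if (inherits(pl, "error")) {
    return(structure(list(verdict = "inconclusive", reason = pl$message,
                          power_law = NULL, gof = NULL,
                          exponential = NULL, lognormal = NULL,
                          lrt_exponential = NULL, lrt_lognormal = NULL),
                     class = "network_verdict"))
  }
  gof <- bootstrap_gof(x, pl, n_reps = n_reps,
                       seed = child_seed(seed, 1), min_tail = min_tail)
  fe <- tryCatch(fit_exponential(x, xmin = pl$xmin), error = function(e) NULL)
  fl <- tryCatch(fit_lognormal(x, xmin = pl$xmin), error = function(e) NULL)
  lrt_e <- if (!is.null(fe)) likelihood_ratio(x, pl, fe) else NULL
  lrt_l <- if (!is.null(fl)) likelihood_ratio(x, pl, fl) else NULL
  alt_wins <- function(lrt) !is.null(lrt) && lrt$p_value < 0.05 &&
    lrt$log_ratio < 0
  verdict <- if (gof$p_value < 0.1 || alt_wins(lrt_e) || alt_wins(lrt_l))
    "not_scale_free"
  else "scale_free"
  structure(list(verdict = verdict, power_law = pl, gof = gof,
                 exponential = fe, lognormal = fl,
                 lrt_exponential = lrt_e, lrt_lognormal = lrt_l),
            class = "network_verdict")
}

#' @export
print.network_verdict <- function(x, ...) {
  cat(sprintf("<network_verdict> %s\n", x$verdict))
  if (!is.null(x$power_law)) print(x$power_law)
  if (!is.null(x$gof)) print(x$gof)
  if (!is.null(x$lrt_exponential)) print(x$lrt_exponential)
  if (!is.null(x$lrt_lognormal)) print(x$lrt_lognormal)
  invisible(x)
}
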