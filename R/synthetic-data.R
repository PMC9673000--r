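# Seeded generators: a schema-conforming malpractice-network emulator with
# tunable preferential attachment, reference graphs (Barabasi-Albert,
# Erdos-Renyi), and exact tail samplers (power law, exponential,
# log-normal) for testing the distribution-fitting stage.

#' Parameters of the synthetic malpractice-network generator
#'
#' Defaults mirror the litigation corpus the schema models: 6,610 claims
#' against 351 tertiary hospitals across 38 specialties, 23 disease
#' groups, 20 comorbidity categories, errors found in 4821/6610 of cases,
#' a mean of 1 + 6201/4821 errors per errorful case (so that one `Error`
#' link plus an `Order` chain per errorful case reproduces the published
#' link tallies), and comorbidity records in 2097/6610 of cases. Outcome
#' severities are not published; the default mix (none .15, minor .35,
#' severe .25, death .20, mental-only .05) is a plausible severity profile
#' for litigated cases.
#'
#' @param n_cases Number of claims (one patient and one claim per case).
#' @param n_hospitals,n_specialties Pool sizes for hospitals and
#'   specialties.
#' @param n_disease_groups Disease-group pool size (at most 23, the ICD-10
#'   chapter count used by the schema).
#' @param n_comorbidity_kinds Comorbidity-category pool size (at most 20).
#' @param error_rate Probability that a case has at least one error.
#' @param mean_errors_per_errorful_case Target mean of the per-case error
#'   count (truncated geometric on 1..8).
#' @param attachment_strength Exponent `beta` of the rich-get-richer rule:
#'   hospitals, specialties, diseases, comorbidity kinds and error labels
#'   are chosen with probability proportional to
#'   `(current degree + 1)^beta`; 0 gives uniform choice.
#' @param outcome_probs Probabilities of the five [outcome_levels()],
#'   summing to 1.
#' @param comorbidity_rate Probability that a case records a comorbidity.
#' @param seed Integer seed; the generator is a pure function of
#'   parameters and seed.
#' @return An object of class `mmnc_gen_params`.
#' @export
mmnc_gen_params <- function(n_cases = 6610, n_hospitals = 351,
                            n_specialties = 38, n_disease_groups = 23,
                            n_comorbidity_kinds = 20,
                            error_rate = 4821 / 6610,
                            mean_errors_per_errorful_case = 1 + 6201 / 4821,
                            attachment_strength = 1,
                            outcome_probs = c(0.15, 0.35, 0.25, 0.20, 0.05),
                            comorbidity_rate = 2097 / 6610,
                            seed = 1) {
  stopifnot(n_cases >= 1, n_hospitals >= 1, n_specialties >= 1,
            n_disease_groups >= 1, n_comorbidity_kinds >= 1)
  if (n_disease_groups > 23) stop("at most 23 disease groups")
  if (n_comorbidity_kinds > 20) stop("at most 20 comorbidity categories")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (comorbidity_rate < 0 || comorbidity_rate > 1)
    stop("comorbidity_rate must be in [0, 1]")
  if (mean_errors_per_errorful_case < 1 ||
      mean_errors_per_errorful_case > 8)
    stop("mean_errors_per_errorful_case must be in [1, 8]")
  if (attachment_strength < 0) stop("attachment_strength must be >= 0")
  if (length(outcome_probs) != 5 || any(outcome_probs < 0) ||
      abs(sum(outcome_probs) - 1) > 1e-12)
    stop("outcome_probs must be 5 nonnegative values summing to 1")
  structure(list(n_cases = as.integer(n_cases),
                 n_hospitals = as.integer(n_hospitals),
                 n_specialties = as.integer(n_specialties),
                 n_disease_groups = as.integer(n_disease_groups),
                 n_comorbidity_kinds = as.integer(n_comorbidity_kinds),
                 error_rate = error_rate,
                 mean_errors_per_errorful_case = mean_errors_per_errorful_case,
                 attachment_strength = attachment_strength,
                 outcome_probs = outcome_probs,
                 comorbidity_rate = comorbidity_rate,
                 seed = seed),
            class = "mmnc_gen_params")
}

# success probability of a geometric distribution truncated to 1..kmax
# with the requested mean
truncated_geom_p <- function(target_mean, kmax = 8) {
  if (target_mean <= 1 + 1e-9) return(1)
  mean_tg <- function(p) {
    k <- seq_len(kmax)
    w <- p * (1 - p)^(k - 1)
    sum(k * w) / sum(w)
  }
  if (target_mean >= mean_tg(1e-9)) stop("target mean not attainable on 1..", kmax)
  uniroot(function(p) mean_tg(p) - target_mean, c(1e-9, 1 - 1e-9))$root
}

rtruncgeom <- function(n, p, kmax = 8) {
  k <- seq_len(kmax)
  w <- p * (1 - p)^(k - 1)
  sample(k, n, replace = TRUE, prob = w)
}

#' Generate a synthetic malpractice knowledge graph
#'
#' Emulates the schema of the litigation corpus: each case contributes one
#' patient and one claim, a hospital, an admission specialty, a disease
#' group, optionally a comorbidity, an outcome severity, and - when errors
#' were found - an ordered chain of distinct error labels. Hospitals,
#' specialties, diseases, comorbidity kinds and error labels are chosen
#' with probability proportional to `(current degree + 1)^beta`
#' (preferential attachment), producing a heavy-tailed degree profile for
#' `beta > 0`. Per case the generator emits one `SufferFrom`,
#' `SeekMedicalAdvice`, `Affiliated` and `AcceptJudgment` link, two `Sue`
#' links (outcome-to-claim and patient-to-hospital), at most one `With`
#' link, and - for errorful cases - one `Cause` link, one `Error` link to
#' the first error and `Order` links chaining the remaining errors. The
#' output always passes [validate_graph()] and
#' [case_cardinality_checks()].
#'
#' @param params An [mmnc_gen_params()] object.
#' @return A [malpractice_graph()] with case-attributed edges.
#' @export
#' @examples
#' g <- generate_mmnc(mmnc_gen_params(n_cases = 50, seed = 7))
#' nrow(validate_graph(g)) == 0
generate_mmnc <- function(params = mmnc_gen_params()) {
  stopifnot(inherits(params, "mmnc_gen_params"))
  p <- params
  reg <- error_registry()
  if (nrow(reg) < 8) stop("error registry too small")
  hosp_ids <- sprintf("H%03d", seq_len(p$n_hospitals))
  spec_ids <- sprintf("S%02d", seq_len(p$n_specialties))
  dis_ids <- sprintf("disease group %02d", seq_len(p$n_disease_groups))
  com_ids <- sprintf("comorbidity %02d", seq_len(p$n_comorbidity_kinds))
  err_ids <- reg$label
  outs <- outcome_levels()

  beta <- p$attachment_strength
  deg_h <- numeric(p$n_hospitals)
  deg_s <- numeric(p$n_specialties)
  deg_d <- numeric(p$n_disease_groups)
  deg_c <- numeric(p$n_comorbidity_kinds)
  deg_e <- numeric(length(err_ids))
  pick <- function(deg, k = 1) {
    w <- (deg + 1)^beta
    sample.int(length(deg), k, replace = FALSE, prob = w)
  }

  geom_p <- truncated_geom_p(p$mean_errors_per_errorful_case)
  cases <- vector("list", p$n_cases)
  with_seed(p$seed, {
    errorful <- runif(p$n_cases) < p$error_rate
    with_com <- runif(p$n_cases) < p$comorbidity_rate
    outcome_i <- sample.int(5, p$n_cases, replace = TRUE,
                            prob = p$outcome_probs)
    for (i in seq_len(p$n_cases)) {
      h <- pick(deg_h); s <- pick(deg_s); d <- pick(deg_d)
      cm <- if (with_com[i]) pick(deg_c) else integer()
      errs <- integer()
      if (errorful[i]) {
        k <- rtruncgeom(1, geom_p)
        errs <- pick(deg_e, k)
      }
      cases[[i]] <- list(
        case = sprintf("C%05d", i),
        patient = sprintf("P%05d", i),
        hospital = hosp_ids[h],
        specialty = spec_ids[s],
        disease = dis_ids[d],
        comorbidities = com_ids[cm],
        outcome = outs[outcome_i[i]],
        errors = err_ids[errs])
      # rich-get-richer: credit each entity with the incident links it
      # gained in this case
      deg_h[h] <- deg_h[h] + 3 + (length(errs) > 0)
      deg_s[s] <- deg_s[s] + 2
      deg_d[d] <- deg_d[d] + 1
      if (length(cm)) deg_c[cm] <- deg_c[cm] + 1
      if (length(errs)) {
        deg_e[errs] <- deg_e[errs] + 1  # Order chain links
        deg_e[errs[1]] <- deg_e[errs[1]] + 1  # Error link
      }
    }
  })
  graph_from_cases(cases)
}

#' Assemble a malpractice graph from case records
#'
#' Builds the typed graph from a list of case records (the JSON-lines
#' exchange format): each record names the case, patient, hospital,
#' specialty, disease, comorbidities (possibly none), outcome level, and
#' the chronologically ordered error labels (possibly none). All
#' case-scoped edges carry the case identifier, which enables the per-case
#' cardinality and `Order`-chain audits.
#'
#' @param cases List of case records (see [read_cases_jsonl()]).
#' @return A [malpractice_graph()].
#' @export
graph_from_cases <- function(cases) {
  stopifnot(is.list(cases), length(cases) >= 1)
  pat <- vapply(cases, `[[`, "", "patient")
  clm <- vapply(cases, `[[`, "", "case")
  hos <- vapply(cases, `[[`, "", "hospital")
  spc <- vapply(cases, `[[`, "", "specialty")
  dis <- vapply(cases, `[[`, "", "disease")
  out <- vapply(cases, `[[`, "", "outcome")
  if (anyDuplicated(clm)) stop("duplicated case identifiers")
  if (anyDuplicated(pat)) stop("duplicated patient identifiers")

  nodes <- rbind(
    data.frame(id = pat, kind = "P", label = pat),
    data.frame(id = clm, kind = "C", label = clm),
    data.frame(id = unique(hos), kind = "H", label = unique(hos)),
    data.frame(id = unique(spc), kind = "S", label = unique(spc)),
    data.frame(id = unique(dis), kind = "D", label = unique(dis)),
    data.frame(id = unique(out), kind = "O", label = unique(out))
  )
  coms <- unique(unlist(lapply(cases, `[[`, "comorbidities")))
  if (length(coms))
    nodes <- rbind(nodes, data.frame(id = coms, kind = "CD", label = coms))
  errs <- unique(unlist(lapply(cases, `[[`, "errors")))
  if (length(errs))
    nodes <- rbind(nodes, data.frame(id = errs, kind = "E", label = errs))

  el <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    from <- c(cs$patient, cs$patient, cs$specialty, cs$hospital,
              cs$outcome, cs$patient)
    to <- c(cs$disease, cs$specialty, cs$hospital, cs$case,
            cs$case, cs$hospital)
    rel <- c("SufferFrom", "SeekMedicalAdvice", "Affiliated",
             "AcceptJudgment", "Sue", "Sue")
    for (cm in cs$comorbidities) {
      from <- c(from, cs$patient); to <- c(to, cm); rel <- c(rel, "With")
    }
    ne <- length(cs$errors)
    if (ne > 0) {
      from <- c(from, cs$hospital, cs$outcome)
      to <- c(to, cs$errors[1], cs$case)
      rel <- c(rel, "Error", "Cause")
      if (ne > 1) {
        from <- c(from, cs$errors[-ne])
        to <- c(to, cs$errors[-1])
        rel <- c(rel, rep("Order", ne - 1))
      }
    }
    el[[i]] <- data.frame(from = from, to = to, relation = rel,
                          case = cs$case, stringsAsFactors = FALSE)
  }
  malpractice_graph(nodes, do.call(rbind, el))
}

#' Generate a preferential-attachment (Barabasi-Albert) reference graph
#'
#' Standard growth process: starting from a single node, each new node
#' attaches `m` edges to existing nodes with probability proportional to
#' their degree. Edges are oriented from the newer node to the older
#' (chronological direction); the total-degree sequence is that of the
#' classic undirected process. Nodes are untyped.
#'
#' @param n Number of nodes (`> m`).
#' @param m Edges attached by each new node (`>= 1`).
#' @param seed Integer seed.
#' @return A [malpractice_graph()] with untyped nodes.
#' @export
#' @examples
#' g <- generate_pa_graph(10, 1, seed = 1)
#' n_relationships(g)  # a tree: 9 edges
generate_pa_graph <- function(n, m, seed = NULL) {
  if (m < 1) stop("m must be >= 1")
  if (n <= m) stop("n must exceed m")
  ig <- with_seed(seed,
                  igraph::sample_pa(n, power = 1, m = m, directed = FALSE))
  e <- igraph::as_edgelist(ig, names = FALSE)
  ids <- sprintf("v%04d", seq_len(n))
  malpractice_graph(
    nodes = data.frame(id = ids),
    edges = data.frame(from = ids[pmax(e[, 1], e[, 2])],
                       to = ids[pmin(e[, 1], e[, 2])]))
}

#' Generate an Erdos-Renyi reference digraph
#'
#' Each ordered pair of distinct nodes is linked independently with
#' probability `p`, giving the Poisson-like (bell-shaped) degree
#' distribution of a random network. Nodes are untyped.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [malpractice_graph()] with untyped nodes.
#' @export
#' @examples
#' n_relationships(generate_random_graph(4, 1, seed = 1))  # 12 = n(n-1)
generate_random_graph <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  ig <- with_seed(seed, igraph::sample_gnp(n, p, directed = TRUE))
  e <- igraph::as_edgelist(ig, names = FALSE)
  ids <- sprintf("v%04d", seq_len(n))
  ed <- if (nrow(e)) data.frame(from = ids[e[, 1]], to = ids[e[, 2]])
  else data.frame(from = character(), to = character())
  malpractice_graph(nodes = data.frame(id = ids), edges = ed)
}

# discrete power-law draw by cumulative search over the exact pmf, with
# the rounded continuous inverse CDF for the far tail (beyond 10^6)
rpl_discrete <- function(n, alpha, xmin) {
  u <- runif(n)
  approx_quantile <- function(uu)
    floor((xmin - 0.5) * (1 - uu)^(-1 / (alpha - 1)) + 0.5)
  K <- min(1e6, max(xmin + 10, 2 * approx_quantile(max(u)) + 10))
  Z <- hurwitz_zeta(alpha, xmin)
  cum <- cumsum((xmin:K)^(-alpha)) / Z
  out <- xmin + findInterval(u, cum)
  over <- u > cum[length(cum)]
  if (any(over)) out[over] <- pmax(approx_quantile(u[over]), K + 1)
  as.numeric(out)
}

#' Sample from a power-law distribution
#'
#' Continuous: inverse-CDF draw `x = xmin * (1 - u)^(-1/(alpha - 1))`.
#' Discrete: exact cumulative search over `P(X = k)` proportional to
#' `k^(-alpha)`, `k >= xmin`, switching to the rounded continuous
#' approximation beyond `k = 10^6` where the remaining mass is negligible.
#'
#' @param n Sample size.
#' @param alpha Exponent, `> 1` (the distribution is non-normalizable
#'   otherwise).
#' @param xmin Lower threshold (`>= 1` for the discrete sampler).
#' @param discrete Integer draws (default `TRUE`).
#' @param seed Optional seed.
#' @return Numeric vector of `n` draws, all `>= xmin`.
#' @export
#' @examples
#' x <- sample_power_law(1000, alpha = 2.5, xmin = 1, seed = 3)
#' mean(x == 1)  # about 1/zeta(2.5) = 0.745
sample_power_law <- function(n, alpha, xmin = 1, discrete = TRUE,
                             seed = NULL) {
  if (alpha <= 1) stop("alpha must exceed 1 (non-normalizable otherwise)")
  stopifnot(n >= 1, xmin >= if (discrete) 1 else .Machine$double.xmin)
  with_seed(seed, {
    if (discrete) rpl_discrete(n, alpha, xmin)
    else xmin * (1 - runif(n))^(-1 / (alpha - 1))
  })
}

#' Sample from an exponential tail
#'
#' Draws from the exponential distribution left-truncated at `xmin`
#' (shift representation: `xmin + Exp(lambda)`).
#'
#' @param n Sample size.
#' @param lambda Rate, `> 0`.
#' @param xmin Truncation point (default 0).
#' @param seed Optional seed.
#' @return Numeric vector of `n` draws, all `>= xmin`.
#' @export
sample_exponential_tail <- function(n, lambda, xmin = 0, seed = NULL) {
  if (lambda <= 0) stop("lambda must be positive")
  with_seed(seed, xmin + rexp(n, lambda))
}

#' Sample from a log-normal tail
#'
#' Inverse-CDF draws from the log-normal distribution left-truncated at
#' `xmin`.
#'
#' @param n Sample size.
#' @param mu,sigma Log-scale mean and standard deviation (`sigma > 0`).
#' @param xmin Truncation point (default 0, i.e. untruncated).
#' @param seed Optional seed.
#' @return Numeric vector of `n` draws, all `>= xmin`.
#' @export
sample_lognormal_tail <- function(n, mu, sigma, xmin = 0, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  p0 <- if (xmin > 0) plnorm(xmin, mu, sigma) else 0
  with_seed(seed, qlnorm(p0 + runif(n) * (1 - p0), mu, sigma))
}
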