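---
title: "Methods: scale-free analysis of a malpractice claims network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scale-free analysis of a malpractice claims network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malnet)
```

## The problem and the data model

Medical malpractice claims are not isolated events: the same hospitals,
specialties and error types recur across cases. `malnet` represents a
corpus of litigated claims as a typed, directed knowledge graph and asks
two questions about it: *is the network scale-free* (a power-law degree
distribution, implying a few dominant hubs) *rather than random* (a
Poisson-like, bell-shaped degree distribution), and *which nodes are the
hubs*?

The schema has eight node kinds — patients (`P`), hospitals (`H`),
specialties (`S`), outcome severities (`O`, five levels adapted from the
WHO International Classification for Patient Safety), claims (`C`),
comorbidity categories (`CD`, at most 20 Charlson groups), error types
(`E`, flagged technical vs nontechnical), and disease groups (`D`, at
most 23 ICD-10 chapters) — and nine relationship kinds whose admissible
endpoints are tabulated by `relation_kinds()`. Edges are directed in the
chronological order of the underlying events: a patient *suffers from* a
disease, *seeks medical advice* from a specialty *affiliated* with a
hospital, the hospital commits *errors* (chained by *order* of
occurrence), negligence *causes* the outcome, the patient and the outcome
*sue*, and the hospital *accepts the judgment*. A complete case therefore
carries exactly two `Sue` links and one each of `SufferFrom`,
`SeekMedicalAdvice`, `Affiliated` and `AcceptJudgment`;
`case_cardinality_checks()` audits these identities and
`validate_graph()` enforces the full schema (endpoint kinds, vocabulary,
acyclic per-case `Order` chains).

Two readings of the schema were genuinely open and are fixed here as
design choices. First, the `Cause` relationship is typed outcome-to-claim
(`O -> C`) even though it is described as hospital negligence causing the
outcome; the typed endpoints are the machine-checkable statement, so they
win. Second, one `Error` link is emitted per errorful case (to the first
error of the chain) rather than one per error occurrence: this is the
only reading under which the number of `Cause` links equals the number of
`Error` links while `Order` links still outnumber zero, as the published
corpus tallies require.

## The synthetic corpus generator

The original litigation texts are not redistributable, so
`generate_mmnc()` emulates the corpus: its contract is schema conformity
plus a tunable heavy tail, *not* statistical realism. Defaults mirror the
published study conditions: 6,610 claims against 351 hospitals across 38
specialties, 23 disease groups and 20 comorbidity categories; errors
found in 4821/6610 of cases; a mean of 1 + 6201/4821 ≈ 2.29 errors per
errorful case (truncated geometric on 1..8 — short, bounded chains keep
`Order` trivially acyclic); comorbidities recorded in 2097/6610 of cases.
Outcome severities are not published anywhere; the mix (none 0.15, minor
0.35, severe 0.25, death 0.20, mental-only 0.05) was chosen once as a
plausible severity profile for litigated cases and is not calibrated to
any target.

Hospitals, specialties, diseases, comorbidity kinds and error labels are
chosen per case with probability proportional to
`(current degree + 1)^beta` (`attachment_strength`, default 1) — the
rich-get-richer mechanism that produces heavy-tailed degree profiles.
Setting `beta = 0` gives uniform choice, which the tests use as the
contrast.

What the generator deliberately does **not** emulate: individual disease
nodes (the corpus had 5,368 diseases in 23 groups; the schema caps `D` at
the 23 groups), patients with multiple claims (one patient and one claim
per case), missing links (every case is complete, so the generated median
degree is around 3 rather than the corpus's reported 1, and almost no
node has a single relationship), judgment amounts, regions, and time
trends. Passing tests on generated data therefore demonstrate that the
*pipeline* is correct under a schema-conforming heavy-tailed input; they
say nothing about parameter values of the real corpus.

Reference generators complete the test bed: `generate_pa_graph()` (the
classic growth-plus-preferential-attachment process; edges oriented new
to old, so the total-degree sequence is the classic undirected one),
`generate_random_graph()` (directed Erdős–Rényi), and exact tail
samplers for the power-law (inverse CDF continuous; exact cumulative
search discrete, switching to the rounded continuous approximation beyond
k = 10^6), exponential and log-normal families. Every generator is a pure
function of its parameters and seed; a pipeline seed expands to
per-component child seeds by fixed offsets.

## Graph primitives and centrality conventions

Degree counts parallel typed edges with their multiplicity (a node's
degree is its number of incident relationships); path semantics collapse
parallel edges to one hop. Distances follow edge direction by default;
an undirected switch exists for sensitivity analysis. Unreachability is
represented explicitly in the primitives (absent entries, never 0); the
closeness convention below is applied only in the centrality layer.

The four hub metrics follow the printed conventions of malpractice
network studies exactly, which differ from several library defaults:

* **Degree**: `D(i) = d_i/(N-1)` on total (in + out) degree.
* **Closeness**: `C(i) = (N-1) / sum_j D_ij`, where an unreachable pair
  contributes 0 to the sum and a node reaching nothing scores 0. Applied
  literally, this convention can exceed 1 on disconnected graphs (a node
  reaching one neighbour at distance 1 scores `N-1`); the anomaly is
  intentional and documented, and harmonic closeness
  (`closeness_centrality(harmonic = TRUE)`, bounded by 1) is offered for
  sanity comparisons.
* **Betweenness**: unnormalized sum over *ordered* pairs `a != b != i` of
  the fraction of shortest directed paths through `i`, computed by
  Brandes' accumulation (C++); geodesics are counted on the simple
  digraph. No division by two: the graph is directed, and normalization
  does not change rankings.
* **PageRank**: the classic unnormalized recurrence
  `PR(i) = (1-d) + d * sum PR(T)/C(T)` with damping `d = 0.85` by
  default, `C(T)` counting parallel out-edges, dangling rank
  redistributed uniformly. The printed formula lacks a stopping rule;
  iteration starts at all ones and stops when the maximum change falls
  below `tol = 1e-8` (cap 200 iterations, non-convergence is an error
  carrying the last iterate). Under this convention converged scores sum
  to `N`, and on a directed cycle every score is 1.

Hub tables (`rank_hubs()`) sort by score descending with lexicographic
node-id tie-breaks so reports are deterministic; the error subgraph
(`E` nodes + `Order` edges) is *recomputed*, not filtered, before
ranking, mirroring how hub errors are reported separately from the
overall graph.

## The scale-free decision

For a degree sequence the package fits a discrete power law
`P(k) ∝ k^(-alpha)`, `k >= xmin`, by maximum likelihood with the
Kolmogorov–Smirnov choice of `xmin` (the threshold minimizing the
distance between the empirical and fitted tail, smallest threshold on
ties), calibrates it with a semi-parametric bootstrap, and compares it
against exponential and log-normal alternatives with a Vuong-style
normalized likelihood-ratio test.

Numerical choices that matter:

* **Exponent estimator.** The popular shifted approximation
  `alpha = 1 + n/sum(log(x/(xmin - 1/2)))` is biased by about −0.5 at
  `xmin = 1` for `alpha = 2.5` (verified by a population-level
  calculation), far outside the ±0.05 recovery band the tests demand, so
  the default estimator maximizes the exact zeta likelihood for
  `xmin < 10` and uses the approximation above (bias < 0.005 there,
  and it is much cheaper inside the bootstrap). `method = "approx"`
  forces the approximation.
* **KS distance.** Evaluated exactly: both empirical CDF steps at every
  observed value and, for unit-binned models, the gap just below each
  support point, so the supremum over all integers is attained without
  scanning them. The discrete power law is normalized by the Hurwitz
  zeta function, computed by Euler–Maclaurin summation.
* **Threshold candidates.** All unique observed values that leave at
  least `min_tail = 10` observations *and* `min_distinct = 10` distinct
  values in the tail. The distinct-value floor is essential on count
  data: without it the search on a short-ranged (Poisson-like) degree
  distribution escapes into an ~8-support-point deep tail where any
  family is locally plausible — the reference `plfit` implementation
  shows exactly this behaviour — and the goodness-of-fit test loses all
  power against random networks.
* **Log-normal family.** On integer samples the log-normal is fitted as
  a unit-binned count model (numeric MLE of the binned, left-truncated
  likelihood; multi-start Nelder–Mead with a BFGS polish). The
  continuous left-truncated MLE degenerates on heavy count tails
  (`mu -> -inf` along a power-law-like ridge), and mixing a continuous
  fit with binned likelihood-ratio masses produces meaningless ratios.
  All tail probabilities are computed on the survival scale so that
  far-tail evaluations never cancel. The exponential fit keeps its
  closed form `lambda = 1/(mean(tail) - xmin)`.
* **Bootstrap.** Each of `n_reps` (default 2500) replicates draws `n`
  values — with probability `n_tail/n` from the fitted tail model,
  otherwise uniformly from the empirical body below the threshold —
  and *refits the same family including a fresh threshold search*. The
  p-value is the fraction of replicates with KS at least the observed
  one; `n_fail_to_reject` additionally counts replicates below the
  asymptotic level-0.05 critical value `1.358/sqrt(n_tail)`, covering
  the per-replicate reading of a published "failed to reject" tally.
  All replicate randomness flows from one explicit seed.
* **Verdict.** `scale_free` when the bootstrap p-value is at least 0.1
  and no alternative is significantly favored (likelihood-ratio p < 0.05
  with the ratio pointing at the alternative); `not_scale_free` when the
  p-value is below 0.1 or an alternative wins; `inconclusive` only when
  the power-law fit itself is degenerate. On preferential-attachment
  degree sequences the log-normal comparison is typically indecisive —
  expected, since a truncated log-normal can mimic a power law over a
  finite range — while on random-graph degrees it wins decisively,
  reinforcing the rejection.

A known honest limitation: the degree distribution of the classic
preferential-attachment process is not a pure power law (its exact form
has low-degree curvature), and with 5,000 nodes the bootstrap genuinely
detects this in roughly one run out of seven, so perfect acceptance of
such networks is not attainable — nor desirable — under this procedure.

## Pipeline and reproducibility

`run_pipeline()` executes validate → summarize → fit/classify →
centralities → hub ranking and returns a report that is a pure function
of configuration and seed; `write_report()` serializes it (JSON,
markdown hub tables, CSV, degree sequence) without timestamps, so
identical runs produce byte-identical files. Percentages are rounded to
2 decimals and fit parameters to 6 only at serialization. The
"top fraction of nodes holding half the relationships" summary sorts by
degree descending (id ascending on ties) and counts relationship
*endpoints* (the degree sum); this convention is stated because the
corresponding published statistic does not specify its tie rule.

Configs load from YAML with strict unknown-key errors. One YAML gotcha is
handled explicitly: a bare `n:` key (natural for a node count) is a
boolean in YAML 1.1; the reader keeps literal `y`/`n` spellings as
strings and converts only `true`/`false`.

Problem sizes used by the shipped test suite were chosen to keep the
whole suite within a few minutes while leaving the statistics meaningful:
parameter recovery at n = 50,000; discrimination over 20 seeded runs at
n = 5,000 (growth) and n = 3,000 (random) with 200 bootstrap replicates;
calibration over 100 seeded runs at n = 500 and 200 replicates; oracle
equivalence for betweenness on 20 random digraphs of up to 25 nodes
against exhaustive geodesic enumeration. The acceptance script runs the
full pipeline at the study scale (6,610 cases, 2,500 replicates).

## Worked example

```{r example}
g <- generate_mmnc(mmnc_gen_params(n_cases = 400, seed = 7))
g
nrow(validate_graph(g))            # 0: schema-conforming by construction
case_cardinality_checks(g)

deg <- degree_sequence(g)
verdict <- classify_network(deg, n_reps = 100, seed = 8)
verdict$verdict
verdict$power_law

rank_hubs(pagerank(g), k = 5, graph = g)
rank_hubs(betweenness_centrality(g), k = 5,
          restrict = "error_subgraph", graph = g)
```

## Limitations

The generator's contract is schema conformity, not realism: recovered
parameters describe the emulator, not Chinese litigation practice. The
closeness convention is implemented as printed even where it behaves
anomalously on disconnected graphs. Weighted shortest paths, clustering
coefficients, community detection, eigenvector/Katz centrality and
truncated power-law or stretched-exponential families are out of scope,
as are NLP extraction from litigation texts and any graph-database
backend.
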