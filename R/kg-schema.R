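#' Node kinds of the malpractice knowledge graph
#'
#' The schema has exactly eight node kinds: patients (`P`), hospitals (`H`),
#' physician specialties (`S`), patient outcomes (`O`), malpractice claims
#' (`C`), comorbidity categories (`CD`, Charlson index groups, at most 20),
#' medical errors (`E`, see [error_registry()]) and disease groups (`D`,
#' ICD-10 chapters, at most 23).
#'
#' @return A data frame with columns `code` and `description`.
#' @export
#' @examples
#' node_kinds()
node_kinds <- function() {
  data.frame(
    code = c("P", "H", "S", "O", "CD", "E", "D", "C"),
    description = c(
      "patient (plaintiff)",
      "hospital (defendant)",
      "physician specialty",
      "patient outcome severity level",
      "comorbidity category (Charlson index)",
      "medical error",
      "disease group (ICD-10)",
      "malpractice claim"
    ),
    stringsAsFactors = FALSE
  )
}

#' Allowed outcome severity levels
#'
#' The five levels of the outcome (`O`) node kind, adapted from the patient
#' outcome axis of the WHO International Classification for Patient Safety:
#' asymptomatic, minor injury, severe injury, death, and mental injury only.
#'
#' @return Character vector of the five outcome labels.
#' @export
outcome_levels <- function() {
  c("none", "minor injury", "severe injury", "death", "mental injury only")
}

#' Relationship kinds and their allowed endpoint kinds
#'
#' The nine directed relationship kinds of the schema, with the node kinds
#' they may connect. Edges are directed in chronological order of the
#' underlying events. `Sue` is the only kind with two admissible endpoint
#' signatures (outcome to claim, and patient to hospital), which is why a
#' complete case carries two `Sue` links.
#'
#' @return A data frame with columns `code`, `source_kind`, `target_kind`;
#'   one row per admissible endpoint signature (`Sue` has two).
#' @export
#' @examples
#' relation_kinds()
relation_kinds <- function() {
  data.frame(
    code = c("With", "SufferFrom", "SeekMedicalAdvice", "Affiliated",
             "Error", "AcceptJudgment", "Cause", "Sue", "Sue", "Order"),
    source_kind = c("P", "P", "P", "S", "H", "H", "O", "O", "P", "E"),
    target_kind = c("CD", "D", "S", "H", "E", "C", "C", "C", "H", "E"),
    stringsAsFactors = FALSE
  )
}

# The 21 error labels recoverable from the published hub tables, each with
# its technical/nontechnical flag. Technical errors relate to diagnosis,
# treatment or surgical skill; nontechnical errors to consent,
# documentation, communication or management.
.builtin_errors <- data.frame(
  label = c(
    "inadequate informed consent",
    "lack of informed consent",
    "unsigned consent documentation",
    "unclear, ambiguous, illegible, or incomplete medical records",
    "supervision or patient safety management",
    "failure to communicate with or instruct the patient or family",
    "emergency management",
    "administrative management",
    "risk management",
    "other management-related errors",
    "delay in treatment",
    "delay in diagnosis",
    "delay in surgery",
    "missed diagnosis",
    "failure to recognize complications",
    "failure to identify postoperative complications",
    "failure to perform preoperative evaluation",
    "failure to perform pretreatment evaluation",
    "untimely patient rounds",
    "other surgery-related errors",
    "other treatment-related errors",
    "other medicine-related errors"
  ),
  technical = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Registry of medical error labels
#'
#' Returns the error taxonomy used for `E` nodes: each label carries exactly
#' one technical/nontechnical flag. The built-in registry ships the labels
#' recoverable from published malpractice hub analyses; additional labels
#' can be registered through `extra`.
#'
#' @param extra Optional data frame with columns `label` and `technical`
#'   (logical) appended to the built-in registry. Duplicated labels are an
#'   error.
#' @return A data frame with columns `label` and `technical`.
#' @export
#' @examples
#' head(error_registry())
#' error_registry(extra = data.frame(label = "wrong-site surgery",
#'                                   technical = TRUE))
error_registry <- function(extra = NULL) {
  reg <- .builtin_errors
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(c("label", "technical") %in% names(extra)))
    stopifnot(is.logical(extra$technical), !anyNA(extra$technical))
    reg <- rbind(reg, extra[, c("label", "technical")])
  }
  if (anyDuplicated(reg$label))
    stop("duplicated error labels in registry: ",
         paste(unique(reg$label[duplicated(reg$label)]), collapse = ", "))
  reg
}

#' Construct a malpractice knowledge graph
#'
#' A `malpractice_graph` is a directed multigraph with typed nodes and typed
#' relationships. Node identifiers are opaque strings; the kind is stored as
#' an explicit attribute and never derived from the identifier. Untyped
#' graphs (e.g. reference random graphs) use `NA` kinds and relations.
#'
#' @param nodes Data frame with columns `id` (character, unique) and
#'   optionally `kind` (one of [node_kinds()] codes or `NA`) and `label`
#'   (display label; defaults to `id`).
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `relation` (one of [relation_kinds()] codes or `NA`) and `case`
#'   (claim identifier attributing the edge to a case, or `NA`).
#' @return An object of class `malpractice_graph` with elements `nodes` and
#'   `edges`.
#' @seealso [validate_graph()], [case_cardinality_checks()]
#' @export
#' @examples
#' g <- malpractice_graph(
#'   nodes = data.frame(id = c("p1", "d1"), kind = c("P", "D")),
#'   edges = data.frame(from = "p1", to = "d1", relation = "SufferFrom"))
#' g
malpractice_graph <- function(nodes = data.frame(id = character()),
                              edges = data.frame(from = character(),
                                                 to = character())) {
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  if (is.null(nodes$kind)) nodes$kind <- rep(NA_character_, nrow(nodes))
  nodes$kind <- as.character(nodes$kind)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes$label <- ifelse(is.na(nodes$label), nodes$id, as.character(nodes$label))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$relation)) edges$relation <- rep(NA_character_, nrow(edges))
  edges$relation <- as.character(edges$relation)
  if (is.null(edges$case)) edges$case <- rep(NA_character_, nrow(edges))
  edges$case <- as.character(edges$case)
  structure(
    list(nodes = nodes[, c("id", "kind", "label")],
         edges = edges[, c("from", "to", "relation", "case")]),
    class = "malpractice_graph"
  )
}

#' @export
print.malpractice_graph <- function(x, ...) {
  kinds <- table(x$nodes$kind, useNA = "ifany")
  cat(sprintf("<malpractice_graph> %d nodes, %d directed relationships\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    cat("  node kinds: ",
        paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of nodes in a graph
#' @param graph A [malpractice_graph()].
#' @return Integer node count.
#' @export
n_nodes <- function(graph) {
  stopifnot(inherits(graph, "malpractice_graph"))
  nrow(graph$nodes)
}

#' Number of directed relationships in a graph
#' @param graph A [malpractice_graph()].
#' @return Integer relationship count (parallel edges counted).
#' @export
n_relationships <- function(graph) {
  stopifnot(inherits(graph, "malpractice_graph"))
  nrow(graph$edges)
}

#' Validate a graph against the malpractice schema
#'
#' Checks every schema rule: node kinds must be known, node identifiers
#' unique, relationship endpoints must reference existing nodes, endpoint
#' kinds must match the signature table of [relation_kinds()], outcome node
#' labels must be one of [outcome_levels()], error node labels must appear
#' in the error registry, and the `Order` relationships attributed to one
#' case must form a simple chain (no repeated endpoints, no cycle). Edges
#' or nodes with `NA` kind/relation are treated as untyped and skip the
#' kind-based rules. `Order` chains can only be audited when edges carry a
#' `case` attribute; unattributed `Order` edges skip the chain rule.
#'
#' The report is independent of node and relationship ordering and
#' validation has no side effects, so it is idempotent.
#'
#' @param graph A [malpractice_graph()].
#' @param errors Error registry data frame, by default [error_registry()].
#' @return A data frame with columns `rule` and `detail`; zero rows when
#'   the graph is valid.
#' @export
#' @examples
#' validate_graph(malpractice_graph())  # empty graph is vacuously valid
validate_graph <- function(graph, errors = error_registry()) {
  stopifnot(inherits(graph, "malpractice_graph"))
  nodes <- graph$nodes
  edges <- graph$edges
  bad <- list()
  note <- function(rule, detail) {
    bad[[length(bad) + 1]] <<- data.frame(rule = rule, detail = detail,
                                          stringsAsFactors = FALSE)
  }

  dup <- unique(nodes$id[duplicated(nodes$id)])
  for (d in dup) note("duplicate_node_id", d)

  known <- node_kinds()$code
  unk <- nodes$id[!is.na(nodes$kind) & !(nodes$kind %in% known)]
  for (u in unk) note("unknown_node_kind",
                      sprintf("node '%s' has kind '%s'", u,
                              nodes$kind[nodes$id == u][1]))

  kind_of <- setNames(nodes$kind, nodes$id)
  miss_from <- !(edges$from %in% nodes$id)
  miss_to <- !(edges$to %in% nodes$id)
  for (i in which(miss_from | miss_to))
    note("dangling_edge",
         sprintf("edge %d (%s -> %s) references a missing node",
                 i, edges$from[i], edges$to[i]))

  rk <- relation_kinds()
  typed <- which(!is.na(edges$relation) & !miss_from & !miss_to)
  if (length(typed)) {
    rel <- edges$relation[typed]
    unknown <- !(rel %in% rk$code)
    for (j in which(unknown))
      note("unknown_relation",
           sprintf("edge %d has relation '%s'", typed[j], rel[j]))
    sk <- unname(kind_of[edges$from[typed]])
    tk <- unname(kind_of[edges$to[typed]])
    sig <- paste(rk$code, rk$source_kind, rk$target_kind)
    mism <- !unknown & !is.na(sk) & !is.na(tk) &
      !(paste(rel, sk, tk) %in% sig)
    for (j in which(mism))
      note("endpoint_kind_mismatch",
           sprintf("edge %d: %s may not link %s -> %s",
                   typed[j], rel[j], sk[j], tk[j]))
  }

  o_nodes <- nodes[!is.na(nodes$kind) & nodes$kind == "O", ]
  bad_o <- o_nodes$id[!(o_nodes$label %in% outcome_levels())]
  for (b in bad_o)
    note("outcome_vocabulary",
         sprintf("O node '%s' has label outside the five outcome levels", b))

  e_nodes <- nodes[!is.na(nodes$kind) & nodes$kind == "E", ]
  bad_e <- e_nodes$id[!(e_nodes$label %in% errors$label)]
  for (b in bad_e)
    note("error_vocabulary",
         sprintf("E node '%s' has label outside the error registry", b))

  ord <- edges[!is.na(edges$relation) & edges$relation == "Order" &
                 !is.na(edges$case), , drop = FALSE]
  if (nrow(ord)) {
    by_case <- split(ord, ord$case)
    for (cs in sort(names(by_case))) {
      ce <- by_case[[cs]]
      if (anyDuplicated(ce$from) || anyDuplicated(ce$to)) {
        note("order_chain",
             sprintf("case '%s': Order edges branch (repeated endpoint)", cs))
        next
      }
      # in/out degree <= 1 holds; a cycle exists iff no start node remains
      if (length(setdiff(ce$from, ce$to)) == 0)
        note("order_chain", sprintf("case '%s': Order edges form a cycle", cs))
    }
  }

  if (length(bad) == 0)
    return(data.frame(rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, bad)
  out[order(out$rule, out$detail), , drop = FALSE]
}

#' Per-case cardinality checks
#'
#' Audits the case-level link counts the schema implies: (a) every claim
#' has exactly two `Sue` links (outcome-to-claim and patient-to-hospital);
#' (b) the number of `Cause` links equals the number of claims with at
#' least one `Error` link (negligence causes the outcome only when an error
#' was found); (c) every claim has exactly one `SufferFrom`,
#' `SeekMedicalAdvice`, `Affiliated` and `AcceptJudgment` link.
#'
#' Checks are performed per case via the `case` edge attribute when it is
#' present on the relevant relation; edges without case attribution fall
#' back to the aggregate identity (total count equals the expected multiple
#' of the number of claims).
#'
#' @param graph A [malpractice_graph()].
#' @return Named logical vector with elements `two_sue_per_case`,
#'   `cause_matches_errorful`, `one_suffer_from_per_case`,
#'   `one_seek_advice_per_case`, `one_affiliated_per_case`,
#'   `one_accept_judgment_per_case`.
#' @export
case_cardinality_checks <- function(graph) {
  stopifnot(inherits(graph, "malpractice_graph"))
  nodes <- graph$nodes
  edges <- graph$edges
  cases <- nodes$id[!is.na(nodes$kind) & nodes$kind == "C"]
  ncase <- length(cases)

  rel_edges <- function(code) edges[!is.na(edges$relation) &
                                      edges$relation == code, , drop = FALSE]
  # exactly `each` links of `code` per case
  per_case_ok <- function(code, each) {
    e <- rel_edges(code)
    if (ncase == 0) return(nrow(e) == 0)
    if (nrow(e) > 0 && all(!is.na(e$case))) {
      cnt <- table(factor(e$case, levels = cases))
      return(all(cnt == each) && all(e$case %in% cases))
    }
    nrow(e) == each * ncase
  }

  err <- rel_edges("Error")
  cau <- rel_edges("Cause")
  if (nrow(err) > 0 && all(!is.na(err$case))) {
    n_errorful <- length(unique(err$case))
  } else {
    # without attribution the best available identity is one Error link
    # per errorful case
    n_errorful <- nrow(err)
  }

  c(two_sue_per_case = per_case_ok("Sue", 2),
    cause_matches_errorful = nrow(cau) == n_errorful,
    one_suffer_from_per_case = per_case_ok("SufferFrom", 1),
    one_seek_advice_per_case = per_case_ok("SeekMedicalAdvice", 1),
    one_affiliated_per_case = per_case_ok("Affiliated", 1),
    one_accept_judgment_per_case = per_case_ok("AcceptJudgment", 1))
}

#' Published tallies of the Chinese malpractice litigation network
#'
#' Node and relationship counts reported for the 6610-claim litigation
#' corpus behind the malpractice network schema, together with the derived
#' totals its results quote (19,099 nodes; 57,700 relationships; 149 top
#' nodes carrying 28,850 relationship endpoints; 6,580 single-relationship
#' nodes, i.e. 34.45%). These are reference inputs for arithmetic
#' consistency checks and report templates; the underlying litigation texts
#' are not redistributable.
#'
#' @return A list with elements `node_counts` (named integer vector over
#'   the eight node kinds), `relation_counts` (named integer vector over
#'   the nine relationship kinds), and `reported` (named numeric vector of
#'   the printed summary figures).
#' @export
#' @examples
#' sum(mmnc_reported_counts()$node_counts)
mmnc_reported_counts <- function() {
  list(
    node_counts = c(P = 6582L, H = 351L, S = 38L, O = 5L, C = 6610L,
                    CD = 20L, E = 125L, D = 5368L),
    relation_counts = c(With = 2097L, SufferFrom = 6610L,
                        SeekMedicalAdvice = 6610L, Affiliated = 6610L,
                        Error = 4821L, AcceptJudgment = 6610L,
                        Cause = 4821L, Sue = 13320L, Order = 6201L),
    reported = c(total_nodes = 19099, total_relationships = 57700,
                 half_relationships = 28850, top_nodes = 149,
                 top_node_pct = 0.78, single_relationship_nodes = 6580,
                 single_relationship_pct = 34.45, n_cases = 6610)
  )
}
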