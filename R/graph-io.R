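# File formats: GraphML (node attribute "kind", edge attribute
# "relation"), a CSV node/edge pair, JSON-lines case records, and plain
# degree-sequence text files. All writers emit UTF-8; readers reject
# unknown kind and relation codes, naming the offending record.

as_igraph <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  # igraph's GraphML writer has no NA representation; encode as ""
  nodes$kind[is.na(nodes$kind)] <- ""
  edges$relation[is.na(edges$relation)] <- ""
  edges$case[is.na(edges$case)] <- ""
  igraph::graph_from_data_frame(
    d = edges[, c("from", "to", "relation", "case")],
    directed = TRUE,
    vertices = nodes[, c("id", "kind", "label")])
}

#' Write a graph to GraphML
#'
#' Nodes carry the attributes `kind` and `label`, edges `relation` and
#' `case`; direction is preserved. A graph that passes [validate_graph()]
#' round-trips unchanged through [read_graphml()].
#'
#' @param graph A [malpractice_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "malpractice_graph"))
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Read a graph from GraphML
#'
#' @param path GraphML file written by [write_graphml()] (or any GraphML
#'   file with `kind`/`relation` attributes).
#' @return A [malpractice_graph()].
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                 error = function(e) stop("cannot parse GraphML file '",
                                          path, "': ", conditionMessage(e)))
  va <- igraph::vertex_attr(ig)
  nodes <- data.frame(id = va$name %||% as.character(seq_len(igraph::vcount(ig))),
                      stringsAsFactors = FALSE)
  nodes$kind <- va$kind %||% NA_character_
  nodes$label <- va$label %||% nodes$id
  nodes$kind[nodes$kind == ""] <- NA_character_
  el <- igraph::as_edgelist(ig, names = TRUE)
  ea <- igraph::edge_attr(ig)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      stringsAsFactors = FALSE)
  edges$relation <- ea$relation %||% NA_character_
  edges$case <- ea$case %||% NA_character_
  edges$relation[edges$relation == ""] <- NA_character_
  edges$case[edges$case == ""] <- NA_character_
  g <- malpractice_graph(nodes, edges)
  check_vocab(g, path)
  g
}

check_vocab <- function(graph, path) {
  bad_kind <- which(!is.na(graph$nodes$kind) &
                      !(graph$nodes$kind %in% node_kinds()$code))
  if (length(bad_kind))
    stop("'", path, "': unknown node kind '",
         graph$nodes$kind[bad_kind[1]], "' at node record ", bad_kind[1])
  bad_rel <- which(!is.na(graph$edges$relation) &
                     !(graph$edges$relation %in% relation_kinds()$code))
  if (length(bad_rel))
    stop("'", path, "': unknown relation '",
         graph$edges$relation[bad_rel[1]], "' at edge record ", bad_rel[1])
  invisible(graph)
}

#' Write a graph as a CSV node/edge pair
#'
#' Writes `nodes.csv` (columns `id`, `kind`, `label`) and `edges.csv`
#' (columns `source`, `target`, `relation`, `case`) into `dir`.
#'
#' @param graph A [malpractice_graph()].
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_graph_csv <- function(graph, dir) {
  stopifnot(inherits(graph, "malpractice_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  np <- file.path(dir, "nodes.csv")
  ep <- file.path(dir, "edges.csv")
  write.csv(graph$nodes, np, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  ed <- graph$edges
  names(ed)[names(ed) == "from"] <- "source"
  names(ed)[names(ed) == "to"] <- "target"
  write.csv(ed, ep, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(c(nodes = np, edges = ep))
}

#' Read a graph from a CSV node/edge pair
#'
#' @param dir Directory containing `nodes.csv` and `edges.csv` as written
#'   by [write_graph_csv()].
#' @return A [malpractice_graph()].
#' @export
read_graph_csv <- function(dir) {
  np <- file.path(dir, "nodes.csv")
  ep <- file.path(dir, "edges.csv")
  for (f in c(np, ep)) if (!file.exists(f)) stop("no such file: ", f)
  nodes <- read.csv(np, stringsAsFactors = FALSE, na.strings = "",
                    fileEncoding = "UTF-8")
  if (!all(c("id") %in% names(nodes)))
    stop("'", np, "': missing required column 'id'")
  edges <- read.csv(ep, stringsAsFactors = FALSE, na.strings = "",
                    fileEncoding = "UTF-8")
  if (!all(c("source", "target") %in% names(edges)))
    stop("'", ep, "': missing required columns 'source'/'target'")
  names(edges)[names(edges) == "source"] <- "from"
  names(edges)[names(edges) == "target"] <- "to"
  g <- malpractice_graph(nodes, edges)
  check_vocab(g, dir)
  g
}

#' Write case records as JSON lines
#'
#' One case per line: `case`, `patient`, `hospital`, `specialty`,
#' `disease`, `comorbidities` (array), `outcome`, `errors` (array, in
#' chronological order).
#'
#' @param cases List of case records (see [graph_from_cases()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cases_jsonl <- function(cases, path) {
  lines <- vapply(cases, function(cs) {
    jsonlite::toJSON(list(case = cs$case, patient = cs$patient,
                          hospital = cs$hospital, specialty = cs$specialty,
                          disease = cs$disease,
                          comorbidities = as.character(cs$comorbidities),
                          outcome = cs$outcome,
                          errors = as.character(cs$errors)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read case records from JSON lines
#'
#' @param path File written by [write_cases_jsonl()].
#' @return List of case records; parse failures name the offending line.
#' @export
read_cases_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  req <- c("case", "patient", "hospital", "specialty", "disease", "outcome")
  lapply(seq_along(lines), function(i) {
    cs <- tryCatch(jsonlite::fromJSON(lines[i]),
                   error = function(e) stop("'", path, "' line ", i,
                                            ": invalid JSON: ",
                                            conditionMessage(e)))
    miss <- setdiff(req, names(cs))
    if (length(miss))
      stop("'", path, "' line ", i, ": missing field(s) ",
           paste(miss, collapse = ", "))
    cs$comorbidities <- as.character(cs$comorbidities %||% character())
    cs$errors <- as.character(cs$errors %||% character())
    cs
  })
}

#' Write a degree sequence as plain text
#'
#' One nonnegative integer per line, the exchange format between the
#' graph stage and the distribution-fitting stage.
#'
#' @param degrees Integer vector (e.g. from [degree_sequence()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_degree_sequence <- function(degrees, path) {
  if (any(degrees != floor(degrees)) || any(degrees < 0))
    stop("degrees must be nonnegative integers")
  writeLines(format(as.integer(degrees), scientific = FALSE, trim = TRUE),
             path)
  invisible(path)
}

#' Read a degree sequence from plain text
#'
#' @param path File with one nonnegative integer per line; anything else
#'   is rejected naming the line.
#' @return Integer vector.
#' @export
read_degree_sequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  bad <- grep("^[0-9]+$", lines, invert = TRUE)
  if (length(bad))
    stop("'", path, "' line ", bad[1], ": not a nonnegative integer: '",
         lines[bad[1]], "'")
  as.integer(lines)
}

#' Read a graph from any supported format
#'
#' Dispatches on the input: `.graphml` files go through [read_graphml()],
#' `.jsonl`/`.ndjson` case files through [read_cases_jsonl()] and
#' [graph_from_cases()], and a directory through [read_graph_csv()].
#'
#' @param path File or directory.
#' @return A [malpractice_graph()].
#' @export
read_graph <- function(path) {
  if (dir.exists(path)) return(read_graph_csv(path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         graphml = read_graphml(path),
         jsonl = ,
         ndjson = graph_from_cases(read_cases_jsonl(path)),
         stop("unsupported graph format '.", ext,
              "' (expected .graphml, .jsonl/.ndjson, or a CSV directory)"))
}
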