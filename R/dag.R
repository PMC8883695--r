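#' Directed acyclic graph over named observable nodes
#'
#' A `dag` is the qualitative part of a structural causal model: a set of
#' named nodes and directed edges between them.  Latent error terms are not
#' nodes; Markovian independence of the errors is encoded by their absence.
#'
#' @param nodes character vector of unique node labels.
#' @param edges edges as a list of length-2 character vectors
#'   `c(parent, child)`, or a 2-column character matrix with one row per
#'   edge.  May be empty.
#' @return an object of class `dag` with components `nodes` (character) and
#'   `edges` (2-column character matrix with columns `from`, `to`).
#' @examples
#' g <- dag(c("X", "Y", "C"), list(c("C", "X"), c("X", "Y"), c("C", "Y")))
#' g
#' @export
dag <- function(nodes, edges = list()) {
  if (!is.character(nodes) || length(nodes) == 0L)
    stop("'nodes' must be a non-empty character vector")
  if (anyDuplicated(nodes))
    stop("duplicate node labels: ", paste(nodes[duplicated(nodes)], collapse = ", "))
  em <- as_edge_matrix(edges)
  unknown <- setdiff(c(em), nodes)
  if (length(unknown))
    stop("unknown node(s) in edges: ", paste(unique(unknown), collapse = ", "))
  if (any(em[, 1L] == em[, 2L]))
    stop("self-loops are not allowed")
  if (anyDuplicated(paste(em[, 1L], em[, 2L], sep = "\r")))
    stop("duplicate edges are not allowed")
  g <- structure(list(nodes = nodes, edges = em), class = "dag")
  if (is_cyclic(g))
    stop("edges contain a directed cycle; the graph must be acyclic")
  g
}

as_edge_matrix <- function(edges) {
  if (is.matrix(edges)) {
    if (length(edges) && ncol(edges) != 2L)
      stop("'edges' matrix must have two columns (parent, child)")
    em <- matrix(as.character(edges), ncol = 2L)
  } else if (is.list(edges)) {
    if (length(edges) && !all(lengths(edges) == 2L))
      stop("each edge must be a length-2 vector c(parent, child)")
    em <- matrix(as.character(unlist(edges)), ncol = 2L, byrow = TRUE)
    if (!length(edges)) em <- matrix(character(), ncol = 2L)
  } else stop("'edges' must be a list of pairs or a 2-column matrix")
  colnames(em) <- c("from", "to")
  em
}

is_cyclic <- function(g) {
  ## Kahn's algorithm: a DAG can be fully peeled by repeatedly removing
  ## nodes without incoming edges.
  nodes <- g$nodes
  em <- g$edges
  while (length(nodes)) {
    sources <- setdiff(nodes, em[, 2L])
    if (!length(sources)) return(TRUE)
    nodes <- setdiff(nodes, sources)
    em <- em[!(em[, 1L] %in% sources), , drop = FALSE]
  }
  FALSE
}

#' @export
print.dag <- function(x, ...) {
  cat("dag with", length(x$nodes), "nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges) == 0L) cat("  (no edges)\n")
  else cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L], collapse = "\n"), "\n")
  invisible(x)
}

edge_keys <- function(g) {
  if (!nrow(g$edges)) return(character())
  paste0(g$edges[, 1L], "->", g$edges[, 2L])
}

check_node <- function(g, ...) {
  nn <- c(...)
  bad <- setdiff(nn, g$nodes)
  if (length(bad)) stop("node(s) not found in graph: ", paste(bad, collapse = ", "))
  invisible(nn)
}

#' @rdname dag-edges
#' @export
has_edge <- function(g, from, to) {
  any(g$edges[, 1L] == from & g$edges[, 2L] == to)
}

#' Add or delete edges of a DAG
#'
#' Set-based edge editing: adding an existing edge or deleting an absent one
#' is a no-op, so edits on disjoint edges commute.
#'
#' @param g a [dag()].
#' @param from,to node labels of the edge's parent and child.
#' @return the modified `dag`.
#' @name dag-edges
#' @export
add_edge <- function(g, from, to) {
  check_node(g, from, to)
  if (has_edge(g, from, to)) return(g)
  dag(g$nodes, rbind(g$edges, c(from, to)))
}

#' @rdname dag-edges
#' @export
delete_edge <- function(g, from, to) {
  keep <- !(g$edges[, 1L] == from & g$edges[, 2L] == to)
  g$edges <- g$edges[keep, , drop = FALSE]
  g
}

parents_of <- function(g, node) g$edges[g$edges[, 2L] == node, 1L]

children_of <- function(g, node) g$edges[g$edges[, 1L] == node, 2L]

#' Proper descendants of a node
#'
#' @param g a [dag()].
#' @param node a node label.
#' @return character vector of all nodes reachable from `node` along
#'   directed edges (excluding `node` itself), in graph node order.
#' @export
descendants_of <- function(g, node) {
  check_node(g, node)
  seen <- character()
  frontier <- children_of(g, node)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unlist(lapply(frontier, children_of, g = g)), seen)
  }
  g$nodes[g$nodes %in% setdiff(seen, node)]
}

ancestors_of <- function(g, nodes) {
  ## inclusive ancestral set of a node set
  seen <- nodes
  frontier <- nodes
  while (length(frontier)) {
    up <- setdiff(unlist(lapply(frontier, parents_of, g = g)), seen)
    seen <- union(seen, up)
    frontier <- up
  }
  g$nodes[g$nodes %in% seen]
}

#' The confounder and collider motif DAGs
#'
#' `confounder_dag()` is the three-node treatment/outcome/confounder graph
#' with edges C->X, X->Y, C->Y.  `collider_dag()` is the four-node graph in
#' which treatment X and a second cause W meet in the collider C, which in
#' turn drives the outcome: X->C, W->C, C->Y.
#'
#' @return a [dag()].
#' @export
confounder_dag <- function() {
  dag(c("X", "Y", "C"), list(c("C", "X"), c("X", "Y"), c("C", "Y")))
}

#' @rdname confounder_dag
#' @export
collider_dag <- function() {
  dag(c("W", "X", "C", "Y"), list(c("X", "C"), c("W", "C"), c("C", "Y")))
}

#' Serialize a DAG to / from edge-list JSON
#'
#' The document is `{"nodes": [...], "edges": [["C","X"], ...]}`.
#'
#' @param g a [dag()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `dag_to_json` returns the JSON string (invisibly when writing to
#'   a file); `dag_from_json` returns a `dag`.
#' @export
dag_to_json <- function(g, path = NULL) {
  edges <- lapply(seq_len(nrow(g$edges)), function(i) unname(g$edges[i, ]))
  txt <- jsonlite::toJSON(list(nodes = g$nodes, edges = edges))
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' @rdname dag_to_json
#' @param x a JSON string, or a path to a JSON file.
#' @export
dag_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyMatrix = TRUE)
  edges <- doc$edges
  if (is.null(edges) || length(edges) == 0L) edges <- list()
  dag(as.character(doc$nodes), edges)
}
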