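#' Enumerate simple paths between two nodes
#'
#' Paths are walked over the undirected skeleton but each step remembers its
#' orientation, so the result can be inspected for chains, forks and
#' colliders.  Paths are simple (no node repeats) and are returned in a
#' deterministic order: depth-first, neighbours visited in graph node order
#' with the forward orientation first.
#'
#' @param g a [dag()].
#' @param x,y distinct node labels.
#' @return a list of paths; each path is a data frame with columns `from`,
#'   `to` (the edge as stored in the DAG) and `forward` (`TRUE` if the edge
#'   is traversed parent-to-child).  `enumerate_paths` returns all simple
#'   paths; `directed_paths` only those in which every edge points toward
#'   `y`.
#' @examples
#' enumerate_paths(confounder_dag(), "X", "Y")
#' directed_paths(collider_dag(), "X", "Y")
#' @export
enumerate_paths <- function(g, x, y) {
  check_node(g, x, y)
  if (x == y) stop("'x' and 'y' must be distinct nodes")
  em <- g$edges
  out <- list()
  walk <- function(at, visited, steps) {
    if (at == y) {
      out[[length(out) + 1L]] <<- steps
      return(invisible())
    }
    for (node in g$nodes) {
      if (node %in% visited) next
      if (any(em[, 1L] == at & em[, 2L] == node))
        walk(node, c(visited, node),
             rbind(steps, data.frame(from = at, to = node, forward = TRUE)))
      if (any(em[, 1L] == node & em[, 2L] == at))
        walk(node, c(visited, node),
             rbind(steps, data.frame(from = node, to = at, forward = FALSE)))
    }
  }
  walk(x, x, data.frame(from = character(), to = character(), forward = logical()))
  out
}

#' @rdname enumerate_paths
#' @export
directed_paths <- function(g, x, y) {
  Filter(function(p) all(p$forward), enumerate_paths(g, x, y))
}

#' Test d-separation of two nodes given a conditioning set
#'
#' Two nodes are d-separated by a set `z` when every path between them is
#' blocked: the path contains a chain or fork whose middle node is in `z`,
#' or a collider whose middle node and all of its descendants lie outside
#' `z`.  The implementation uses the equivalent ancestral moral-graph
#' criterion (restrict to the ancestors of `{x, y} union z`, marry parents
#' of a common child, drop orientations, remove `z`, and test graphical
#' connectivity), which is exact for DAGs.
#'
#' @param g a [dag()].
#' @param x,y distinct node labels, neither contained in `z`.
#' @param z character vector of conditioning nodes (possibly empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @examples
#' d_separated(confounder_dag(), "X", "Y", "C")   # FALSE: X -> Y stays open
#' d_separated(collider_dag(), "W", "X")          # TRUE:  blocked collider
#' d_separated(collider_dag(), "W", "X", "C")     # FALSE: conditioning opens it
#' @export
d_separated <- function(g, x, y, z = character()) {
  z <- as.character(z)
  check_node(g, x, y, z)
  if (x == y) stop("'x' and 'y' must be distinct nodes")
  if (x %in% z || y %in% z) stop("'x' and 'y' must not be in the conditioning set")

  anc <- ancestors_of(g, c(x, y, z))
  em <- g$edges
  em <- em[em[, 1L] %in% anc & em[, 2L] %in% anc, , drop = FALSE]

  ## moralize: undirected edges plus links between co-parents
  und <- rbind(em, em[, 2L:1L, drop = FALSE])
  for (child in unique(em[, 2L])) {
    pa <- em[em[, 2L] == child, 1L]
    if (length(pa) > 1L) {
      pairs <- utils::combn(pa, 2L)
      und <- rbind(und, t(pairs), t(pairs[2L:1L, , drop = FALSE]))
    }
  }

  ## remove conditioning nodes, then test reachability x -> y
  keep <- setdiff(anc, z)
  und <- und[und[, 1L] %in% keep & und[, 2L] %in% keep, , drop = FALSE]
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nb <- setdiff(und[und[, 1L] %in% frontier, 2L], seen)
    if (y %in% nb) return(FALSE)
    seen <- c(seen, nb)
    frontier <- nb
  }
  TRUE
}

subsets_by_size <- function(pool) {
  ## all subsets of `pool`, smallest first, lexicographic within a size
  pool <- sort(pool)
  out <- list(character())
  for (k in seq_along(pool))
    out <- c(out, utils::combn(pool, k, simplify = FALSE))
  out
}

#' Minimal single-door adjustment set for an edge coefficient
#'
#' The structural coefficient on the edge `from -> to` equals the partial
#' regression coefficient of `from` in the regression of `to` on
#' `{from} union Z` whenever `Z` contains no descendant of `to` and `Z`
#' d-separates `from` and `to` in the graph with the edge removed.  The
#' search is exhaustive over subsets of the remaining observable nodes,
#' returning the first admissible set by minimal cardinality, ties broken
#' by lexicographically smallest label tuple.
#'
#' @param g a [dag()].
#' @param from,to the edge; must be present in `g`.
#' @return a character vector (possibly empty, meaning no adjustment
#'   needed), or `NULL` when no admissible set of observables exists.
#' @examples
#' single_door_set(confounder_dag(), "X", "Y")  # "C"
#' single_door_set(collider_dag(), "X", "C")    # character(0)
#' @export
single_door_set <- function(g, from, to) {
  check_node(g, from, to)
  if (!has_edge(g, from, to)) stop("edge ", from, " -> ", to, " not present in graph")
  g_alpha <- delete_edge(g, from, to)
  pool <- setdiff(g$nodes, c(from, to, descendants_of(g, to)))
  for (z in subsets_by_size(pool))
    if (d_separated(g_alpha, from, to, z)) return(z)
  NULL
}

#' Minimal backdoor adjustment set for a total effect
#'
#' A set `Z` is backdoor-admissible for the total effect of `x` on `y` when
#' no member of `Z` is a descendant of `x` and `Z` d-separates `x` and `y`
#' in the subgraph with every edge leaving `x` removed.  Search order as in
#' [single_door_set()].
#'
#' @param g a [dag()].
#' @param x,y distinct node labels.
#' @return a character vector (possibly empty), or `NULL` when no
#'   admissible set exists.
#' @examples
#' backdoor_set(confounder_dag(), "X", "Y")  # "C"
#' backdoor_set(collider_dag(), "X", "Y")    # character(0)
#' @export
backdoor_set <- function(g, x, y) {
  check_node(g, x, y)
  if (x == y) stop("'x' and 'y' must be distinct nodes")
  g_under <- g
  g_under$edges <- g$edges[g$edges[, 1L] != x, , drop = FALSE]
  pool <- setdiff(g$nodes, c(x, y, descendants_of(g, x)))
  for (z in subsets_by_size(pool))
    if (d_separated(g_under, x, y, z)) return(z)
  NULL
}
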