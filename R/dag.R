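#' Directed acyclic graphs over named variables
#'
#' A `bn_dag` is a minimal DAG container used throughout the package: a
#' character vector of node names plus a named list mapping each node to its
#' parent set. All structure-learning and inference code operates on this
#' class.
#'
#' @param nodes character vector of unique node names.
#' @param edges optional two-column character matrix (or data.frame) of
#'   directed edges, `from` in column 1 and `to` in column 2.
#' @return an object of class `bn_dag`.
#' @examples
#' g <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' dag_parents(g, "C")
#' @export
new_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  g <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    for (i in seq_len(nrow(edges))) {
      g <- dag_add_edge(g, edges[i, 1], edges[i, 2])
    }
  }
  g
}

#' @rdname new_dag
#' @export
empty_dag <- function(nodes) new_dag(nodes)

check_node <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown node: ", node)
  node
}

#' Edge-level accessors and editors
#'
#' @param dag a `bn_dag`.
#' @param from,to node names.
#' @param node a node name.
#' @name dag-edges
NULL

#' @rdname dag-edges
#' @export
dag_parents <- function(dag, node) dag$parents[[check_node(dag, node)]]

#' @rdname dag-edges
#' @export
dag_children <- function(dag, node) {
  check_node(dag, node)
  dag$nodes[vapply(dag$parents, function(p) node %in% p, logical(1))]
}

#' @rdname dag-edges
#' @export
dag_has_edge <- function(dag, from, to) from %in% dag$parents[[to]]

#' @rdname dag-edges
#' @export
dag_add_edge <- function(dag, from, to) {
  check_node(dag, from); check_node(dag, to)
  if (from == to) stop("self-loop: ", from)
  if (dag_has_edge(dag, from, to)) stop("duplicate edge ", from, " -> ", to)
  dag$parents[[to]] <- c(dag$parents[[to]], from)
  if (!dag_is_acyclic(dag)) stop("edge ", from, " -> ", to, " creates a cycle")
  dag
}

#' @rdname dag-edges
#' @export
dag_remove_edge <- function(dag, from, to) {
  if (!dag_has_edge(dag, from, to)) stop("no edge ", from, " -> ", to)
  dag$parents[[to]] <- setdiff(dag$parents[[to]], from)
  dag
}

#' @rdname dag-edges
#' @export
dag_reverse_edge <- function(dag, from, to) {
  dag <- dag_remove_edge(dag, from, to)
  dag_add_edge(dag, to, from)
}

#' @rdname dag-edges
#' @export
dag_edges <- function(dag) {
  from <- unlist(dag$parents, use.names = FALSE)
  to <- rep(dag$nodes, lengths(dag$parents))
  m <- cbind(from = from, to = to)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Acyclicity and topological order
#'
#' `dag_is_acyclic()` checks for directed cycles by iterated leaf removal;
#' `topological_order()` returns the nodes sorted parents-before-children
#' (error on cyclic input).
#'
#' @param dag a `bn_dag`.
#' @export
dag_is_acyclic <- function(dag) {
  !is.null(topo_order_or_null(dag))
}

topo_order_or_null <- function(dag) {
  indeg <- lengths(dag$parents)
  remaining <- dag$nodes
  ord <- character(0)
  while (length(remaining)) {
    free <- remaining[indeg[remaining] == 0]
    if (!length(free)) return(NULL)
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
    for (v in remaining) {
      indeg[v] <- length(setdiff(dag$parents[[v]], ord))
    }
  }
  ord
}

#' @rdname dag_is_acyclic
#' @export
topological_order <- function(dag) {
  ord <- topo_order_or_null(dag)
  if (is.null(ord)) stop("graph is cyclic")
  ord
}

#' Structural Hamming distance between two DAGs
#'
#' Counts the edge operations (additions, deletions, re-orientations)
#' separating two DAGs over the same node set. A pair adjacent in both graphs
#' but with opposite orientation counts 1; an edge present in only one graph
#' counts 1.
#'
#' @param dag1,dag2 `bn_dag` objects over identical node sets.
#' @return integer distance.
#' @export
shd <- function(dag1, dag2) {
  if (!setequal(dag1$nodes, dag2$nodes)) stop("node sets differ")
  key <- function(g) {
    e <- dag_edges(g)
    if (!nrow(e)) return(list(dir = character(0), und = character(0)))
    list(dir = paste(e[, 1], e[, 2], sep = "\r"),
         und = paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "\r"))
  }
  k1 <- key(dag1); k2 <- key(dag2)
  only1 <- sum(!(k1$und %in% k2$und))
  only2 <- sum(!(k2$und %in% k1$und))
  shared <- intersect(k1$und, k2$und)
  flipped <- sum(vapply(shared, function(u) {
    d1 <- k1$dir[match(u, k1$und)]
    d2 <- k2$dir[match(u, k2$und)]
    d1 != d2
  }, logical(1)))
  only1 + only2 + flipped
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("Directed acyclic graph over", length(x$nodes), "nodes,",
      nrow(e), "edges\n")
  if (nrow(e)) {
    cat(paste0("  ", e[, 1], " -> ", e[, 2]), sep = "\n")
  }
  invisible(x)
}

#' Markov blanket of a node
#'
#' The Markov blanket of a target consists of its parents, its children, and
#' its spouses (other parents of its children). Given the blanket, the target
#' is conditionally independent of every remaining variable in the network.
#'
#' @param dag a `bn_dag`.
#' @param target node name.
#' @return a list with components `parents`, `children`, `spouses` and their
#'   union `blanket` (all character vectors, target excluded), of class
#'   `bn_blanket`.
#' @export
markov_blanket <- function(dag, target) {
  check_node(dag, target)
  pa <- dag_parents(dag, target)
  ch <- dag_children(dag, target)
  sp <- setdiff(unique(unlist(lapply(ch, dag_parents, dag = dag))), target)
  structure(list(
    target = target,
    parents = sort(pa),
    children = sort(ch),
    spouses = sort(setdiff(sp, c(pa, ch))),
    blanket = sort(unique(c(pa, ch, setdiff(sp, target))))
  ), class = "bn_blanket")
}

#' @export
print.bn_blanket <- function(x, ...) {
  cat("Markov blanket of", x$target, "\n")
  cat("  parents :", paste(x$parents, collapse = ", "), "\n")
  cat("  children:", paste(x$children, collapse = ", "), "\n")
  cat("  spouses :", paste(x$spouses, collapse = ", "), "\n")
  invisible(x)
}
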