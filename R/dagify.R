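# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Kahn topological sort; returns node order, or NULL if the graph is cyclic
.topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (NROW(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1L]; v <- edges[i, 2L]
      adj[[u]] <- c(adj[[u]], v)
      indeg[v] <- indeg[v] + 1L
    }
  }
  queue <- nodes[indeg == 0L]
  order <- character(0)
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    order <- c(order, u)
    for (v in adj[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

#' Is a directed graph acyclic?
#' @param nodes Character vector of node ids.
#' @param edges Two-column character matrix of directed edges.
#' @return TRUE if a topological order exists.
#' @export
is_acyclic <- function(nodes, edges) !is.null(.topo_sort(nodes, edges))

#' Convert a pathway graph to a DAG by randomized edge insertion
#'
#' Starting from the node set with no edges, the deduplicated edges are
#' visited in a uniformly random permutation determined by `seed`; an edge is
#' inserted only if the graph stays acyclic (self-loops, being length-1
#' cycles, are always dropped). The result records which edges were kept and
#' dropped and is bit-reproducible for a fixed seed.
#'
#' @param graph A [pathway_graph()] with at least one node.
#' @param seed Integer seed determining the edge permutation.
#' @return An object of class `pathway_dag` with fields `name`, `nodes`,
#'   `kept_edges`, `dropped_edges`, `seed`, `insertion_order`.
#' @export
dagify <- function(graph, seed = 0L) {
  edges <- unique(graph$edges)
  ord <- if (nrow(edges) > 1L)
    with_local_seed(seed, sample.int(nrow(edges))) else seq_len(nrow(edges))
  dag <- dagify_order(graph, ord)
  dag$seed <- as.integer(seed)
  dag
}

#' DAG-ify with an explicit edge insertion order
#'
#' Deterministic core of [dagify()]: edges (deduplicated, in original order)
#' are inserted following the supplied permutation, skipping any edge whose
#' insertion would create a cycle. Exposed so that insertion-order
#' sensitivity can be enumerated exhaustively on small graphs.
#'
#' @param graph A [pathway_graph()].
#' @param order Integer permutation of `seq_len(nrow(unique(graph$edges)))`.
#' @return A `pathway_dag` (with `seed = NA`).
#' @export
dagify_order <- function(graph, order) {
  if (length(graph$nodes) < 1L) stop("pathway graph has no nodes")
  edges <- unique(graph$edges)
  if (length(order) != nrow(edges) || !setequal(order, seq_len(max(0L, nrow(edges)))))
    if (nrow(edges) > 0L) stop("order must be a permutation of the deduplicated edge indices")
  nodes <- graph$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  # reach[u, v] TRUE if v is reachable from u through kept edges
  reach <- diag(length(nodes)) > 0
  kept <- logical(nrow(edges))
  for (i in order) {
    u <- idx[[edges[i, 1L]]]; v <- idx[[edges[i, 2L]]]
    if (reach[v, u]) next   # includes self-loops (u == v)
    kept[i] <- TRUE
    # adding u -> v makes everything reaching u reach everything v reaches
    from <- which(reach[, u]); to <- which(reach[v, ])
    reach[from, to] <- TRUE
  }
  structure(list(name = graph$name, nodes = nodes,
                 kept_edges = edges[kept, , drop = FALSE],
                 dropped_edges = edges[!kept, , drop = FALSE],
                 seed = NA_integer_,
                 insertion_order = as.integer(order)),
            class = "pathway_dag")
}

#' @export
print.pathway_dag <- function(x, ...) {
  cat(sprintf("Pathway DAG '%s': %d nodes, %d edges kept, %d dropped (seed %s)\n",
              x$name, length(x$nodes), nrow(x$kept_edges),
              nrow(x$dropped_edges), format(x$seed)))
  invisible(x)
}

#' Parents of each node in a pathway DAG
#' @param dag A `pathway_dag`.
#' @return Named list: for each node, the character vector of its parents.
#' @export
dag_parents <- function(dag) {
  parents <- stats::setNames(rep(list(character(0)), length(dag$nodes)), dag$nodes)
  e <- dag$kept_edges
  for (i in seq_len(nrow(e))) parents[[e[i, 2L]]] <- c(parents[[e[i, 2L]]], e[i, 1L])
  parents
}

#' Topological node order of a pathway DAG
#' @param dag A `pathway_dag`.
#' @return Character vector of nodes, parents before children.
#' @export
topological_order <- function(dag) {
  ord <- .topo_sort(dag$nodes, dag$kept_edges)
  if (is.null(ord)) stop("kept edges contain a cycle; not a DAG")
  ord
}
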