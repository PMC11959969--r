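#' Undirected graph structure
#'
#' A labelled undirected graph: the conditional-independence skeleton of a
#' multimorbidity network. No self-loops; the adjacency matrix is symmetric
#' with a zero diagonal and is kept consistent with the edge list.
#'
#' @param nodes character vector of node labels (ordered).
#' @param edges optional two-column matrix / data frame of node-label pairs.
#' @param adjacency optional symmetric logical matrix (alternative to
#'   `edges`; exactly one of the two may be given, or neither for the empty
#'   graph).
#'
#' @return Object of class `graph_structure` with elements `nodes`,
#'   `edges` (two-column character matrix, each pair listed once with the
#'   lower node order first) and `adjacency`.
#' @export
graph_structure <- function(nodes, edges = NULL, adjacency = NULL) {
  nodes <- as.character(nodes)
  p <- length(nodes)
  if (anyDuplicated(nodes)) stop_morbnet("duplicate node labels")
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(adjacency)) {
    adjacency <- as.matrix(adjacency)
    if (!all(dim(adjacency) == c(p, p))) {
      stop_morbnet("'adjacency' must be ", p, "x", p)
    }
    adjacency <- adjacency != 0
    if (!isTRUE(all(adjacency == t(adjacency)))) {
      stop_morbnet("'adjacency' must be symmetric")
    }
    diag(adjacency) <- FALSE
    adj <- adjacency
    dimnames(adj) <- list(nodes, nodes)
  } else if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop_morbnet("'edges' must have two columns")
    ii <- match(edges[, 1L], nodes)
    jj <- match(edges[, 2L], nodes)
    if (anyNA(ii) || anyNA(jj)) {
      stop_morbnet("edge endpoint not among the node labels")
    }
    if (any(ii == jj)) stop_morbnet("self-loops are not allowed")
    adj[cbind(ii, jj)] <- TRUE
    adj[cbind(jj, ii)] <- TRUE
  }
  el <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- cbind(from = nodes[el[, 1L]], to = nodes[el[, 2L]])
  structure(list(nodes = nodes, edges = edges, adjacency = adj),
            class = "graph_structure")
}

#' @export
print.graph_structure <- function(x, ...) {
  cat("Undirected graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, density", signif(graph_density(x), 3), "\n")
  invisible(x)
}

n_edges <- function(structure) nrow(structure$edges)

# Canonical per-edge keys (sorted label pairs).
structure_edge_keys <- function(structure) {
  if (nrow(structure$edges) == 0L) return(character(0))
  edge_key(structure$edges[, 1L], structure$edges[, 2L])
}

as_igraph <- function(structure) {
  igraph::graph_from_adjacency_matrix(structure$adjacency * 1,
                                      mode = "undirected")
}

#' Graph density
#'
#' Number of edges divided by the number of possible edges `p(p-1)/2`.
#'
#' @param structure a [graph_structure()].
#' @return A proportion in `[0, 1]`.
#' @export
graph_density <- function(structure) {
  p <- length(structure$nodes)
  if (p < 2L) stop_morbnet("density needs at least 2 nodes")
  nrow(structure$edges) / (p * (p - 1) / 2)
}

#' Edge-set differences between two graphs on the same nodes
#'
#' Partition of the union of two edge sets into edges only in the first
#' graph, only in the second, and shared — the comparison used when
#' contrasting subgroup networks (e.g. associations present in women but
#' absent in men).
#'
#' @param a,b [graph_structure()] objects on the same node set.
#' @return List with character-matrix elements `only_in_a`, `only_in_b`,
#'   `shared` (two columns, one row per edge).
#' @export
edge_differences <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) {
    stop_morbnet("graphs must share the same node set")
  }
  ka <- structure_edge_keys(a)
  kb <- structure_edge_keys(b)
  unkey <- function(k) {
    if (length(k) == 0L) {
      return(matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to"))))
    }
    m <- do.call(rbind, strsplit(k, "|", fixed = TRUE))
    colnames(m) <- c("from", "to")
    m
  }
  list(only_in_a = unkey(setdiff(ka, kb)),
       only_in_b = unkey(setdiff(kb, ka)),
       shared = unkey(intersect(ka, kb)))
}
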