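#' All-pairs shortest-path hop distances
#'
#' Unweighted shortest-path distances on the learned graph; `d(i,i) = 0`,
#' symmetric. Unreachable pairs are assigned distance `p` (one more than
#' the longest possible path), a convention that keeps closeness finite
#' and ranks isolated nodes last; a message flags disconnected graphs.
#'
#' @param structure a [graph_structure()].
#' @return Symmetric numeric matrix of hop distances.
#' @export
shortest_path_lengths <- function(structure) {
  p <- length(structure$nodes)
  d <- igraph::distances(as_igraph(structure))
  if (any(is.infinite(d))) {
    message("disconnected graph: unreachable distances set to p = ", p)
    d[is.infinite(d)] <- p
  }
  dimnames(d) <- list(structure$nodes, structure$nodes)
  d
}

#' Raw closeness centrality
#'
#' `closeness(i) = 1 / sum_{j != i} d(i, j)`: the more central a node, the
#' closer it is to all others. Distances follow the
#' [shortest_path_lengths()] convention for unreachable pairs.
#'
#' @param structure a [graph_structure()] with `p >= 2`.
#' @return Named vector of raw closeness values.
#' @export
closeness_centrality <- function(structure) {
  if (length(structure$nodes) < 2L) stop_morbnet("need p >= 2")
  d <- suppressMessages(shortest_path_lengths(structure))
  1 / rowSums(d)
}

#' Raw betweenness centrality
#'
#' `betweenness(i) = sum_{(s,t): s != t != i} sigma_st(i) / sigma_st` over
#' unordered pairs, where `sigma_st` counts shortest s–t paths and
#' `sigma_st(i)` those passing through `i`: how often a node bridges the
#' shortest path between two others.
#'
#' @param structure a [graph_structure()] with `p >= 3`.
#' @return Named vector of raw betweenness values.
#' @export
betweenness_centrality <- function(structure) {
  if (length(structure$nodes) < 3L) stop_morbnet("need p >= 3")
  b <- igraph::betweenness(as_igraph(structure), directed = FALSE)
  stats::setNames(as.numeric(b), structure$nodes)
}

minmax_norm <- function(v) {
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    message("all raw centrality values equal; normalized values set to 0")
    return(stats::setNames(rep(0, length(v)), names(v)))
  }
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

#' Ordered centrality table with min–max normalization
#'
#' Closeness and betweenness centrality, each min–max normalized to
#' `[0, 1]` so that 1 marks the most central node of the network and 0 the
#' most peripheral; rows are ordered by descending normalized closeness
#' (ties broken by node order). The graph density is attached.
#'
#' @param structure a [graph_structure()] with `p >= 3`.
#' @return Object of class `centrality_result`: a data frame with columns
#'   `node`, `closeness_raw`, `betweenness_raw`, `closeness`,
#'   `betweenness`, plus attribute `density`.
#' @export
centrality_table <- function(structure) {
  cl <- closeness_centrality(structure)
  bt <- betweenness_centrality(structure)
  tab <- data.frame(node = structure$nodes,
                    closeness_raw = unname(cl),
                    betweenness_raw = unname(bt),
                    closeness = unname(minmax_norm(cl)),
                    betweenness = unname(minmax_norm(bt)))
  tab <- tab[order(-tab$closeness, seq_len(nrow(tab))), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "density") <- graph_density(structure)
  class(tab) <- c("centrality_result", "data.frame")
  tab
}

#' @export
print.centrality_result <- function(x, digits = 3, ...) {
  cat("Centrality table (density ",
      signif(attr(x, "density"), 3), "):\n", sep = "")
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
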