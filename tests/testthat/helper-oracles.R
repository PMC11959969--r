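# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct enumeration, Floyd-Warshall, explicit
# path enumeration, and the textbook Holm step-down formula.

# Holm step-down by direct enumeration of the adjustment formula.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix,
# unreachable pairs mapped to p.
floyd_warshall <- function(adj) {
  p <- nrow(adj)
  d <- matrix(Inf, p, p)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d[is.infinite(d)] <- p
  d
}

# All simple paths between s and t by depth-first enumeration.
all_simple_paths_bf <- function(adj, s, t) {
  p <- nrow(adj)
  paths <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in which(adj[last, ] > 0)) {
      if (!(nb %in% path)) recurse(c(path, nb))
    }
  }
  recurse(s)
  paths
}

# Brute-force closeness and betweenness with the unreachable-distance = p
# convention and shortest paths counted by explicit enumeration.
bf_centrality <- function(adj) {
  p <- nrow(adj)
  d <- floyd_warshall(adj)
  closeness <- 1 / rowSums(d)
  betw <- numeric(p)
  for (s in 1:(p - 1)) {
    for (t in (s + 1):p) {
      paths <- all_simple_paths_bf(adj, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1)) - 1L
      short <- paths[lens == min(lens)]
      sigma <- length(short)
      for (i in seq_len(p)) {
        if (i == s || i == t) next
        through <- sum(vapply(short, function(pa) i %in% pa, logical(1)))
        betw[i] <- betw[i] + through / sigma
      }
    }
  }
  list(closeness = closeness, betweenness = betw)
}

# Random undirected graph structure on `p` labelled nodes.
rand_structure <- function(p, prob = 0.4) {
  nodes <- LETTERS[seq_len(p)]
  adj <- matrix(0L, p, p)
  adj[upper.tri(adj)] <- rbinom(p * (p - 1) / 2, 1L, prob)
  adj <- adj + t(adj)
  graph_structure(nodes, adjacency = adj)
}

# Chain-graph Ising truth: lambda on consecutive pairs only.
chain_params <- function(p, lam = log(3), main = -1) {
  labels <- paste0("X", seq_len(p))
  inter <- matrix(0, p, p)
  for (i in seq_len(p - 1)) inter[i, i + 1] <- inter[i + 1, i] <- lam
  ising_params(labels, rep(main, p), inter)
}

# Star graph structure: node 1 is the hub.
star_structure <- function(p) {
  nodes <- paste0("N", seq_len(p))
  graph_structure(nodes, edges = cbind(nodes[1], nodes[-1]))
}
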