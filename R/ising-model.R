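#' Ising model parameters
#'
#' Container for the parameters of an Ising model on `{0,1}`-coded binary
#' variables: one main effect \eqn{\lambda_i} per variable (log-odds scale)
#' and one symmetric pairwise interaction \eqn{\lambda_{ij}} per variable
#' pair (log conditional odds-ratio scale). A zero interaction corresponds
#' to a missing edge, i.e. conditional independence of the two variables
#' given all others. With the `{0,1}` coding used throughout this package,
#' `exp(lambda_ij)` is exactly the conditional odds ratio of the pair at
#' any fixed configuration of the remaining variables.
#'
#' @param labels character vector of variable names.
#' @param main_effects numeric vector of main effects, one per label.
#' @param interactions symmetric numeric matrix of pairwise interactions
#'   with zero diagonal; entry `[i, j]` is \eqn{\lambda_{ij}}.
#' @param structure optional [graph_structure()]; when omitted it is derived
#'   from the non-zero pattern of `interactions`. When supplied, all
#'   interactions off its edge set must be exactly zero.
#' @param se optional list with elements `main_effects` and `interactions`
#'   holding standard errors of the free parameters (filled by
#'   [fit_ising_mle()]).
#'
#' @return An object of class `ising_params`.
#' @export
ising_params <- function(labels, main_effects, interactions,
                         structure = NULL, se = NULL) {
  p <- length(labels)
  if (p < 1L || anyDuplicated(labels)) {
    stop_morbnet("'labels' must be a non-empty vector of unique names")
  }
  main_effects <- as.numeric(main_effects)
  if (length(main_effects) != p) {
    stop_morbnet("'main_effects' must have one entry per label")
  }
  interactions <- as.matrix(interactions)
  if (!all(dim(interactions) == c(p, p))) {
    stop_morbnet("'interactions' must be a ", p, "x", p, " matrix")
  }
  if (max(abs(interactions - t(interactions))) > 1e-12) {
    stop_morbnet("'interactions' must be symmetric (lambda_ij = lambda_ji)")
  }
  if (any(diag(interactions) != 0)) {
    stop_morbnet("'interactions' must have a zero diagonal")
  }
  dimnames(interactions) <- list(labels, labels)
  names(main_effects) <- labels
  if (is.null(structure)) {
    structure <- graph_structure(labels, adjacency = interactions != 0)
  } else {
    if (!identical(structure$nodes, labels)) {
      stop_morbnet("'structure' nodes must match 'labels' in order")
    }
    off <- interactions[!structure$adjacency & !diag(p)]
    if (any(off != 0)) {
      stop_morbnet("non-zero interaction outside the declared edge set")
    }
  }
  structure(list(labels = labels, main_effects = main_effects,
                 interactions = interactions, structure = structure,
                 se = se),
            class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat("Ising model parameters:", length(x$labels), "variables,",
      nrow(x$structure$edges), "edges\n")
  cat("  main effects (log-odds):",
      paste0(x$labels, "=", signif(x$main_effects, 3), collapse = " "), "\n")
  invisible(x)
}

#' Canonical binary state space
#'
#' All `2^p` binary vectors in binary-counting order with variable 1 as the
#' least-significant bit: state `k` (1-based) has `x_i = bit (i-1)` of
#' `k - 1`. This canonical order is shared by [enumerate_joint()] and all
#' enumeration-based computations so results are reproducible against
#' external oracles.
#'
#' @param p number of binary variables.
#' @return Integer matrix with `2^p` rows and `p` columns.
#' @export
state_space <- function(p) {
  idx <- 0:(2^p - 1)
  vapply(seq_len(p), function(i) (idx %/% 2^(i - 1)) %% 2, numeric(2^p))
}

#' Enumerate the exact Ising joint distribution
#'
#' Computes the full normalized joint distribution of an Ising model by
#' explicit enumeration of all `2^p` states. The unnormalized
#' log-probability of a state \eqn{x \in \{0,1\}^p} is
#' \eqn{\sum_i \lambda_i x_i + \sum_{i<j} \lambda_{ij} x_i x_j};
#' normalization uses a log-sum-exp over the state space.
#'
#' @param params an [ising_params()] object.
#' @param limit maximum `p` for enumeration (default 20).
#' @return Object of class `joint_distribution` with elements `labels`,
#'   `states` (the canonical [state_space()]) and `prob`.
#' @export
enumerate_joint <- function(params, limit = 20L) {
  stopifnot(inherits(params, "ising_params"))
  p <- length(params$labels)
  if (p > limit) {
    stop_morbnet("enumeration limit exceeded: p = ", p, " > ", limit,
                 " (2^p states); use the gibbs sampler / pseudo-likelihood")
  }
  states <- state_space(p)
  logw <- drop(states %*% params$main_effects) +
    rowSums((states %*% params$interactions) * states) / 2
  m <- max(logw)
  logz <- m + log(sum(exp(logw - m)))
  structure(list(labels = params$labels, states = states,
                 prob = exp(logw - logz), logz = logz),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat("Exact Ising joint distribution over", nrow(x$states), "states of",
      length(x$labels), "variables\n")
  invisible(x)
}

# One-variable marginals E[X_i] of an enumerated joint.
joint_marginals <- function(joint) {
  m <- drop(crossprod(joint$states, joint$prob))
  names(m) <- joint$labels
  m
}

# Pairwise moments E[X_i X_j] (matrix; diagonal = marginals).
joint_pair_moments <- function(joint) {
  m <- crossprod(joint$states, joint$prob * joint$states)
  dimnames(m) <- list(joint$labels, joint$labels)
  m
}

# 2x2 probability table of (i, j) collapsed over the remaining variables,
# returned as c(p11, p10, p01, p00).
joint_pair_table <- function(joint, i, j) {
  xi <- joint$states[, i]
  xj <- joint$states[, j]
  c(p11 = sum(joint$prob[xi == 1 & xj == 1]),
    p10 = sum(joint$prob[xi == 1 & xj == 0]),
    p01 = sum(joint$prob[xi == 0 & xj == 1]),
    p00 = sum(joint$prob[xi == 0 & xj == 0]))
}

# Marginal (collapsed) odds ratio of a pair under the exact joint.
marginal_or_from_joint <- function(joint, i, j) {
  t <- joint_pair_table(joint, i, j)
  (t["p11"] * t["p00"]) / (t["p10"] * t["p01"])
}

# Conditional odds ratios of (i, j) at every configuration of the remaining
# variables under the exact joint. Returns a vector of length 2^(p-2)
# (NA where a stratum has zero probability).
conditional_or_from_joint <- function(joint, i, j) {
  labels <- joint$labels
  if (is.character(i)) i <- match(i, labels)
  if (is.character(j)) j <- match(j, labels)
  p <- length(labels)
  others <- setdiff(seq_len(p), c(i, j))
  key <- if (length(others)) {
    drop(joint$states[, others, drop = FALSE] %*% 2^(seq_along(others) - 1))
  } else {
    rep(0, nrow(joint$states))
  }
  cell <- 2 * joint$states[, i] + joint$states[, j] # 0=00 1=01 2=10 3=11
  nconf <- 2^length(others)
  tab <- matrix(0, nconf, 4)
  for (s in seq_along(key)) {
    tab[key[s] + 1, cell[s] + 1] <- tab[key[s] + 1, cell[s] + 1] + joint$prob[s]
  }
  or <- (tab[, 4] * tab[, 1]) / (tab[, 3] * tab[, 2])
  or[apply(tab, 1, function(r) any(r == 0))] <- NA_real_
  or
}

#' Exact Ising log-likelihood of a binary cohort
#'
#' Sum over individuals of the log-probability of their disease profile
#' under the enumerated Ising joint. Requires `p <= limit` because the
#' normalizing constant is computed by state enumeration.
#'
#' @param params an [ising_params()] object whose labels all appear as
#'   columns of `cohort`.
#' @param cohort a data frame of 0/1 columns (see [as_binary_cohort()]).
#' @param limit enumeration limit on the number of variables.
#' @return The scalar log-likelihood (always `<= 0`).
#' @export
ising_loglik <- function(params, cohort, limit = 20L) {
  x <- as.matrix(as.data.frame(cohort)[, params$labels, drop = FALSE])
  if (!all(x == 0 | x == 1)) stop_morbnet("cohort columns must be 0/1")
  joint <- enumerate_joint(params, limit = limit)
  p <- length(params$labels)
  idx <- drop(x %*% 2^(seq_len(p) - 1)) + 1
  sum(log(joint$prob[idx]))
}
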