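# Sufficient-statistic design over the state space for a given structure:
# columns are x_i (all nodes) then x_i x_j (edges only).
suff_stat_design <- function(states, structure) {
  ek <- structure$edges
  nodes <- structure$nodes
  extra <- if (nrow(ek)) {
    cols <- lapply(seq_len(nrow(ek)), function(r) {
      states[, match(ek[r, 1L], nodes)] * states[, match(ek[r, 2L], nodes)]
    })
    do.call(cbind, cols)
  } else {
    NULL
  }
  t_mat <- cbind(states, extra)
  colnames(t_mat) <- c(nodes,
                       if (nrow(ek)) paste0(ek[, 1L], ":", ek[, 2L]))
  t_mat
}

#' Joint maximum-likelihood fit of the Ising model on a fixed structure
#'
#' Maximizes the exact Ising log-likelihood over the free parameters — one
#' main effect per node plus one interaction per edge of the supplied
#' structure — by Newton iterations on the exponential-family form: the
#' gradient is observed-minus-expected sufficient statistics and the
#' Hessian their covariance under the model, both computed by state
#' enumeration (hence `p <= limit`). Deterministic zero initialization;
#' convergence when the gradient max-norm (per individual) falls below
#' `tol`. At the optimum the fitted expected one-node and edge moments
#' match the observed sample means (exponential-family moment matching).
#'
#' If any observed moment used in matching is exactly 0 or 1 the MLE is
#' not finite; the empirical moment vector is then shrunk toward the
#' uniform-distribution moments with weight `1/(2n)` and a warning is
#' issued.
#'
#' @param cohort a binary cohort whose columns include all structure
#'   nodes.
#' @param structure a [graph_structure()] restricting the interactions.
#' @param tol gradient max-norm convergence tolerance (default 1e-9).
#' @param max_iter maximum Newton iterations (default 200).
#' @param limit enumeration limit on `p` (default 20).
#' @return An [ising_params()] with standard errors (`se`) from the
#'   inverse observed information and attributes `loglik`, `gradient_norm`,
#'   `n`.
#' @export
fit_ising_mle <- function(cohort, structure, tol = 1e-9, max_iter = 200L,
                          limit = 20L) {
  stopifnot(inherits(structure, "graph_structure"))
  nodes <- structure$nodes
  p <- length(nodes)
  if (p > limit) {
    stop_morbnet("enumeration limit exceeded: p = ", p, " > ", limit)
  }
  x <- as.matrix(as.data.frame(cohort)[, nodes, drop = FALSE])
  if (!all(x == 0 | x == 1)) stop_morbnet("cohort columns must be 0/1")
  n <- nrow(x)
  states <- state_space(p)
  t_states <- suff_stat_design(states, structure)
  t_obs <- suff_stat_design(x, structure)
  s_obs <- colMeans(t_obs)
  if (any(s_obs == 0 | s_obs == 1)) {
    w <- 1 / (2 * n)
    s_unif <- colMeans(t_states) # moments under the uniform distribution
    s_obs <- (1 - w) * s_obs + w * s_unif
    warning("observed margin at 0 or 1; empirical moments shrunk toward ",
            "uniform with weight 1/(2n)", call. = FALSE)
  }
  d <- ncol(t_states)
  theta <- numeric(d)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    logw <- drop(t_states %*% theta)
    m <- max(logw)
    logz <- m + log(sum(exp(logw - m)))
    prob <- exp(logw - logz)
    mu <- drop(crossprod(t_states, prob))
    grad <- mu - s_obs                       # gradient of (A(theta) - theta.s)
    if (max(abs(grad)) < tol) { conv <- TRUE; break }
    h <- crossprod(t_states, prob * t_states) - tcrossprod(mu)
    step <- tryCatch(solve(h + diag(1e-10, d), grad),
                     error = function(e) grad)
    f0 <- logz - sum(theta * s_obs)
    alpha <- 1
    repeat {
      theta_new <- theta - alpha * step
      logw_n <- drop(t_states %*% theta_new)
      mn <- max(logw_n)
      f1 <- mn + log(sum(exp(logw_n - mn))) - sum(theta_new * s_obs)
      if (f1 <= f0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- theta_new
  }
  logw <- drop(t_states %*% theta)
  m <- max(logw)
  logz <- m + log(sum(exp(logw - m)))
  prob <- exp(logw - logz)
  mu <- drop(crossprod(t_states, prob))
  grad <- mu - s_obs
  if (!conv && max(abs(grad)) > 1e-6) {
    warning("Ising MLE did not reach gradient tolerance (max |grad| = ",
            signif(max(abs(grad)), 3), ")", call. = FALSE)
  }
  h <- crossprod(t_states, prob * t_states) - tcrossprod(mu)
  # observed information of the full sample = n * Cov(T); SEs from inverse
  info <- n * h
  se_vec <- tryCatch(sqrt(diag(solve(info))), error = function(e) {
    warning("singular information matrix; standard errors unavailable",
            call. = FALSE)
    rep(NA_real_, d)
  })
  main <- stats::setNames(theta[seq_len(p)], nodes)
  lam <- matrix(0, p, p, dimnames = list(nodes, nodes))
  se_main <- stats::setNames(se_vec[seq_len(p)], nodes)
  se_lam <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  ek <- structure$edges
  if (nrow(ek)) {
    for (r in seq_len(nrow(ek))) {
      i <- ek[r, 1L]; j <- ek[r, 2L]
      lam[i, j] <- lam[j, i] <- theta[p + r]
      se_lam[i, j] <- se_lam[j, i] <- se_vec[p + r]
    }
  }
  params <- ising_params(nodes, main, lam, structure = structure,
                         se = list(main_effects = se_main,
                                   interactions = se_lam))
  attr(params, "loglik") <- n * (sum(theta * s_obs) - logz)
  attr(params, "gradient_norm") <- max(abs(grad))
  attr(params, "n") <- n
  params
}

#' Conditional odds-ratio matrix from fitted Ising parameters
#'
#' `OR_ij = exp(lambda_ij)` for every edge of the fitted structure;
#' non-edges are left absent (`NA`), denoting conditional independence.
#' Yule's Q entries are `(OR - 1) / (OR + 1)`. Wald confidence intervals
#' and p-values are included where standard errors are available.
#'
#' @param params a fitted [ising_params()] (e.g. from [fit_ising_mle()]).
#' @param conf_level confidence level for the Wald intervals.
#' @return An `association_matrix` of kind `"conditional"`.
#' @export
conditional_or_matrix <- function(params, conf_level = 0.95) {
  stopifnot(inherits(params, "ising_params"))
  nodes <- params$labels
  p <- length(nodes)
  adj <- params$structure$adjacency
  or <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  or[adj] <- exp(params$interactions[adj])
  se <- params$se$interactions
  lo <- hi <- pv <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  if (!is.null(se)) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo[adj] <- exp(params$interactions[adj] - z * se[adj])
    hi[adj] <- exp(params$interactions[adj] + z * se[adj])
    pv[adj] <- 2 * stats::pnorm(-abs(params$interactions[adj] / se[adj]))
  }
  ph <- pv
  up <- upper.tri(pv) & adj
  if (any(up) && !anyNA(pv[up])) {
    ph[up] <- holm_adjust(pv[up])
    ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  }
  structure(list(kind = "conditional", labels = nodes, or = or,
                 ci_low = lo, ci_high = hi, p = pv, p_holm = ph,
                 q = yules_q(or), alpha = NA_real_,
                 n_tests = sum(adj) / 2),
            class = "association_matrix")
}

#' Per-edge Wald tests of the fitted interactions
#'
#' Wald statistics `z = lambda_hat / SE` with two-sided p-values for every
#' edge of a fitted Ising model, using standard errors from the inverse
#' observed information.
#'
#' @param params a fitted [ising_params()] with standard errors.
#' @return Data frame with one row per edge: `from`, `to`, `lambda`, `or`,
#'   `se`, `z`, `p`.
#' @export
edge_wald <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  if (is.null(params$se)) {
    stop_morbnet("no standard errors; fit the model with fit_ising_mle()")
  }
  ek <- params$structure$edges
  if (nrow(ek) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      lambda = numeric(0), or = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0)))
  }
  lam <- params$interactions[ek]
  se <- params$se$interactions[ek]
  z <- lam / se
  z[lam == 0 & se == 0] <- 0
  data.frame(from = ek[, 1L], to = ek[, 2L], lambda = lam, or = exp(lam),
             se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
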