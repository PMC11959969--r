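#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + k log(n) + 2 gamma k log(m)` for a fitted model with
#' `k` free parameters, sample size `n` and `m` candidate predictors;
#' `gamma = 0` reduces exactly to the BIC.
#'
#' @param loglik fitted log-likelihood.
#' @param k number of free parameters (`>= 0`).
#' @param n sample size (`>= 1`).
#' @param m number of candidate predictors (`>= 1`).
#' @param gamma EBIC weight in `[0, 1]`.
#' @return The EBIC score (smaller is better).
#' @export
ebic <- function(loglik, k, n, m, gamma = 0.25) {
  if (length(gamma) != 1L || is.na(gamma) || gamma < 0 || gamma > 1) {
    stop_morbnet("'gamma' must lie in [0, 1]")
  }
  stopifnot(n >= 1, k >= 0, m >= 1)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(m)
}

# Aggregate 0/1 columns to unique row patterns with frequency weights.
# The weighted binomial log-likelihood over patterns equals the row-wise
# Bernoulli log-likelihood, so EBIC comparisons are unchanged while fit
# cost scales with the number of distinct profiles, not n.
aggregate_patterns <- function(df, cols) {
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  key <- drop(m %*% 2^(seq_along(cols) - 1))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(x = m[first, , drop = FALSE], w = tabulate(idx, nbins = sum(first)))
}

# Ridge-penalized weighted logistic Newton solver: fallback used when
# glm.fit does not converge or separates. The intercept is unpenalized;
# `ridge` is a small fixed L2 weight on the slopes, enough to keep the
# selection-time log-likelihood finite under separation.
logistic_ridge <- function(x, y, w, ridge = 1e-4, maxit = 100L,
                           tol = 1e-10) {
  d <- ncol(x)
  pen <- c(0, rep(ridge, d - 1L))
  beta <- numeric(d)
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(x, w * (y - mu))) - pen * beta
    wt <- pmax(w * mu * (1 - mu), 1e-10)
    h <- crossprod(x, wt * x) + diag(pen, d)
    step <- solve(h, g)
    beta <- beta + step
    if (max(abs(g)) < tol) break
  }
  mu <- stats::plogis(drop(x %*% beta))
  wt <- pmax(w * mu * (1 - mu), 1e-10)
  h <- crossprod(x, wt * x) + diag(pen, d)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  list(coefficients = beta, loglik = ll, vcov = solve(h), separated = TRUE)
}

# Weighted logistic fit of y on the columns of x (first column =
# intercept). Primary route: stats::glm.fit; on non-convergence or
# separation (unbounded coefficients) the ridge fallback is used and
# flagged.
fit_logistic <- function(x, y, w = rep(1, length(y))) {
  fit <- suppressWarnings(stats::glm.fit(x, y, weights = w,
                                         family = stats::binomial()))
  sep <- !fit$converged || fit$boundary ||
    max(abs(fit$coefficients)) > 15
  if (sep) return(logistic_ridge(x, y, w))
  vc <- tryCatch({
    r <- fit$qr
    cov <- chol2inv(qr.R(r))
    full <- matrix(NA_real_, ncol(x), ncol(x))
    piv <- r$pivot[seq_len(r$rank)]
    full[piv, piv] <- cov
    full
  }, error = function(e) NULL)
  list(coefficients = fit$coefficients, loglik = -fit$deviance / 2,
       vcov = vc, separated = FALSE)
}

#' Backward stepwise predictor elimination under EBIC
#'
#' Node-wise neighborhood selection for one response variable: starts from
#' the logistic regression of `y` on all candidate predictors and
#' repeatedly removes the predictor whose removal gives the lowest EBIC,
#' as long as that EBIC is strictly lower than the current model's. Among
#' removals tied within `1e-9`, the predictor with the smallest absolute
#' Wald z in the current model is removed first; remaining ties are broken
#' by variable order. Separated or non-convergent fits are replaced by a
#' small-ridge regularized fit for selection purposes (with a warning
#' naming the response).
#'
#' @param y response variable name.
#' @param candidates character vector of candidate predictor names
#'   (excluding `y`).
#' @param cohort a binary cohort.
#' @param gamma EBIC weight (default 0.25).
#' @return Object of class `nodewise_fit`: `response`, `selected`,
#'   `coefficients` (named, selected predictors), `intercept`, `ebic`,
#'   `trace` (data frame of accepted removals with the EBIC after each),
#'   `separated`.
#' @export
backward_stepwise <- function(y, candidates, cohort, gamma = 0.25) {
  cohort <- as.data.frame(cohort)
  if (y %in% candidates) stop_morbnet("'y' must not be among the candidates")
  m <- length(candidates)
  n <- nrow(cohort)
  agg <- aggregate_patterns(cohort, c(y, candidates))
  yv <- agg$x[, 1L]
  wv <- agg$w
  xall <- cbind(`(Intercept)` = 1, agg$x[, -1L, drop = FALSE])
  sel <- seq_len(m)          # indices into `candidates`
  any_sep <- FALSE
  do_fit <- function(idx) {
    f <- fit_logistic(xall[, c(1L, idx + 1L), drop = FALSE], yv, wv)
    f$ebic <- ebic(f$loglik, k = length(idx) + 1L, n = n, m = m,
                   gamma = gamma)
    f
  }
  cur <- do_fit(sel)
  any_sep <- any_sep || cur$separated
  trace <- data.frame(removed = character(0), ebic = numeric(0))
  while (length(sel) > 0L) {
    cand_fits <- lapply(seq_along(sel), function(k) do_fit(sel[-k]))
    scores <- vapply(cand_fits, `[[`, numeric(1), "ebic")
    best <- min(scores)
    if (!(best < cur$ebic)) break
    tied <- which(scores <= best + 1e-9)
    if (length(tied) > 1L) {
      # smallest |Wald z| in the *current* model goes first
      z <- rep(Inf, length(tied))
      if (!is.null(cur$vcov)) {
        se <- sqrt(diag(cur$vcov))[-1L]
        zc <- abs(cur$coefficients[-1L]) / se
        z <- zc[tied]
        z[is.na(z)] <- Inf
      }
      pick <- tied[order(z, tied)][1L]
    } else {
      pick <- tied
    }
    trace <- rbind(trace, data.frame(removed = candidates[sel[pick]],
                                     ebic = scores[pick]))
    cur <- cand_fits[[pick]]
    any_sep <- any_sep || cur$separated
    sel <- sel[-pick]
  }
  if (any_sep) {
    warning("separation in node-wise fit for '", y,
            "'; ridge-regularized fit used for selection", call. = FALSE)
  }
  coefs <- cur$coefficients
  structure(list(response = y, selected = candidates[sel],
                 coefficients = stats::setNames(coefs[-1L], candidates[sel]),
                 intercept = unname(coefs[1L]), ebic = cur$ebic,
                 trace = trace, separated = any_sep),
            class = "nodewise_fit")
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat("Node-wise fit for '", x$response, "': ", length(x$selected),
      " neighbor(s) [", paste(x$selected, collapse = ", "),
      "], EBIC = ", signif(x$ebic, 6), "\n", sep = "")
  invisible(x)
}

#' Learn the graph structure by node-wise logistic regression
#'
#' Runs [backward_stepwise()] for every node against all others (sex and
#' age-band covariates included as ordinary nodes when present) and
#' combines the local neighborhoods into one undirected graph. Under the
#' `AND` rule an edge (i, j) requires each node to select the other; under
#' `OR` either selection suffices.
#'
#' @param cohort a binary cohort; all analyzed columns must be
#'   non-constant.
#' @param gamma EBIC weight (default 0.25).
#' @param rule neighborhood combination rule, `"AND"` (default) or `"OR"`.
#' @param nodes columns to analyze (default: every binary node column).
#' @return A [graph_structure()] with the per-node fits in attribute
#'   `fits`.
#' @export
learn_structure <- function(cohort, gamma = 0.25, rule = c("AND", "OR"),
                            nodes = NULL) {
  rule <- match.arg(rule)
  cohort <- as_binary_cohort(cohort)
  nodes <- nodes %||% cohort_variables(cohort)
  const <- nodes[vapply(nodes, function(v) length(unique(cohort[[v]])) == 1L,
                        logical(1))]
  if (length(const)) {
    stop_morbnet("constant column(s): ", paste(const, collapse = ", "))
  }
  p <- length(nodes)
  fits <- lapply(nodes, function(v) {
    backward_stepwise(v, setdiff(nodes, v), cohort, gamma = gamma)
  })
  names(fits) <- nodes
  selmat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (v in nodes) selmat[v, fits[[v]]$selected] <- TRUE
  adj <- if (rule == "AND") selmat & t(selmat) else selmat | t(selmat)
  g <- graph_structure(nodes, adjacency = adj)
  attr(g, "fits") <- fits
  attr(g, "rule") <- rule
  attr(g, "gamma") <- gamma
  g
}
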