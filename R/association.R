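#' Cross-classify two binary variables
#'
#' Counts the 2x2 table of a pair of 0/1 columns: `a` = (1,1), `b` = (1,0),
#' `c` = (0,1), `d` = (0,0). The four counts partition the cohort.
#'
#' @param cohort a binary cohort (data frame of 0/1 columns).
#' @param i,j column names or indices of the two variables.
#' @return Object of class `two_by_two` with fields `a`, `b`, `c`, `d`,
#'   `pair`.
#' @export
two_by_two <- function(cohort, i, j) {
  cohort <- as.data.frame(cohort)
  if (is.numeric(i)) i <- names(cohort)[i]
  if (is.numeric(j)) j <- names(cohort)[j]
  if (identical(i, j)) stop_morbnet("'i' and 'j' must differ")
  x <- cohort[[i]]
  y <- cohort[[j]]
  if (!is_binary(x)) stop_morbnet("column '", i, "' is not 0/1 coded")
  if (!is_binary(y)) stop_morbnet("column '", j, "' is not 0/1 coded")
  structure(list(a = sum(x == 1 & y == 1), b = sum(x == 1 & y == 0),
                 c = sum(x == 0 & y == 1), d = sum(x == 0 & y == 0),
                 pair = c(i, j)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(paste0(x$pair[1], "=", 1:0),
                              paste0(x$pair[2], "=", 1:0)))
  print(m)
  invisible(x)
}

#' Marginal odds ratio of a 2x2 table with Wald inference
#'
#' `OR = a*d / (b*c)` with a two-sided Wald test of `log OR = 0` using
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)` and a 95% confidence interval on the
#' log scale. With `continuity = TRUE`, 0.5 is added to every cell
#' (Haldane–Anscombe) whenever any cell is zero; with it off, a zero cell
#' is an error naming the pair.
#'
#' @param table a [two_by_two()] table.
#' @param continuity apply the Haldane–Anscombe 0.5 correction on zero
#'   cells (default `FALSE`).
#' @param conf_level confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `log_or`, `se`.
#' @export
marginal_or <- function(table, continuity = FALSE, conf_level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    if (!continuity) {
      stop_morbnet("zero cell in the 2x2 table of pair (",
                   paste(table$pair, collapse = ", "),
                   "); set continuity = TRUE for the Haldane-Anscombe ",
                   "correction")
    }
    cells <- cells + 0.5
  }
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       p = 2 * stats::pnorm(-abs(log_or) / se),
       log_or = log_or, se = se)
}

#' Holm step-down adjustment of p-values
#'
#' Family-wise error rate control under arbitrary dependence of the
#' p-values: sort ascending, set adjusted p (k) to
#' `min(1, max_{j<=k} (m-j+1) p_(j))`, and return in the original order.
#' Implemented via [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_morbnet("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Yule's Q association coefficient
#'
#' `Q = (OR - 1) / (OR + 1)`, a symmetric transform of the odds ratio into
#' `[-1, 1]` with `Q(1) = 0` and `Q(OR) = -Q(1/OR)`; `OR = Inf` maps to 1.
#'
#' @param or positive odds ratio(s); `Inf` allowed.
#' @return Values in `[-1, 1]`.
#' @export
yules_q <- function(or) {
  bad <- !is.na(or) & or <= 0
  if (any(bad)) stop_morbnet("odds ratios must be positive")
  ifelse(is.infinite(or), 1, (or - 1) / (or + 1))
}

#' Matrix of pairwise marginal odds ratios with Holm correction
#'
#' Computes the odds ratio, Wald confidence interval and p-value for all
#' `p(p-1)/2` distinct variable pairs of the cohort, then Holm-adjusts the
#' p-values over the whole family of tests.
#'
#' @param cohort a binary cohort.
#' @param alpha nominal significance level recorded with the result
#'   (default 0.05).
#' @param continuity passed to [marginal_or()].
#' @param nodes columns to analyze (default: every binary node column).
#' @return Object of class `association_matrix` (kind `"marginal"`) with
#'   symmetric matrices `or`, `ci_low`, `ci_high`, `p`, `p_holm`, `q` and
#'   an `n_tests` field.
#' @export
marginal_or_matrix <- function(cohort, alpha = 0.05, continuity = FALSE,
                               nodes = NULL) {
  cohort <- as_binary_cohort(cohort)
  nodes <- nodes %||% cohort_variables(cohort)
  p <- length(nodes)
  if (p < 2L) stop_morbnet("need at least 2 variables")
  pairs <- utils::combn(p, 2L)
  mk <- function() matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  or <- mk(); lo <- mk(); hi <- mk(); pv <- mk()
  failed <- character(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    res <- tryCatch(
      marginal_or(two_by_two(cohort, nodes[i], nodes[j]), continuity),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, paste0("(", nodes[i], ", ", nodes[j], ")"))
      next
    }
    or[i, j] <- or[j, i] <- res$or
    lo[i, j] <- lo[j, i] <- res$ci_low
    hi[i, j] <- hi[j, i] <- res$ci_high
    pv[i, j] <- pv[j, i] <- res$p
  }
  if (length(failed)) {
    stop_morbnet("zero cell(s) with continuity off for pair(s) ",
                 paste(failed, collapse = ", "))
  }
  raw <- pv[upper.tri(pv)]
  ph <- mk()
  ph[upper.tri(ph)] <- holm_adjust(raw)
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  structure(list(kind = "marginal", labels = nodes, or = or, ci_low = lo,
                 ci_high = hi, p = pv, p_holm = ph, q = yules_q(or),
                 alpha = alpha, n_tests = ncol(pairs)),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, digits = 3, ...) {
  cat("Association matrix (", x$kind, "): ", length(x$labels),
      " variables\n", sep = "")
  print(round(x$or, digits))
  invisible(x)
}

#' Conditional 2x2 tables across all strata of the remaining variables
#'
#' For a pair (i, j) among `p >= 3` binary variables, enumerates all
#' `2^(p-2)` level combinations of the remaining variables and
#' cross-tabulates (i, j) within each stratum. Per-stratum odds ratios are
#' computed only where all four cells are positive; other strata are
#' flagged degenerate (`or = NA`). The tables summed over strata reproduce
#' the marginal [two_by_two()] table.
#'
#' @param cohort a binary cohort.
#' @param i,j the pair of variable names.
#' @param nodes the variable set to condition on (default: every binary
#'   node column of the cohort).
#' @return Object of class `conditional_strata` with `config` (a
#'   `2^(p-2) x (p-2)` 0/1 matrix of stratum configurations), `tables`
#'   (matrix of counts `a`, `b`, `c`, `d` per stratum), `or`, and
#'   `degenerate` (logical).
#' @export
conditional_strata_tables <- function(cohort, i, j, nodes = NULL) {
  cohort <- as_binary_cohort(cohort)
  nodes <- nodes %||% cohort_variables(cohort)
  if (length(nodes) < 3L) stop_morbnet("need p >= 3 variables")
  others <- setdiff(nodes, c(i, j))
  k <- length(others)
  xo <- as.matrix(as.data.frame(cohort)[, others, drop = FALSE])
  key <- drop(xo %*% 2^(seq_len(k) - 1))
  cell <- 2L * cohort[[i]] + cohort[[j]] # 3 = a(1,1), 2 = b(1,0), 1 = c, 0 = d
  nconf <- 2^k
  counts <- matrix(0L, nconf, 4L,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
  tab <- table(factor(key, levels = 0:(nconf - 1)),
               factor(cell, levels = c(3, 2, 1, 0)))
  counts[] <- as.integer(tab)
  config <- state_space(k)
  colnames(config) <- others
  or <- (counts[, "a"] * counts[, "d"]) / (counts[, "b"] * counts[, "c"])
  degenerate <- apply(counts == 0L, 1L, any)
  or[degenerate] <- NA_real_
  structure(list(pair = c(i, j), conditioning = others, config = config,
                 tables = counts, or = or, degenerate = degenerate),
            class = "conditional_strata")
}

#' @export
print.conditional_strata <- function(x, ...) {
  cat("Conditional 2x2 tables of (", x$pair[1], ", ", x$pair[2], ") over ",
      nrow(x$tables), " strata of ", length(x$conditioning),
      " variables (", sum(!x$degenerate), " non-degenerate)\n", sep = "")
  invisible(x)
}
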