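#' Balance the sexes within five-year age bands
#'
#' Within each age band (closed-open intervals of `band_width` years
#' starting at 65, last band open-ended at `age_cap`), retains an equal
#' number of men and women by seeded sampling without replacement from the
#' larger sex. Retained rows are unchanged. Because women are on average
#' older than men, comparing unbalanced sex strata would confound sex with
#' age; this extraction removes that imbalance.
#'
#' @param cohort a binary cohort with `sex` and integer `age_years`
#'   columns.
#' @param band_width band width in years (default 5).
#' @param seed RNG seed for the subsampling.
#' @param age_cap age at which the open-ended last band starts
#'   (default 85).
#' @return The balanced cohort (a subset of the input rows).
#' @export
age_balance <- function(cohort, band_width = 5, seed = 1L, age_cap = 85) {
  cohort <- as_binary_cohort(cohort)
  if (!("age_years" %in% names(cohort))) {
    stop_morbnet("'age_years' column required for age balancing")
  }
  if (!("sex" %in% names(cohort))) stop_morbnet("'sex' column required")
  if (band_width < 1) stop_morbnet("'band_width' must be >= 1")
  age <- cohort$age_years
  band <- pmin(floor(pmax(age - 65, 0) / band_width),
               floor((age_cap - 65) / band_width))
  keep <- with_seed(seed, {
    idx <- integer(0)
    for (b in sort(unique(band))) {
      rows <- which(band == b)
      men <- rows[cohort$sex[rows] == 1L]
      women <- rows[cohort$sex[rows] == 0L]
      k <- min(length(men), length(women))
      pick <- function(v) if (length(v) > k) sort(sample(v, k)) else v
      idx <- c(idx, pick(men), pick(women))
    }
    sort(idx)
  })
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_binary_cohort(out)
}

#' Stratified multimorbidity networks by sex and age band
#'
#' Splits the cohort into the four sex-by-age-band strata (women/men
#' crossed with the younger and older band), then learns the structure and
#' fits the Ising model independently within each stratum on the disease
#' nodes only (sex and age band are constant within a stratum). Strata
#' where a disease indicator is constant are flagged and skipped. For
#' every pair of strata the edge-difference sets and, on shared edges,
#' two-sample log-odds-ratio comparisons are reported.
#'
#' @param cohort a binary cohort with `sex` and `age_band` columns.
#' @param gamma EBIC weight (default 0.25), shared across strata for
#'   comparability.
#' @param rule neighborhood combination rule (default `"AND"`).
#' @param holm Holm-adjust the shared-edge comparison p-values within each
#'   stratum pair (default `FALSE`).
#' @return Object of class `stratified_result`: `strata` (per-stratum
#'   list with `n`, `structure`, `params`, `conditional`, `density`, or a
#'   `flagged` reason), and `comparisons` (per stratum pair: edge
#'   differences and a data frame of shared-edge tests).
#' @export
stratified_networks <- function(cohort, gamma = 0.25, rule = "AND",
                                holm = FALSE) {
  cohort <- as_binary_cohort(cohort)
  for (v in c("sex", "age_band")) {
    if (!(v %in% names(cohort))) stop_morbnet("'", v, "' column required")
  }
  diseases <- cohort_diseases(cohort)
  sex_lab <- c(`0` = "F", `1` = "M")
  age_lab <- c(`0` = "65-75", `1` = "76+")
  strata <- list()
  for (s in 0:1) {
    for (a in 0:1) {
      name <- paste0(sex_lab[as.character(s)], "/",
                     age_lab[as.character(a)])
      rows <- cohort$sex == s & cohort$age_band == a
      sub <- as.data.frame(cohort)[rows, diseases, drop = FALSE]
      const <- names(sub)[vapply(sub, function(x) length(unique(x)) == 1L,
                                 logical(1))]
      if (nrow(sub) == 0L || length(const)) {
        strata[[name]] <- list(n = nrow(sub), flagged = TRUE,
                               reason = paste("constant column(s):",
                                              paste(const, collapse = ", ")))
        warning("stratum ", name, " flagged: ",
                strata[[name]]$reason, call. = FALSE)
        next
      }
      sub <- as_binary_cohort(sub)
      g <- learn_structure(sub, gamma = gamma, rule = rule)
      fit <- fit_ising_mle(sub, g)
      strata[[name]] <- list(n = nrow(sub), flagged = FALSE, structure = g,
                             params = fit,
                             conditional = conditional_or_matrix(fit),
                             density = graph_density(g))
    }
  }
  ok <- names(strata)[!vapply(strata, `[[`, logical(1), "flagged")]
  comparisons <- list()
  if (length(ok) >= 2L) {
    for (pair in utils::combn(ok, 2L, simplify = FALSE)) {
      a <- strata[[pair[1L]]]; b <- strata[[pair[2L]]]
      diff <- edge_differences(a$structure, b$structure)
      shared <- diff$shared
      tests <- if (nrow(shared)) {
        rows <- lapply(seq_len(nrow(shared)), function(r) {
          cmp <- compare_edge_logor(a$params, b$params, shared[r, ])
          data.frame(from = shared[r, 1L], to = shared[r, 2L],
                     lambda_a = cmp$lambda_a, lambda_b = cmp$lambda_b,
                     difference = cmp$difference, z = cmp$z, p = cmp$p)
        })
        out <- do.call(rbind, rows)
        out$p_holm <- if (holm) holm_adjust(out$p) else NA_real_
        out
      } else {
        data.frame()
      }
      comparisons[[paste(pair, collapse = " vs ")]] <-
        list(strata = pair, only_in_a = diff$only_in_a,
             only_in_b = diff$only_in_b, shared = shared, tests = tests)
    }
  }
  structure(list(strata = strata, comparisons = comparisons,
                 gamma = gamma, rule = rule),
            class = "stratified_result")
}

#' @export
print.stratified_result <- function(x, ...) {
  cat("Stratified multimorbidity networks:\n")
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    if (isTRUE(s$flagged)) {
      cat("  ", nm, ": flagged (", s$reason, ")\n", sep = "")
    } else {
      cat("  ", nm, ": n = ", s$n, ", ", nrow(s$structure$edges),
          " edges, density ", signif(s$density, 3), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Compare one edge's log conditional odds ratio between two strata
#'
#' Two-sample z test of the difference in fitted interaction
#' `lambda_a - lambda_b` between independently fitted strata, with
#' `SE = sqrt(SE_a^2 + SE_b^2)` and a two-sided p-value. If the edge is
#' absent from either structure the strengths are not comparable (the
#' association exists in one group only) and a not-comparable result is
#' returned.
#'
#' @param params_a,params_b fitted [ising_params()] for the two strata.
#' @param edge length-2 character vector of node labels.
#' @return List with `comparable`, and when comparable `lambda_a`,
#'   `lambda_b`, `difference`, `se`, `z`, `p`.
#' @export
compare_edge_logor <- function(params_a, params_b, edge) {
  edge <- as.character(edge)
  stopifnot(length(edge) == 2L)
  has <- function(par) {
    all(edge %in% par$labels) && par$structure$adjacency[edge[1L], edge[2L]]
  }
  if (!has(params_a) || !has(params_b)) {
    return(list(comparable = FALSE,
                reason = "edge absent in at least one stratum",
                lambda_a = NA_real_, lambda_b = NA_real_,
                difference = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_))
  }
  la <- params_a$interactions[edge[1L], edge[2L]]
  lb <- params_b$interactions[edge[1L], edge[2L]]
  sa <- params_a$se$interactions[edge[1L], edge[2L]]
  sb <- params_b$se$interactions[edge[1L], edge[2L]]
  if (is.null(sa) || is.null(sb) || is.na(sa) || is.na(sb)) {
    stop_morbnet("standard errors unavailable for the compared edge")
  }
  se <- sqrt(sa^2 + sb^2)
  z <- (la - lb) / se
  list(comparable = TRUE, lambda_a = la, lambda_b = lb,
       difference = la - lb, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
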