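make_aged_cohort <- function(n_men, n_women, ages_men, ages_women,
                             seed = 1) {
  set.seed(seed)
  data.frame(D1 = rbinom(n_men + n_women, 1, 0.2),
             sex = rep(c(1L, 0L), c(n_men, n_women)),
             age_years = c(ages_men, ages_women),
             age_band = as.integer(c(ages_men, ages_women) >= 76))
}

test_that("age balancing equalizes the sexes within each band", {
  cohort <- make_aged_cohort(100, 80, rep(67, 100), rep(68, 80))
  bal <- age_balance(cohort, seed = 3)
  expect_equal(sum(bal$sex == 1), 80)
  expect_equal(sum(bal$sex == 0), 80)
  # already balanced: unchanged up to row order
  bal2 <- age_balance(bal, seed = 5)
  expect_equal(nrow(bal2), nrow(bal))
  # determinism and row preservation
  cohort2 <- make_aged_cohort(50, 70, sample(65:90, 50, TRUE),
                              sample(65:90, 70, TRUE), seed = 2)
  b1 <- age_balance(cohort2, seed = 11)
  b2 <- age_balance(cohort2, seed = 11)
  expect_identical(b1, b2)
  expect_lte(nrow(b1), nrow(cohort2))
  # every retained row appears verbatim in the input
  key_in <- do.call(paste, as.data.frame(cohort2))
  key_out <- do.call(paste, as.data.frame(b1))
  expect_true(all(key_out %in% key_in))
  # per-band counts never increase
  band <- function(df) floor(pmax(df$age_years - 65, 0) / 5)
  tab_in <- table(band(cohort2))
  tab_out <- table(factor(band(b1), levels = names(tab_in)))
  expect_true(all(tab_out <= tab_in))
  expect_error(age_balance(cohort2[, c("D1", "sex")]), "age_years")
})

test_that("edge differences partition the union of edge sets", {
  a <- graph_structure(c("A", "B", "C"), edges = cbind("A", "B"))
  b <- graph_structure(c("A", "B", "C"), edges = cbind("B", "C"))
  d <- edge_differences(a, b)
  expect_equal(nrow(d$only_in_a), 1L)
  expect_equal(nrow(d$only_in_b), 1L)
  expect_equal(nrow(d$shared), 0L)
  expect_equal(nrow(d$only_in_a) + nrow(d$shared), nrow(a$edges))
  same <- edge_differences(a, a)
  expect_equal(nrow(same$only_in_a), 0L)
  expect_equal(nrow(same$only_in_b), 0L)
  expect_error(edge_differences(a, graph_structure(c("A", "B"))),
               "node set")
})

test_that("edge log-OR comparison is a two-sample z test with antisymmetry", {
  pars <- chain_params(4, lam = log(2), main = -0.8)
  ca <- sample_cohort(simulation_spec(pars, n = 3000, seed = 51))
  cb <- sample_cohort(simulation_spec(pars, n = 3000, seed = 52))
  fa <- fit_ising_mle(ca, pars$structure)
  fb <- fit_ising_mle(cb, pars$structure)
  edge <- c("X1", "X2")
  self <- compare_edge_logor(fa, fa, edge)
  expect_equal(self$difference, 0)
  expect_equal(self$p, 1)
  ab <- compare_edge_logor(fa, fb, edge)
  ba <- compare_edge_logor(fb, fa, edge)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$se, sqrt(fa$se$interactions["X1", "X2"]^2 +
                             fb$se$interactions["X1", "X2"]^2))
  # absent edge: explicit not-comparable signal
  nc <- compare_edge_logor(fa, fb, c("X1", "X3"))
  expect_false(nc$comparable)
})

test_that("stratified networks fit each sex-by-age stratum independently", {
  spec <- make_multimorbidity_preset(n = 40000, seed = 61)
  cohort <- sample_cohort(spec)
  # separation warnings from rare diseases in small strata are expected
  res <- suppressWarnings(stratified_networks(cohort, gamma = 0.25))
  expect_setequal(names(res$strata),
                  c("F/65-75", "M/65-75", "F/76+", "M/76+"))
  for (s in res$strata) {
    expect_false(s$flagged)
    expect_lte(s$density, 1)
    expect_equal(s$density, graph_density(s$structure))
    # strata use the 12 disease nodes only
    expect_false(any(c("sex", "age_band") %in% s$structure$nodes))
  }
  expect_equal(sum(vapply(res$strata, `[[`, integer(1), "n")),
               nrow(cohort))
  expect_length(res$comparisons, 6L)

  # a stratum with a constant disease column is flagged, not fatal
  tiny <- as.data.frame(cohort)[1:400, ]
  tiny$SEN[tiny$sex == 1 & tiny$age_band == 1] <- 0L
  warns <- capture_warnings(res2 <- stratified_networks(as_binary_cohort(tiny)))
  expect_true(any(grepl("flagged", warns)))
  flagged <- vapply(res2$strata, `[[`, logical(1), "flagged")
  expect_true(any(flagged))
})
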