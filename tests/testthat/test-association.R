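test_that("two_by_two counts partition the cohort", {
  toy <- data.frame(x = c(1, 1, 0, 0), y = c(1, 0, 1, 0))
  t1 <- two_by_two(toy, "x", "y")
  expect_equal(unlist(t1[c("a", "b", "c", "d")], use.names = FALSE),
               rep(1L, 4))
  # constant column: a single row of the table holds everyone
  toy2 <- data.frame(x = c(1, 1, 1), y = c(0, 0, 0))
  t2 <- two_by_two(toy2, "x", "y")
  expect_equal(t2$b, 3)
  expect_equal(t2$a + t2$c + t2$d, 0)
  # independent counting oracle on sampled data
  cohort <- sample_cohort(simulation_spec(chain_params(3), n = 500,
                                          seed = 5))
  tt <- two_by_two(cohort, "X1", "X3")
  oracle <- table(factor(cohort$X1, 0:1), factor(cohort$X3, 0:1))
  expect_equal(tt$a, oracle["1", "1"])
  expect_equal(tt$b, oracle["1", "0"])
  expect_equal(tt$c, oracle["0", "1"])
  expect_equal(tt$d, oracle["0", "0"])
  expect_error(two_by_two(data.frame(x = c(1, 2), y = c(0, 1)), "x", "y"),
               "not 0/1")
})

test_that("marginal odds ratios follow the closed form with Wald inference", {
  mk <- function(a, b, c, d) {
    structure(list(a = a, b = b, c = c, d = d, pair = c("x", "y")),
              class = "two_by_two")
  }
  r1 <- marginal_or(mk(10, 10, 10, 10))
  expect_equal(r1$or, 1)
  expect_equal(r1$p, 1)
  expect_equal(marginal_or(mk(20, 10, 10, 20))$or, 4)
  # Haldane-Anscombe correction on a zero cell, by hand arithmetic
  r3 <- marginal_or(mk(5, 0, 3, 7), continuity = TRUE)
  expect_equal(r3$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(marginal_or(mk(5, 0, 3, 7)), "zero cell")
  expect_match(tryCatch(marginal_or(mk(5, 0, 3, 7)),
                        error = conditionMessage), "x, y")
  # CI covers the point estimate
  r4 <- marginal_or(mk(20, 10, 10, 20))
  expect_true(r4$ci_low < r4$or && r4$or < r4$ci_high)
})

test_that("the marginal screen computes one test per variable pair", {
  set.seed(1)
  cohort <- as.data.frame(matrix(rbinom(200 * 2, 1, 0.5), 200, 2,
                                 dimnames = list(NULL, c("A", "B"))))
  m2 <- marginal_or_matrix(cohort, continuity = TRUE)
  expect_equal(m2$n_tests, 1L)
  expect_equal(m2$p_holm["A", "B"], m2$p["A", "B"]) # m = 1: unchanged
  # all-positive interaction truth: every marginal OR exceeds 1 at large n
  p <- 4
  inter <- matrix(log(2), p, p)
  diag(inter) <- 0
  pars <- ising_params(paste0("V", 1:p), rep(-1.5, p), inter)
  cohort <- sample_cohort(simulation_spec(pars, n = 20000, seed = 8))
  mm <- marginal_or_matrix(cohort)
  expect_true(all(mm$or[upper.tri(mm$or)] > 1))
  # truth check via enumeration: the true collapsed ORs exceed 1 too
  joint <- enumerate_joint(pars)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_gt(morbnet:::marginal_or_from_joint(joint, i, j), 1)
    }
  }
})

test_that("marginal OR converges to 1 for disconnected pairs", {
  # two separate components: (V1, V2) and (V3, V4); no path joins V1, V3
  inter <- matrix(0, 4, 4)
  inter[1, 2] <- inter[2, 1] <- log(3)
  inter[3, 4] <- inter[4, 3] <- log(3)
  pars <- ising_params(paste0("V", 1:4), rep(-1, 4), inter)
  cohort <- sample_cohort(simulation_spec(pars, n = 100000, seed = 13))
  r <- marginal_or(two_by_two(cohort, "V1", "V3"))
  expect_lt(abs(r$log_or), 3 * r$se)
})

test_that("holm adjustment reproduces the step-down formula", {
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(sample(2:40, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))               # never rejects more
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone step-down
  }
})

test_that("conditional strata enumerate every configuration and sum to the margin", {
  # X3 constant at 0: only the all-zero stratum is populated
  toy <- data.frame(x = c(1, 0, 1, 0), y = c(1, 1, 0, 0),
                    z = c(0, 0, 0, 0))
  cs <- conditional_strata_tables(toy, "x", "y")
  expect_equal(nrow(cs$tables), 2L)
  expect_equal(sum(cs$tables[1, ]), 4L)
  expect_equal(sum(cs$tables[2, ]), 0L)
  expect_true(cs$degenerate[2])
  # partition identity on sampled data
  cohort <- sample_cohort(simulation_spec(chain_params(5), n = 400,
                                          seed = 21))
  cs <- conditional_strata_tables(cohort, "X2", "X4")
  expect_equal(nrow(cs$tables), 2^3)
  marg <- two_by_two(cohort, "X2", "X4")
  expect_equal(colSums(cs$tables),
               c(a = marg$a, b = marg$b, c = marg$c, d = marg$d))
  expect_error(conditional_strata_tables(toy[, 1:2], "x", "y"), "p >= 3")
})

test_that("yules q transforms odds ratios as documented", {
  expect_equal(yules_q(1), 0)
  expect_equal(yules_q(3), 0.5)
  expect_equal(yules_q(1 / 3), -0.5)
  expect_equal(yules_q(Inf), 1)
  expect_error(yules_q(0), "positive")
  expect_error(yules_q(-2), "positive")
  # antisymmetry and monotonicity on a grid
  or <- c(0.2, 0.5, 1, 2, 5)
  expect_equal(yules_q(or), -yules_q(1 / or))
  expect_true(all(diff(yules_q(or)) > 0))
})
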