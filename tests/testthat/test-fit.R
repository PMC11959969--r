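test_that("the MLE on the empty graph is the independence closed form", {
  set.seed(4)
  df <- as.data.frame(matrix(rbinom(500 * 3, 1, 0.3), 500, 3,
                             dimnames = list(NULL, c("A", "B", "C"))))
  g <- graph_structure(c("A", "B", "C"))
  fit <- fit_ising_mle(df, g)
  expect_equal(unname(fit$main_effects), qlogis(colMeans(df)),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_true(all(fit$interactions == 0))
})

test_that("the joint MLE agrees with an IPF log-linear oracle on p = 4", {
  pars <- chain_params(4, lam = log(2.5), main = -0.7)
  cohort <- sample_cohort(simulation_spec(pars, n = 4000, seed = 17))
  g <- pars$structure # chain 1-2-3-4
  fit <- fit_ising_mle(cohort, g)

  # oracle: IPF for the hierarchical log-linear model with the same
  # pairwise generators, via stats::loglin on the 2^4 table
  x <- as.data.frame(cohort)
  tab <- table(factor(x$X1, 0:1), factor(x$X2, 0:1),
               factor(x$X3, 0:1), factor(x$X4, 0:1))
  ipf <- loglin(tab, margin = list(c(1, 2), c(2, 3), c(3, 4)),
                fit = TRUE, print = FALSE, eps = 1e-10, iter = 100)
  pfit <- ipf$fit / sum(ipf$fit)
  # translate the fitted positive joint into Ising parameters by
  # log-probability contrasts against the all-zero state
  pr <- function(v) pfit[v[1] + 1, v[2] + 1, v[3] + 1, v[4] + 1]
  base <- pr(c(0, 0, 0, 0))
  e <- diag(4)
  main_oracle <- vapply(1:4, function(i) log(pr(e[i, ]) / base), numeric(1))
  lam_oracle <- function(i, j) {
    log(pr(e[i, ] + e[j, ]) * base / (pr(e[i, ]) * pr(e[j, ])))
  }
  expect_equal(unname(fit$main_effects), main_oracle, tolerance = 1e-4)
  for (k in 1:3) {
    expect_equal(fit$interactions[k, k + 1], lam_oracle(k, k + 1),
                 tolerance = 1e-4)
  }
  # moment matching: fitted expected margins equal observed within 1e-6
  joint <- enumerate_joint(fit)
  mom <- morbnet:::joint_pair_moments(joint)
  obs1 <- colMeans(x)
  expect_lt(max(abs(diag(mom) - obs1)), 1e-6)
  for (k in 1:3) {
    expect_lt(abs(mom[k, k + 1] - mean(x[[k]] * x[[k + 1]])), 1e-6)
  }
  expect_lt(attr(fit, "gradient_norm"), 1e-6)
})

test_that("the structured fit is nested below the saturated pairwise fit", {
  pars <- chain_params(4, lam = log(2), main = -0.6)
  cohort <- sample_cohort(simulation_spec(pars, n = 2000, seed = 23))
  fit_chain <- fit_ising_mle(cohort, pars$structure)
  sat_adj <- matrix(TRUE, 4, 4); diag(sat_adj) <- FALSE
  g_sat <- graph_structure(pars$labels, adjacency = sat_adj)
  fit_sat <- fit_ising_mle(cohort, g_sat)
  expect_lte(attr(fit_chain, "loglik"), attr(fit_sat, "loglik") + 1e-8)
  expect_equal(attr(fit_chain, "loglik"),
               ising_loglik(fit_chain, cohort), tolerance = 1e-6)
})

test_that("full-likelihood and pseudo-likelihood estimates agree at large n", {
  pars <- chain_params(6, lam = log(2), main = -1)
  cohort <- sample_cohort(simulation_spec(pars, n = 50000, seed = 29))
  fit <- fit_ising_mle(cohort, pars$structure)
  # maximum pseudo-likelihood oracle: optimize the sum of full-conditional
  # log-likelihoods over the same free parameters
  x <- as.matrix(as.data.frame(cohort))
  ek <- pars$structure$edges
  p <- ncol(x)
  unpack <- function(theta) {
    lam <- matrix(0, p, p, dimnames = dimnames(pars$interactions))
    for (r in seq_len(nrow(ek))) {
      lam[ek[r, 1], ek[r, 2]] <- lam[ek[r, 2], ek[r, 1]] <- theta[p + r]
    }
    list(main = theta[1:p], lam = lam)
  }
  npll <- function(theta) {
    par <- unpack(theta)
    eta <- sweep(x %*% par$lam, 2, par$main, "+")
    -sum(x * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, p + nrow(ek)), npll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  ple <- unpack(opt$par)
  expect_lt(max(abs(ple$main - fit$main_effects)), 0.05)
  expect_lt(max(abs(ple$lam - fit$interactions)), 0.05)
})

test_that("conditional OR matrix renders edges and blanks as in the model", {
  labels <- c("A", "B", "C")
  inter <- matrix(0, 3, 3, dimnames = list(labels, labels))
  inter["A", "B"] <- inter["B", "A"] <- log(1.3)
  pars <- ising_params(labels, rep(-1, 3), inter)
  cm <- conditional_or_matrix(pars)
  expect_equal(cm$or["A", "B"], 1.3)
  expect_equal(cm$q["A", "B"], 0.3 / 2.3)
  expect_true(is.na(cm$or["A", "C"]))          # non-edge: absent
  expect_true(is.na(cm$or["A", "A"]))          # diagonal undefined
  expect_equal(cm$or, t(cm$or))
})

test_that("edge Wald tests use the observed information", {
  pars <- chain_params(4, lam = log(2), main = -0.8)
  cohort <- sample_cohort(simulation_spec(pars, n = 2000, seed = 37))
  fit <- fit_ising_mle(cohort, pars$structure)
  ew <- edge_wald(fit)
  expect_equal(nrow(ew), 3L)
  expect_equal(ew$z, ew$lambda / ew$se)
  # a zero estimate gives z = 0, p = 1
  labels <- c("A", "B")
  inter <- matrix(0, 2, 2, dimnames = list(labels, labels))
  g2 <- graph_structure(labels, edges = cbind("A", "B"))
  pz <- ising_params(labels, c(0, 0), inter, structure = g2,
                     se = list(main_effects = c(A = 0.1, B = 0.1),
                               interactions = matrix(0.2, 2, 2,
                                 dimnames = list(labels, labels))))
  ewz <- edge_wald(pz)
  expect_equal(ewz$z, 0)
  expect_equal(ewz$p, 1)

  # nonparametric bootstrap oracle on a p = 4 toy: SEs agree within 5%
  boot <- matrix(NA_real_, 200, 3)
  x <- as.data.frame(cohort)
  set.seed(99)
  for (b in 1:200) {
    xb <- x[sample.int(nrow(x), replace = TRUE), ]
    fb <- fit_ising_mle(xb, pars$structure)
    boot[b, ] <- fb$interactions[cbind(1:3, 2:4)]
  }
  se_boot <- apply(boot, 2, sd)
  expect_lt(max(abs(se_boot / ew$se - 1)), 0.05 + 0.05) # 5% + MC slack
})

test_that("SEs shrink when the cohort grows", {
  pars <- chain_params(4, lam = log(2), main = -0.8)
  small <- sample_cohort(simulation_spec(pars, n = 2000, seed = 41))
  big <- sample_cohort(simulation_spec(pars, n = 8000, seed = 41))
  se_small <- median(edge_wald(fit_ising_mle(small, pars$structure))$se)
  se_big <- median(edge_wald(fit_ising_mle(big, pars$structure))$se)
  expect_lt(se_big, se_small)
})

test_that("degenerate margins trigger the uniform shrinkage guard", {
  # A and B never co-occur although the structure has the edge
  df <- data.frame(A = c(1, 1, 0, 0, 0, 0), B = c(0, 0, 1, 1, 0, 0))
  g <- graph_structure(c("A", "B"), edges = cbind("A", "B"))
  expect_warning(fit <- fit_ising_mle(df, g), "shrunk toward")
  expect_true(all(is.finite(fit$interactions)))
})
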