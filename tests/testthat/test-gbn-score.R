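test_that("family marginal matches full 2-D quadrature for a parent-free node", {
  set.seed(41)
  y <- rnorm(5, 1)
  for (prior in list(gaussian_prior(),
                     gaussian_prior(nu = 2.5, a0 = 0.7, b0 = 1.9))) {
    got <- family_log_marginal(y, NULL, prior)
    expect_equal(got, quad2d_parentfree(y, prior), tolerance = 1e-6)
    expect_equal(got, quad_family_marginal(y, NULL, prior), tolerance = 1e-6)
  }
  # single observation at the prior mean: prior predictive value
  expect_equal(family_log_marginal(0, NULL, gaussian_prior()),
               quad2d_parentfree(0, gaussian_prior()), tolerance = 1e-6)
})

test_that("family marginal matches quadrature with 1 to 3 parents", {
  set.seed(42)
  for (p in 1:3) {
    P <- matrix(rnorm(8 * p), 8, p)
    y <- drop(P %*% runif(p, -1, 1)) + rnorm(8, 0, 0.7)
    for (prior in list(gaussian_prior(),
                       gaussian_prior(nu = 1.6, a0 = 1.4, b0 = 0.8))) {
      got <- family_log_marginal(y, P, prior)
      expect_equal(got, quad_family_marginal(y, P, prior), tolerance = 1e-6)
    }
  }
  expect_error(family_log_marginal(c(1, NA), NULL), "non-finite")
})

test_that("duplicating the data strictly decreases the log marginal", {
  set.seed(43)
  y <- rnorm(6)
  P <- matrix(rnorm(6), 6, 1)
  expect_lt(family_log_marginal(c(y, y), rbind(P, P)),
            family_log_marginal(y, P))
  expect_lt(family_log_marginal(rep(y, 2), NULL),
            family_log_marginal(y, NULL))
})

test_that("network score decomposes over families and flags missing nodes", {
  set.seed(44)
  X <- matrix(rnorm(4 * 40), 4, 40,
              dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:40)))
  g0 <- dag(rownames(X))
  s0 <- network_score(g0, X)
  expect_equal(s0$total, sum(s0$family_scores), tolerance = 1e-12)
  # empty dag total = sum of univariate marginals
  uni <- sum(vapply(rownames(X), function(v)
    family_log_marginal(scale(X[v, ], scale = FALSE), NULL), numeric(1)))
  expect_equal(s0$total, uni, tolerance = 1e-9)
  # adding one edge changes exactly one family term
  g1 <- dag(rownames(X), data.frame(from = "A", to = "B"))
  s1 <- network_score(g1, X)
  expect_equal(s1$family_scores[c("A", "C", "D")],
               s0$family_scores[c("A", "C", "D")], tolerance = 1e-12)
  expect_equal(s1$total - s0$total,
               s1$family_scores[["B"]] - s0$family_scores[["B"]],
               tolerance = 1e-12)
  expect_error(network_score(dag(c("A", "Z")), X), "Z")
})

test_that("Markov-equivalent structures receive identical scores", {
  set.seed(45)
  X <- matrix(rnorm(3 * 30), 3, 30,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:30)))
  # X->Y vs Y->X on two nodes
  ab <- network_score(dag(c("A", "B"), data.frame(from = "A", to = "B")),
                      X[1:2, ])$total
  ba <- network_score(dag(c("A", "B"), data.frame(from = "B", to = "A")),
                      X[1:2, ])$total
  expect_equal(ab, ba, tolerance = 1e-10)
  # all 25 dags on three nodes, grouped by the skeleton/v-structure oracle
  amats <- enumerate_all_dags(rownames(X))
  expect_length(amats, 25)
  scores <- vapply(amats, function(a)
    network_score(apoptonet:::dag_from_amat(a), X)$total, numeric(1))
  keys <- vapply(amats, cpdag_key, character(1))
  for (k in unique(keys)) {
    s <- scores[keys == k]
    expect_lt(max(s) - min(s), 1e-8 * max(1, abs(mean(s))))
  }
  # sanity: non-equivalent structures do differ
  expect_gt(length(unique(round(scores, 6))), 1)
})

test_that("posterior odds are zero within classes and favor true structure", {
  g <- dag(c("X", "Y", "Z"), data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  sem <- sem_params(g, beta = data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                                         coef = c(2, 2)),
                    sigma2 = setNames(c(1, 0.25, 0.25), c("X", "Y", "Z")))
  X <- simulate_sem(sem, 500, seed = 46)
  expect_equal(log_posterior_odds(g, g, X), 0)
  grev <- dag(c("X", "Y", "Z"),
              data.frame(from = c("Y", "Z"), to = c("X", "Y")))
  expect_lt(abs(log_posterior_odds(g, grev, X)), 1e-8)
  expect_gt(log_posterior_odds(g, dag(c("X", "Y", "Z")), X), 0)
  expect_error(log_posterior_odds(g, dag(c("A", "B", "C")), X),
               "different node sets")
})

test_that("conjugate local fit is consistent and matches its sampler", {
  # no data: posterior equals the prior
  pr <- gaussian_prior(a0 = 3, b0 = 2)
  fit0 <- fit_local_params(numeric(0), NULL, pr)
  expect_equal(fit0$alpha, pr$mu0)
  expect_equal(fit0$an, pr$a0)
  expect_equal(fit0$bn, pr$b0)
  expect_equal(fit0$sigma2, pr$b0 / (pr$a0 - 1))
  # near-noiseless linear child: coefficient and variance recovered
  set.seed(47)
  x <- rnorm(2000)
  y <- 2 * x + rnorm(2000, 0, 0.01)
  fit <- fit_local_params(y, matrix(x), gaussian_prior())
  expect_equal(unname(fit$beta), 2, tolerance = 0.01)
  expect_lt(fit$sigma2, 0.01)
  # sampling mode agrees with the closed form within Monte-Carlo error
  set.seed(48)
  P <- matrix(rnorm(40), 20, 2)
  yy <- drop(P %*% c(1, -1)) + rnorm(20, 0, 0.5)
  cf <- fit_local_params(yy, P, gaussian_prior(), n_draws = 20000, seed = 9)
  mc_mean <- colMeans(cf$draws)
  mc_se <- apply(cf$draws, 2, sd) / sqrt(nrow(cf$draws))
  expect_lt(abs(mc_mean[["intercept"]] - cf$alpha), 3 * mc_se[["intercept"]])
  expect_lt(abs(mc_mean[["b1"]] - cf$beta[1]), 3 * mc_se[["b1"]])
  expect_lt(abs(mc_mean[["b2"]] - cf$beta[2]), 3 * mc_se[["b2"]])
  expect_lt(abs(mc_mean[["sigma2"]] - cf$sigma2), 4 * mc_se[["sigma2"]])
})

test_that("the score cannot be built from an improper prior", {
  expect_error(gaussian_prior(nu = 0), "positive")
  expect_error(gaussian_prior(a0 = -1), "positive")
})
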