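#' Conjugate prior for the conditional linear Gaussian score
#'
#' The local model of every node is a linear regression on its parents with
#' Gaussian noise; the prior is conjugate (Gaussian for the coefficients
#' given the noise variance, Inverse-Gamma for the variance) and identical in
#' form for every node (parameter modularity). Internally the per-family
#' priors are tied together as the conditionals of one joint
#' Normal-Wishart prior over all genes (parametric matrix `2 * b0 * I`,
#' degrees of freedom chosen so a parent-free family has an exact
#' `Inv-Gamma(a0, b0)` variance prior). This construction makes the network
#' score *score-equivalent*: Markov-equivalent structures receive identical
#' marginal likelihoods.
#'
#' For a node with `p` parents the implied regression-form prior (exact when
#' `mu0 = 0`) is: variance `sigma2 ~ Inv-Gamma(a0 + p/2, b0)`; coefficients
#' `beta | sigma2 ~ N(0, sigma2 / (2 * b0) * I)`; intercept
#' `alpha | sigma2 ~ N(mu0, sigma2 / nu)`.
#'
#' @param mu0 prior mean of each gene (0 with per-gene centered data).
#' @param nu equivalent sample size (prior precision scale) for the mean.
#' @param a0 noise-variance prior shape.
#' @param b0 noise-variance prior scale.
#' @return An object of class `gaussian_prior`.
#' @export
gaussian_prior <- function(mu0 = 0, nu = 1, a0 = 1, b0 = 1) {
  if (nu <= 0 || a0 <= 0 || b0 <= 0) stop("nu, a0, b0 must be positive")
  structure(list(mu0 = mu0, nu = nu, a0 = a0, b0 = b0),
            class = "gaussian_prior")
}

# log multivariate gamma function
lmvgamma <- function(a, p) {
  if (p == 0) return(0)
  (p * (p - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# log marginal likelihood of an n x l data block under the joint
# Normal-Wishart prior restricted to l variables; logdetR = log |R_Y| with
# R_Y = 2*b0*I + S + (nu*n/(nu+n)) (xbar - mu0)(xbar - mu0)^T.
logm_const <- function(l, n, prior) {
  if (l == 0) return(0)
  al <- 2 * prior$a0 + l - 1
  -(n * l / 2) * log(pi) + (l / 2) * log(prior$nu / (prior$nu + n)) +
    lmvgamma((al + n) / 2, l) - lmvgamma(al / 2, l) +
    (al / 2) * l * log(2 * prior$b0)
}

subset_R <- function(Y, prior) {
  n <- nrow(Y)
  xbar <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, xbar))
  diag(2 * prior$b0, ncol(Y)) + S +
    (prior$nu * n / (prior$nu + n)) * tcrossprod(xbar - prior$mu0)
}

#' Per-family log marginal likelihood
#'
#' The closed-form marginal likelihood of one node's data given its parents'
#' data, with the conjugate parameters integrated out — the per-family
#' factor of the network score. Computed as the ratio of the joint marginals
#' of the `(parents, child)` and `(parents)` data blocks under the
#' Normal-Wishart construction of [gaussian_prior()]; for `mu0 = 0` it is
#' identical to the Normal-Inverse-Gamma linear-regression marginal of the
#' child on `(1, parents)`.
#'
#' @param child numeric vector, the node's data (length n >= 1).
#' @param parents numeric matrix of parent data, n x p, or `NULL` for a
#'   parent-free node.
#' @param prior a [gaussian_prior()].
#' @return A finite scalar log marginal likelihood.
#' @export
family_log_marginal <- function(child, parents = NULL,
                                prior = gaussian_prior()) {
  if (!all(is.finite(child))) stop("non-finite values in child data")
  n <- length(child)
  if (n < 1) stop("need at least one observation")
  if (is.null(parents)) parents <- matrix(0, n, 0)
  parents <- as.matrix(parents)
  if (!all(is.finite(parents))) stop("non-finite values in parent data")
  if (nrow(parents) != n) stop("child and parents have different lengths")
  p <- ncol(parents)
  Y1 <- cbind(parents, child)
  l1 <- logm_const(p + 1, n, prior) -
    ((2 * prior$a0 + p + n) / 2) * as.numeric(determinant(subset_R(Y1, prior))$modulus)
  if (p == 0) return(l1)
  l0 <- logm_const(p, n, prior) -
    ((2 * prior$a0 + p - 1 + n) / 2) *
    as.numeric(determinant(subset_R(parents, prior))$modulus)
  l1 - l0
}

# Fast cached family scorer over a fixed dataset.
#
# data: genes x samples matrix. Returns a closure score(i, pa) taking the
# child row index and an integer vector of parent row indices; family scores
# are cached by (node, parent set), which together with score
# decomposability makes hill climbing tractable.
make_family_scorer <- function(data, prior = gaussian_prior(),
                               center = TRUE) {
  X <- as.matrix(data)
  n <- ncol(X)
  xbar <- rowMeans(X)
  Xc <- X - xbar
  if (center) xbar <- rep(0, nrow(X))
  Rfull <- diag(2 * prior$b0, nrow(X)) + tcrossprod(Xc) +
    (prior$nu * n / (prior$nu + n)) * tcrossprod(xbar - prior$mu0)
  dimnames(Rfull) <- dimnames(tcrossprod(Xc))
  consts <- vapply(0:nrow(X), logm_const, numeric(1), n = n, prior = prior)
  # dconst[p + 1] = A(p + 1) - A(p)
  dconst <- diff(consts)
  a0 <- prior$a0
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(i, pa) {
    key <- paste(i, paste(pa, collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- length(pa)
    if (p == 0) {
      val <- dconst[1] - ((2 * a0 + n) / 2) * log(Rfull[i, i])
    } else {
      Rpa <- Rfull[pa, pa, drop = FALSE]
      U <- chol(Rpa)
      logdet0 <- 2 * sum(log(diag(U)))
      z <- backsolve(U, Rfull[pa, i], transpose = TRUE)
      schur <- Rfull[i, i] - sum(z * z)
      val <- dconst[p + 1] - ((2 * a0 + p + n) / 2) * log(schur) -
        0.5 * logdet0
    }
    cache[[key]] <- val
    val
  }
}

#' Score a network structure against data
#'
#' The log marginal likelihood of the data given the structure,
#' `score(G : D) = log p(D | G)`, computed as the sum of per-family
#' marginals ([family_log_marginal()]). The score is locally decomposable:
#' changing the parents of one node changes only that family's term. Data
#' are centered per gene before scoring by default (scale preserved).
#'
#' @param dag a [dag()] whose nodes are rows of `data`.
#' @param data genes x samples numeric matrix with at least 3 samples.
#' @param prior a [gaussian_prior()].
#' @param center center each gene before scoring.
#' @return An object of class `scored_network`: list with `dag`,
#'   `family_scores` (named per node), and `total`.
#' @export
network_score <- function(dag, data, prior = gaussian_prior(),
                          center = TRUE) {
  stopifnot(inherits(dag, "dag"))
  missing <- setdiff(dag$nodes, rownames(data))
  if (length(missing))
    stop("nodes missing from the data: ", paste(missing, collapse = ", "))
  if (ncol(data) < 3) stop("need at least 3 samples")
  X <- data[dag$nodes, , drop = FALSE]
  scorer <- make_family_scorer(X, prior, center)
  idx <- seq_along(dag$nodes)
  fam <- vapply(idx, function(i) scorer(i, which(dag$amat[, i])), numeric(1))
  names(fam) <- dag$nodes
  structure(list(dag = dag, family_scores = fam, total = sum(fam)),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("scored network: %d nodes, %d edges, log score %.4f\n",
              length(x$dag$nodes), dag_n_edges(x$dag), x$total))
  invisible(x)
}

#' Log posterior odds of two structures
#'
#' With a uniform structure prior the log posterior odds of two structures
#' equal the log Bayes factor, i.e. the difference of their network scores.
#'
#' @param g1,g2 [dag()]s over the same node set.
#' @inheritParams network_score
#' @return Scalar `score(g1) - score(g2)`.
#' @export
log_posterior_odds <- function(g1, g2, data, prior = gaussian_prior(),
                               center = TRUE) {
  if (!setequal(g1$nodes, g2$nodes))
    stop("structures are defined over different node sets")
  network_score(g1, data, prior, center)$total -
    network_score(g2, data, prior, center)$total
}

#' Conjugate posterior of one node's local model
#'
#' Exact Normal-Inverse-Gamma update of the regression of a node on its
#' parents under the regression-form prior of [gaussian_prior()] (exact for
#' `mu0 = 0`, the default): posterior means of the intercept and
#' coefficients, the posterior expectation of the noise variance, and the
#' family's log marginal likelihood. An optional sampling mode draws from
#' the exact posterior (useful to emulate MCMC-style parameter estimates and
#' to cross-check the closed form).
#'
#' @inheritParams family_log_marginal
#' @param n_draws if positive, also return `n_draws` posterior draws of
#'   `(alpha, beta, sigma2)`.
#' @param seed seed for the sampling mode.
#' @return An object of class `local_gaussian_model`: list with `alpha`,
#'   `beta`, `sigma2` (posterior expectation, `NA` if the posterior shape is
#'   <= 1), `log_marginal`, the posterior hyperparameters, and optionally
#'   `draws` (matrix with columns `alpha`, coefficients, `sigma2`).
#' @export
fit_local_params <- function(child, parents = NULL,
                             prior = gaussian_prior(), n_draws = 0,
                             seed = 1) {
  n <- length(child)
  if (is.null(parents)) parents <- matrix(0, n, 0)
  parents <- as.matrix(parents)
  p <- ncol(parents)
  X <- cbind(intercept = rep(1, n), parents)
  if (is.null(colnames(parents)) && p > 0)
    colnames(X) <- c("intercept", paste0("b", seq_len(p)))
  V0inv <- diag(c(prior$nu, rep(2 * prior$b0, p)), p + 1)
  m0 <- c(prior$mu0, rep(0, p))
  a <- prior$a0 + p / 2
  b <- prior$b0
  Vninv <- V0inv + crossprod(X)
  mn <- drop(solve(Vninv, V0inv %*% m0 + crossprod(X, child)))
  an <- a + n / 2
  bn <- b + 0.5 * (sum(child^2) + sum(m0 * (V0inv %*% m0)) -
                     sum(mn * (Vninv %*% mn)))
  out <- list(alpha = unname(mn[1]), beta = mn[-1],
              sigma2 = if (an > 1) bn / (an - 1) else NA_real_,
              mn = mn, Vninv = Vninv, an = an, bn = bn,
              log_marginal = if (n > 0)
                family_log_marginal(child, if (p) parents else NULL, prior)
              else NA_real_)
  if (n_draws > 0) {
    local_seed(seed)
    s2 <- 1 / rgamma(n_draws, shape = an, rate = bn)
    L <- chol(solve(Vninv)) # upper-triangular factor of posterior covariance
    th <- matrix(rnorm(n_draws * (p + 1)), n_draws) %*% L
    th <- sweep(th * sqrt(s2), 2, mn, "+")
    out$draws <- cbind(th, sigma2 = s2)
    colnames(out$draws) <- c(colnames(X), "sigma2")
  }
  class(out) <- "local_gaussian_model"
  out
}
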