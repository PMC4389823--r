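# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) wherever they check one.

# All labeled digraphs on the given nodes, filtered for acyclicity, as a
# list of logical adjacency matrices. Feasible for n <= 4 (2^12 digraphs).
enumerate_all_dags <- function(nodes) {
  n <- length(nodes)
  cells <- which(diag(n) == 0)
  np <- length(cells)
  out <- list()
  for (code in 0:(2^np - 1)) {
    amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    bits <- bitwAnd(code %/% 2^(seq_len(np) - 1), 1) == 1
    amat[cells[bits]] <- TRUE
    if (oracle_acyclic(amat)) out[[length(out) + 1]] <- amat
  }
  out
}

# Acyclicity by brute-force path powers (independent of the package's
# Kahn-based check): a digraph is acyclic iff no power of the adjacency
# matrix has a positive diagonal.
oracle_acyclic <- function(amat) {
  n <- nrow(amat)
  M <- (amat) * 1
  P <- M
  for (k in seq_len(n)) {
    if (any(diag(P) > 0)) return(FALSE)
    P <- (P %*% M > 0) * 1
  }
  TRUE
}

# Markov equivalence class key: skeleton plus v-structures.
cpdag_key <- function(amat) {
  nodes <- rownames(amat)
  und <- amat | t(amat)
  idx <- which(und & upper.tri(und), arr.ind = TRUE)
  skel <- sort(paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "~"))
  vs <- character(0)
  for (k in seq_len(nrow(amat))) {
    pa <- which(amat[, k])
    if (length(pa) >= 2) {
      for (a in seq_along(pa)) for (b in seq_along(pa)) {
        if (a < b && !und[pa[a], pa[b]])
          vs <- c(vs, paste(nodes[pa[a]], nodes[pa[b]], nodes[k], sep = "|"))
      }
    }
  }
  paste(c(skel, "||", sort(vs)), collapse = ";")
}

# Closed-form Gaussian integral over (intercept, coefficients) combined with
# adaptive 1-D quadrature over the noise variance. Uses the regression-form
# prior of gaussian_prior() with mu0 = 0: sigma2 ~ IG(a0 + p/2, b0),
# theta | sigma2 ~ N(0, sigma2 * V0) with V0^-1 = diag(nu, 2*b0, ...).
quad_family_marginal <- function(y, P, prior) {
  n <- length(y)
  p <- if (is.null(P)) 0 else ncol(P)
  X <- cbind(rep(1, n), P)
  V0 <- diag(1 / c(prior$nu, rep(2 * prior$b0, p)), p + 1)
  C <- diag(n) + X %*% V0 %*% t(X)
  cc <- chol(C)
  z <- backsolve(cc, y, transpose = TRUE)
  q <- sum(z^2)
  ld <- 2 * sum(log(diag(cc)))
  a <- prior$a0 + p / 2
  b <- prior$b0
  logdens <- function(s2) {
    -(n / 2) * log(2 * pi * s2) - ld / 2 - q / (2 * s2) +
      a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2
  }
  off <- logdens((q + 2 * b) / (n + 2 * a + 2)) # mode-ish scaling offset
  val <- stats::integrate(function(s2) exp(logdens(s2) - off), 0, Inf,
                          rel.tol = 1e-11, abs.tol = 0)$value
  log(val) + off
}

# Fully numerical 2-D quadrature over (intercept, variance) for a
# parent-free family; independent of the closed-form route above.
quad2d_parentfree <- function(y, prior) {
  n <- length(y)
  a <- prior$a0; b <- prior$b0; nu <- prior$nu; mu0 <- prior$mu0
  inner <- function(s2) {
    f <- function(al) {
      vapply(al, function(m) {
        exp(sum(stats::dnorm(y, m, sqrt(s2), log = TRUE)) +
              stats::dnorm(m, mu0, sqrt(s2 / nu), log = TRUE))
      }, numeric(1))
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value *
      exp(a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2)
  }
  log(stats::integrate(Vectorize(inner), 0, Inf, rel.tol = 1e-10)$value)
}

# BFS all-shortest-paths oracle on an undirected edge list (data frame
# from/to). Returns list(dist, paths); paths is a list of node vectors.
bfs_all_shortest_paths <- function(edges, a, b) {
  adj <- list()
  adde <- function(u, v) adj[[u]] <<- unique(c(adj[[u]], v))
  for (r in seq_len(nrow(edges))) {
    adde(edges$from[r], edges$to[r])
    adde(edges$to[r], edges$from[r])
  }
  if (is.null(adj[[a]]) || is.null(adj[[b]]))
    return(list(dist = Inf, paths = list()))
  dist <- setNames(Inf, a)
  dist[a] <- 0
  preds <- list()
  frontier <- a
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        dv <- if (v %in% names(dist)) dist[[v]] else Inf
        if (dv == dist[[u]] + 1) {
          preds[[v]] <- unique(c(preds[[v]], u))
        } else if (dv > dist[[u]] + 1) {
          dist[v] <- dist[[u]] + 1
          preds[[v]] <- u
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (!(b %in% names(dist)) || !is.finite(dist[[b]]))
    return(list(dist = Inf, paths = list()))
  walk <- function(v) {
    if (v == a) return(list(a))
    unlist(lapply(preds[[v]], function(u) {
      lapply(walk(u), function(p) c(p, v))
    }), recursive = FALSE)
  }
  list(dist = dist[[b]], paths = walk(b))
}

# Random planted-path validation fixture: a reference network over a gene
# pool plus predicted edges at assorted distances (direct, 2-hop, absent).
make_validation_fixture <- function(seed) {
  set.seed(seed)
  genes <- sprintf("G%02d", 1:12)
  pairs <- t(combn(genes, 2))
  pick <- pairs[sample(nrow(pairs), 14), , drop = FALSE]
  ref <- data.frame(from = pick[, 1], to = pick[, 2],
                    stringsAsFactors = FALSE)
  preds <- pairs[sample(nrow(pairs), 6), , drop = FALSE]
  pred <- data.frame(from = c(preds[, 1], "G99"),
                     to = c(preds[, 2], genes[1]),
                     stringsAsFactors = FALSE)
  list(reference = ref, predicted = pred)
}

# Build a fake bootstrap ensemble from explicit dags (for confidence tests).
fake_ensemble <- function(dags, scores = NULL) {
  if (is.null(scores)) scores <- seq_along(dags)
  networks <- lapply(seq_along(dags), function(i) {
    structure(list(dag = dags[[i]], family_scores = NULL,
                   total = scores[i]), class = "scored_network")
  })
  structure(list(networks = networks, scores = scores, B = length(dags),
                 n_samples = NA_integer_, seed = 0,
                 retained = seq_along(dags)), class = "bn_ensemble")
}
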