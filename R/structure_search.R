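# ---- arbitrary-precision non-negative integers (base 1e7, little-endian) ----
# Needed because the number of labeled DAGs exceeds 2^53 already at 12 nodes.

big_norm <- function(d) {
  base <- 1e7
  carry <- 0
  i <- 1
  while (i <= length(d) || carry > 0) {
    if (i > length(d)) d[i] <- 0
    v <- d[i] + carry
    d[i] <- v %% base
    carry <- v %/% base
    i <- i + 1
  }
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% 1e7)
    x <- x %/% 1e7
    if (x == 0) break
  }
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

big_cmp <- function(a, b) { # -1, 0, 1
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) if (a[i] != b[i]) return(sign(a[i] - b[i]))
  0
}

big_sub <- function(a, b) { # requires a >= b
  stopifnot(big_cmp(a, b) >= 0)
  b <- c(b, rep(0, length(a) - length(b)))
  d <- a - b
  for (i in seq_along(d)) {
    if (d[i] < 0) { d[i] <- d[i] + 1e7; d[i + 1] <- d[i + 1] - 1 }
  }
  big_norm(d)
}

big_mul_small <- function(a, m) { # m < 9e8 keeps digit products exact
  stopifnot(m >= 0, m < 9e8)
  if (m == 0) return(0)
  big_norm(a * m)
}

big_mul <- function(a, b) {
  out <- 0
  for (i in seq_along(b)) {
    term <- big_mul_small(a, b[i])
    if (i > 1) term <- c(rep(0, i - 1), term)
    out <- big_add(out, term)
  }
  out
}

big_pow2 <- function(e) {
  out <- 1
  while (e >= 20) { out <- big_mul_small(out, 2^20); e <- e - 20 }
  if (e > 0) out <- big_mul_small(out, 2^e)
  out
}

big_to_string <- function(d) {
  top <- sprintf("%.0f", d[length(d)])
  rest <- if (length(d) > 1) paste0(sprintf("%07.0f", rev(d[-length(d)])), collapse = "") else ""
  paste0(top, rest)
}

#' Count labeled directed acyclic graphs
#'
#' The exact number of labeled DAGs on `n` nodes via Robinson's recurrence
#' `a(n) = sum_{k=1..n} (-1)^(k+1) C(n,k) 2^(k(n-k)) a(n-k)`, `a(0) = 1`,
#' computed in exact arbitrary-precision integer arithmetic (the count
#' exceeds double precision beyond 11 nodes; at 13 nodes it is about
#' 1.87e31, which is why exhaustive structure search is hopeless and greedy
#' search is used instead).
#'
#' @param n number of nodes (>= 0).
#' @return The exact count as a decimal character string (convert with
#'   `as.numeric()` for approximate use).
#' @export
count_dags <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stop("n must be a single integer >= 0")
  a <- vector("list", n + 1)
  a[[1]] <- big_from_num(1)
  if (n >= 1) for (m in 1:n) {
    pos <- 0; neg <- 0
    for (k in 1:m) {
      term <- big_mul(a[[m - k + 1]],
                      big_mul(big_from_num(choose(m, k)), big_pow2(k * (m - k))))
      if (k %% 2 == 1) pos <- big_add(pos, term) else neg <- big_add(neg, term)
    }
    a[[m + 1]] <- big_sub(pos, neg)
  }
  big_to_string(a[[n + 1]])
}

# ---- single-edge moves -------------------------------------------------------

# Reachability matrix: reach[i, j] TRUE iff a directed path i ~> j exists.
reachability <- function(amat) {
  reach <- amat
  repeat {
    nxt <- reach | ((reach %*% amat) > 0)
    if (identical(nxt, reach)) return(reach)
    reach <- nxt
  }
}

# Path i ~> j avoiding the direct edge i -> j (for reversal legality).
has_other_path <- function(amat, i, j) {
  amat[i, j] <- FALSE
  stack <- which(amat[i, ])
  seen <- logical(nrow(amat))
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == j) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(amat[v, ] & !seen))
  }
  FALSE
}

# Deterministic lexicographic candidate list: (type, from label, to label)
# with type order add < delete < reverse. Returns a data frame of moves.
enumerate_moves <- function(amat, labels) {
  ordn <- order(labels)
  reach <- reachability(amat)
  adds <- dels <- revs <- list()
  for (i in ordn) for (j in ordn) {
    if (i == j) next
    if (!amat[i, j] && !amat[j, i] && !reach[j, i])
      adds[[length(adds) + 1]] <- c(i, j)
    if (amat[i, j]) {
      dels[[length(dels) + 1]] <- c(i, j)
      if (!has_other_path(amat, i, j))
        revs[[length(revs) + 1]] <- c(i, j)
    }
  }
  mk <- function(lst, type) if (length(lst))
    data.frame(type = type, from = vapply(lst, `[`, 0L, 1),
               to = vapply(lst, `[`, 0L, 2)) else NULL
  rbind(mk(adds, "add"), mk(dels, "delete"), mk(revs, "reverse"))
}

#' All single-move neighbors of a dag
#'
#' Every dag reachable by one edge addition, deletion, or reversal that
#' preserves acyclicity — the move set of the hill-climbing search.
#'
#' @param g a [dag()].
#' @return List of `dag` objects (no duplicates).
#' @export
neighbor_moves <- function(g) {
  stopifnot(inherits(g, "dag"))
  mv <- enumerate_moves(g$amat, g$nodes)
  if (is.null(mv)) return(list())
  lapply(seq_len(nrow(mv)), function(r) {
    amat <- g$amat
    i <- mv$from[r]; j <- mv$to[r]
    switch(mv$type[r],
           add = { amat[i, j] <- TRUE },
           delete = { amat[i, j] <- FALSE },
           reverse = { amat[i, j] <- FALSE; amat[j, i] <- TRUE })
    dag_from_amat(amat)
  })
}

#' Random restart initializer
#'
#' A random dag over the given nodes (random topological order, edge
#' probability 0.2), used for restarts after the first (which always starts
#' from the empty graph).
#'
#' @param nodes character vector of node labels.
#' @param seed integer seed.
#' @return A `dag`.
#' @export
random_dag_init <- function(nodes, seed) sample_random_dag(nodes, 0.2, seed)

#' Greedy structure search: hill climbing with random restarts
#'
#' From each start (first: the empty graph; later restarts: random), the
#' search repeatedly moves to the best-scoring single-edge neighbor while
#' the score strictly improves, and stops at a local optimum. Family scores
#' are cached by (node, parent set) — by score decomposability, a move's
#' gain is the changed families' score difference — so equal families are
#' never rescored. Ties among equally good moves break lexicographically by
#' (move type, source, target), making the search deterministic for a fixed
#' seed.
#'
#' @param data genes x samples numeric matrix.
#' @param prior a [gaussian_prior()].
#' @param n_restarts number of climbs (>= 1).
#' @param seed master seed (drives only the random restart structures).
#' @param nodes nodes to learn over; default all rows of `data`.
#' @param center center genes before scoring.
#' @param max_steps safety cap on accepted moves per climb.
#' @return An object of class `search_trace`: `best` (a
#'   [network_score()]-style `scored_network`), `restarts` (per-restart
#'   list with `start_score`, `score_path`, `final`), and
#'   `structures_evaluated` (every candidate structure scored, including
#'   rejected ones).
#' @export
hill_climb <- function(data, prior = gaussian_prior(), n_restarts = 2,
                       seed = 1, nodes = rownames(data), center = TRUE,
                       max_steps = 1000) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  X <- data[nodes, , drop = FALSE]
  d <- length(nodes)
  scorer <- make_family_scorer(X, prior, center)
  evaluated <- 0L
  restarts <- vector("list", n_restarts)
  best <- NULL

  for (r in seq_len(n_restarts)) {
    g <- if (r == 1) dag(nodes) else
      random_dag_init(nodes, substream_seed(seed, paste0("restart:", r)))
    amat <- g$amat
    fam <- vapply(seq_len(d), function(i) scorer(i, which(amat[, i])),
                  numeric(1))
    total <- sum(fam)
    path <- total
    moves <- list()
    for (step in seq_len(max_steps)) {
      mv <- enumerate_moves(amat, nodes)
      if (is.null(mv)) break
      best_delta <- 0; best_mv <- NULL
      for (k in seq_len(nrow(mv))) {
        i <- mv$from[k]; j <- mv$to[k]
        pa_j <- which(amat[, j])
        delta <- switch(
          mv$type[k],
          add = scorer(j, sort(c(pa_j, i))) - fam[j],
          delete = scorer(j, setdiff(pa_j, i)) - fam[j],
          reverse = (scorer(j, setdiff(pa_j, i)) - fam[j]) +
            (scorer(i, sort(c(which(amat[, i]), j))) - fam[i]))
        evaluated <- evaluated + 1L
        if (delta > best_delta + 1e-9) { best_delta <- delta; best_mv <- k }
      }
      if (is.null(best_mv)) break
      i <- mv$from[best_mv]; j <- mv$to[best_mv]
      type <- mv$type[best_mv]
      if (type == "add") {
        amat[i, j] <- TRUE
        fam[j] <- scorer(j, which(amat[, j]))
      } else if (type == "delete") {
        amat[i, j] <- FALSE
        fam[j] <- scorer(j, which(amat[, j]))
      } else {
        amat[i, j] <- FALSE; amat[j, i] <- TRUE
        fam[j] <- scorer(j, which(amat[, j]))
        fam[i] <- scorer(i, which(amat[, i]))
      }
      total <- sum(fam)
      path <- c(path, total)
      moves[[length(moves) + 1]] <- list(type = type, from = nodes[i],
                                         to = nodes[j], delta = best_delta)
    }
    final <- structure(list(dag = dag_from_amat(amat),
                            family_scores = setNames(fam, nodes),
                            total = total), class = "scored_network")
    restarts[[r]] <- list(start_score = path[1], score_path = path,
                          moves = moves, final = final)
    if (is.null(best) || total > best$total) best <- final
  }
  structure(list(best = best, restarts = restarts,
                 structures_evaluated = evaluated, n_restarts = n_restarts,
                 seed = seed), class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("hill climb: %d restart(s), %d structures evaluated, best score %.4f (%d edges)\n",
              x$n_restarts, x$structures_evaluated, x$best$total,
              dag_n_edges(x$best$dag)))
  invisible(x)
}
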