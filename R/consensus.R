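#' Bootstrap structure learning
#'
#' Learns one best-scoring network per bootstrap replicate: each replicate
#' resamples the samples (columns) with replacement and runs
#' [hill_climb()] with its own deterministic substream seed. The ensemble is
#' the raw material of bootstrap model averaging.
#'
#' @param data genes x samples numeric matrix (>= 3 samples).
#' @param prior a [gaussian_prior()].
#' @param B number of bootstrap replicates (>= 1).
#' @param seed master seed; replicate r draws from substreams
#'   `resample:r` and `search:r`.
#' @param n_restarts restarts per replicate's hill climb.
#' @param nodes nodes to learn over; default all rows.
#' @param center center genes before scoring.
#' @return An object of class `bn_ensemble`: list with `networks` (list of
#'   `scored_network`), `scores`, `B`, `n_samples`, `seed`, `retained`
#'   (indices of replicates currently retained; initially all).
#' @export
bootstrap_learn <- function(data, prior = gaussian_prior(), B = 200,
                            seed = 1, n_restarts = 2,
                            nodes = rownames(data), center = TRUE) {
  if (B < 1) stop("B must be >= 1")
  if (ncol(data) < 3) stop("need at least 3 samples")
  X <- data[nodes, , drop = FALSE]
  n <- ncol(X)
  networks <- vector("list", B)
  for (r in seq_len(B)) {
    local_seed(substream_seed(seed, paste0("resample:", r)))
    idx <- sample.int(n, n, replace = TRUE)
    tr <- hill_climb(X[, idx, drop = FALSE], prior,
                     n_restarts = n_restarts,
                     seed = substream_seed(seed, paste0("search:", r)),
                     nodes = nodes, center = center)
    networks[[r]] <- tr$best
  }
  structure(list(networks = networks,
                 scores = vapply(networks, `[[`, numeric(1), "total"),
                 B = B, n_samples = n, seed = seed,
                 retained = seq_len(B)),
            class = "bn_ensemble")
}

#' @export
print.bn_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap ensemble: %d replicates (%d retained), score range [%.2f, %.2f]\n",
              x$B, length(x$retained), min(x$scores[x$retained]),
              max(x$scores[x$retained])))
  invisible(x)
}

#' Retain replicates inside the central score interval
#'
#' Robustness filter of the model-averaging stage: keeps replicates whose
#' total score lies within the central `level` empirical interval of the
#' ensemble scores, i.e. between the `(1-level)/2` and `1-(1-level)/2`
#' quantiles, inclusive.
#'
#' @param ensemble a [bootstrap_learn()] ensemble.
#' @param level central interval mass in `(0, 1]` (default 0.95).
#' @return The ensemble with its `retained` index set updated.
#' @export
filter_score_interval <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "bn_ensemble"))
  if (level <= 0 || level > 1) stop("level must lie in (0, 1]")
  s <- ensemble$scores
  q <- quantile(s, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  ensemble$retained <- which(s >= q[1] & s <= q[2])
  ensemble
}

#' Bootstrap edge confidence
#'
#' The confidence of a directed edge is its frequency among the retained
#' replicates; the skeleton confidence of an unordered pair is the frequency
#' of the pair being connected in either direction (always at least the
#' larger directed confidence — bootstrap direction flips within a Markov
#' equivalence class are expected).
#'
#' @param ensemble a (possibly filtered) `bn_ensemble`.
#' @return An object of class `edge_confidence`: list with `edges` (data
#'   frame: `from`, `to`, `directed_conf`, `skeleton_conf`; rows for every
#'   edge observed in any retained replicate), `directed` and `skeleton`
#'   confidence matrices, and `n_retained`.
#' @export
edge_confidence <- function(ensemble) {
  stopifnot(inherits(ensemble, "bn_ensemble"))
  nets <- ensemble$networks[ensemble$retained]
  if (!length(nets)) stop("no retained replicates")
  nodes <- nets[[1]]$dag$nodes
  acc <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  skel <- acc
  for (nw in nets) {
    a <- nw$dag$amat
    acc <- acc + a
    skel <- skel + (a | t(a))
  }
  m <- length(nets)
  dirconf <- acc / m
  skelconf <- skel / m
  idx <- which(dirconf > 0, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      directed_conf = dirconf[idx],
                      skeleton_conf = skelconf[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, directed = dirconf, skeleton = skelconf,
                 n_retained = m), class = "edge_confidence")
}

#' Thresholded consensus network
#'
#' Keeps directed edges whose bootstrap confidence exceeds the threshold
#' (strictly, by default). When both directions of a pair pass, the
#' higher-confidence direction is kept (exact ties break lexicographically
#' and are flagged). The result is reported as a directed interaction graph
#' and is not forced to be acyclic: averaging DAGs does not guarantee a DAG.
#'
#' @param conf an [edge_confidence()] table.
#' @param threshold confidence threshold in `[0, 1]` (default 0.75).
#' @param strict if `TRUE` (default) require confidence `> threshold`,
#'   otherwise `>=`.
#' @param level `"directed"` (default) thresholds the directed edge
#'   frequency; `"skeleton"` thresholds the direction-ignoring pair
#'   frequency, which is robust to bootstrap direction flips within a
#'   Markov equivalence class (each retained pair is then oriented by its
#'   majority direction).
#' @return An object of class `consensus_network`: list with `nodes`,
#'   `edges` (data frame: `from`, `to`, `confidence`, `skeleton_conf`,
#'   `tie_flag`), `threshold`, `level`.
#' @export
build_consensus <- function(conf, threshold = 0.75, strict = TRUE,
                            level = c("directed", "skeleton")) {
  stopifnot(inherits(conf, "edge_confidence"))
  level <- match.arg(level)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  e <- conf$edges
  crit <- if (level == "directed") e$directed_conf else e$skeleton_conf
  pass <- if (strict) crit > threshold else crit >= threshold
  e <- e[pass, , drop = FALSE]
  keep <- rep(TRUE, nrow(e))
  tie <- rep(FALSE, nrow(e))
  if (nrow(e) > 1) {
    key <- apply(cbind(pmin(e$from, e$to), pmax(e$from, e$to)), 1, paste,
                 collapse = "~")
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      cf <- e$directed_conf[rows]
      if (cf[1] == cf[2]) {
        # lexicographic tie-break on (from, to), flagged
        pickrow <- rows[order(e$from[rows], e$to[rows])][1]
        tie[pickrow] <- TRUE
      } else pickrow <- rows[which.max(cf)]
      keep[setdiff(rows, pickrow)] <- FALSE
    }
  }
  e <- e[keep, , drop = FALSE]
  out <- data.frame(from = e$from, to = e$to,
                    confidence = if (level == "directed") e$directed_conf
                    else e$skeleton_conf,
                    directed_conf = e$directed_conf,
                    skeleton_conf = e$skeleton_conf, tie_flag = tie[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(nodes = rownames(conf$directed), edges = out,
                 threshold = threshold, level = level),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus network: %d nodes, %d edges with confidence %s %.2f\n",
              length(x$nodes), nrow(x$edges), ">", x$threshold))
  if (nrow(x$edges))
    print(utils::head(x$edges[, c("from", "to", "confidence")], 20))
  invisible(x)
}

#' Skeleton precision and recall against a true structure
#'
#' Compares the undirected skeleton of a predicted network with the skeleton
#' of a ground-truth dag: recall is the fraction of true pairs recovered,
#' precision the fraction of predicted pairs that are true.
#'
#' @param predicted a `consensus_network`, `dag`, or edge data frame.
#' @param truth a `dag` (for example the generating SEM structure).
#' @return List with `recall`, `precision`, `n_true`, `n_pred`, `n_hit`.
#' @export
skeleton_metrics <- function(predicted, truth) {
  stopifnot(inherits(truth, "dag"))
  pe <- if (inherits(predicted, "consensus_network")) predicted$edges
  else if (inherits(predicted, "dag")) dag_edges(predicted)
  else predicted
  pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  te <- dag_edges(truth)
  tp <- unique(pair(te$from, te$to))
  pp <- if (nrow(pe)) unique(pair(pe$from, pe$to)) else character(0)
  hit <- length(intersect(tp, pp))
  list(recall = if (length(tp)) hit / length(tp) else NA_real_,
       precision = if (length(pp)) hit / length(pp) else NA_real_,
       n_true = length(tp), n_pred = length(pp), n_hit = hit)
}
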