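#' Construct a labeled directed acyclic graph
#'
#' A `dag` is the structure object of a Gaussian Bayesian network: a set of
#' node labels plus a directed edge set stored as a logical adjacency matrix
#' (`amat[i, j]` is `TRUE` for an edge i -> j). Acyclicity is checked on
#' construction and after every mutation.
#'
#' @param nodes character vector of unique node labels.
#' @param edges optional two-column matrix or data frame of edges
#'   (from, to), given as node labels.
#' @return An object of class `dag`.
#' @examples
#' g <- dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
#' dag_parents(g, "B")
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  n <- length(nodes)
  amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    miss <- setdiff(unique(c(edges)), nodes)
    if (length(miss)) stop("edge endpoints not in node set: ",
                           paste(miss, collapse = ", "))
    amat[edges] <- TRUE
  }
  if (any(diag(amat))) stop("self-loops are not allowed")
  g <- structure(list(nodes = nodes, amat = amat), class = "dag")
  if (!is_acyclic(amat)) stop("edge set contains a directed cycle")
  g
}

#' @export
print.dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("dag: %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e)) {
    shown <- utils::head(e, 20L)
    cat(paste0("  ", shown$from, " -> ", shown$to, collapse = "\n"), "\n")
    if (nrow(e) > 20L) cat("  ...\n")
  }
  invisible(x)
}

# Kahn's algorithm on a logical adjacency matrix.
is_acyclic <- function(amat) {
  indeg <- colSums(amat)
  active <- rep(TRUE, nrow(amat))
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    active[src] <- FALSE
    if (length(src) == 1L) {
      indeg <- indeg - amat[src, ]
    } else {
      indeg <- indeg - colSums(amat[src, , drop = FALSE])
    }
  }
  !any(active)
}

#' Topological order of a dag
#'
#' @param g a `dag`.
#' @return Character vector of node labels so that every edge points from an
#'   earlier to a later position.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "dag"))
  amat <- g$amat
  n <- length(g$nodes)
  order <- character(0)
  indeg <- colSums(amat)
  active <- rep(TRUE, n)
  for (step in seq_len(n)) {
    src <- which(active & indeg == 0)
    if (!length(src)) stop("internal error: dag contains a cycle")
    pick <- src[1L]
    order <- c(order, g$nodes[pick])
    active[pick] <- FALSE
    indeg <- indeg - amat[pick, ]
    indeg[!active] <- 1L # keep processed nodes out of the source set
  }
  order
}

#' Parents of a node
#'
#' @param g a `dag`.
#' @param node a node label.
#' @return Character vector of parent labels (possibly empty).
#' @export
dag_parents <- function(g, node) {
  stopifnot(inherits(g, "dag"))
  if (!node %in% g$nodes) stop("unknown node: ", node)
  g$nodes[g$amat[, node]]
}

#' Edge list of a dag
#'
#' @param g a `dag`.
#' @return Data frame with columns `from`, `to`.
#' @export
dag_edges <- function(g) {
  stopifnot(inherits(g, "dag"))
  idx <- which(g$amat, arr.ind = TRUE)
  data.frame(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Number of edges in a dag
#' @param g a `dag`.
#' @return Integer edge count.
#' @export
dag_n_edges <- function(g) sum(g$amat)

# Internal constructor from a validated adjacency matrix (no re-check).
dag_from_amat <- function(amat) {
  structure(list(nodes = rownames(amat), amat = amat), class = "dag")
}

#' Sample a random dag
#'
#' Draws a random topological order (a permutation of the nodes) and then
#' includes each forward edge independently with probability `edge_prob`.
#' Acyclicity holds by construction. Used both to build ground-truth
#' structures for simulation and as the random restart initializer of the
#' structure search.
#'
#' @param n_nodes number of nodes (>= 1); alternatively a character vector of
#'   node labels.
#' @param edge_prob probability in `[0, 1]` for each forward pair.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A `dag`. Nodes are labeled `g01`, `g02`, ... when `n_nodes` is a
#'   count.
#' @export
sample_random_dag <- function(n_nodes, edge_prob, seed) {
  if (is.character(n_nodes)) {
    nodes <- n_nodes
  } else {
    if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 1)
      stop("n_nodes must be a single integer >= 1")
    nodes <- sprintf("g%02d", seq_len(n_nodes))
  }
  if (!is.numeric(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("edge_prob must lie in [0, 1]")
  n <- length(nodes)
  local_seed(seed)
  ord <- sample(nodes)
  amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (n > 1 && edge_prob > 0) {
    for (i in seq_len(n - 1L)) {
      take <- stats::runif(n - i) < edge_prob
      amat[ord[i], ord[seq(i + 1L, n)][take]] <- TRUE
    }
  }
  dag_from_amat(amat)
}

#' Sample a random dag with a fixed number of edges
#'
#' Draws a random topological order and then a uniform sample of `n_edges`
#' forward pairs. Convenient for planting ground-truth structures of a stated
#' size (for example the 13-node, 15-edge apoptosis module used throughout
#' the package's examples).
#'
#' @param n_nodes node count or character vector of labels.
#' @param n_edges number of edges; at most `choose(n, 2)`.
#' @param seed integer seed.
#' @return A `dag`.
#' @export
sample_dag_n_edges <- function(n_nodes, n_edges, seed) {
  nodes <- if (is.character(n_nodes)) n_nodes else sprintf("g%02d", seq_len(n_nodes))
  n <- length(nodes)
  if (n_edges > choose(n, 2)) stop("too many edges requested")
  local_seed(seed)
  ord <- sample(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  take <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
  amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  amat[cbind(ord[take[, 1]], ord[take[, 2]])] <- TRUE
  dag_from_amat(amat)
}

#' Write / read a dag as an edge-list TSV
#'
#' The file holds one `from<TAB>to` line per edge; isolated nodes are listed
#' in a `# nodes:` header comment so the full node set round-trips.
#'
#' @param g a `dag`.
#' @param path file path.
#' @return `write_dag` returns `path` invisibly; `read_dag` returns a `dag`.
#' @export
write_dag <- function(g, path) {
  stopifnot(inherits(g, "dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(g$nodes, collapse = ",")), con)
  e <- dag_edges(g)
  if (nrow(e)) writeLines(paste(e$from, e$to, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# nodes:", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  edges <- NULL
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stop("malformed edge at line ", bad[1])
    edges <- do.call(rbind, lapply(parts, function(p) p[1:2]))
  }
  nodes <- if (length(hdr)) {
    strsplit(sub("^# nodes: *", "", hdr[1]), ",", fixed = TRUE)[[1]]
  } else unique(c(edges))
  dag(nodes, edges)
}
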