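#' Load a curated reference interaction network
#'
#' Reads a two-column edge-list TSV or a three-column SIF (interaction type
#' in the middle column) into an undirected simple graph. Symbols are
#' matched case-insensitively (uppercased); self-loops and duplicate
#' interactions are dropped with a message reporting the counts.
#'
#' @param path file path, or a data frame with columns `from`, `to`.
#' @return An object of class `reference_network`: list with `nodes`,
#'   `edges` (data frame `from`, `to`, each pair once, endpoints sorted),
#'   `graph` (an undirected [igraph::graph_from_data_frame()] graph),
#'   `n_duplicates`, `n_self_loops`.
#' @export
load_reference <- function(path) {
  if (is.data.frame(path)) {
    edges <- data.frame(from = toupper(path$from), to = toupper(path$to),
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stop("malformed interaction line ", bad[1], " in ", path)
    edges <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) >= 3L) c(p[1], p[3]) else c(p[1], p[2]) # SIF or 2-col
    }))
    edges <- data.frame(from = toupper(edges[, 1]), to = toupper(edges[, 2]),
                        stringsAsFactors = FALSE)
    if (nrow(edges) && edges$from[1] == "FROM" && edges$to[1] == "TO")
      edges <- edges[-1, , drop = FALSE] # header line of an edge TSV
  }
  self <- edges$from == edges$to
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  dup <- duplicated(paste(a, b, sep = "~"))
  n_dup <- sum(dup)
  edges <- data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
  if (n_self || n_dup)
    message("reference network: dropped ", n_self, " self-loop(s) and ",
            n_dup, " duplicate interaction(s)")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(nodes = igraph::V(g)$name, edges = edges, graph = g,
                 n_duplicates = n_dup, n_self_loops = n_self),
            class = "reference_network")
}

#' Classify predicted edges against the reference network
#'
#' Each predicted edge (direction ignored) is `direct` when the pair is a
#' reference interaction; otherwise `indirect` when a path exists between
#' the two genes via intermediates, recording *all* shortest paths; and
#' `unsupported` when no path exists or an endpoint is absent from the
#' reference.
#'
#' @param predicted a `consensus_network` or a data frame with columns
#'   `from`, `to`.
#' @param reference a [load_reference()] network.
#' @return An object of class `validation_report`: list with `edges` (data
#'   frame: `from`, `to`, `status`, `path_length`), `paths` (per-edge list
#'   of shortest paths as node vectors), and `counts`
#'   (`direct`, `indirect`, `unsupported`, `total`).
#' @export
classify_edges <- function(predicted, reference) {
  stopifnot(inherits(reference, "reference_network"))
  pe <- if (inherits(predicted, "consensus_network")) predicted$edges else predicted
  from <- toupper(pe$from); to <- toupper(pe$to)
  ref_pairs <- paste(reference$edges$from, reference$edges$to, sep = "~")
  status <- character(length(from))
  plen <- rep(NA_integer_, length(from))
  paths <- vector("list", length(from))
  for (k in seq_along(from)) {
    a <- from[k]; b <- to[k]
    pair <- paste(min(a, b), max(a, b), sep = "~")
    if (!(a %in% reference$nodes) || !(b %in% reference$nodes)) {
      status[k] <- "unsupported"
    } else if (pair %in% ref_pairs) {
      status[k] <- "direct"
      plen[k] <- 1L
      paths[[k]] <- list(c(a, b))
    } else {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(reference$graph, a, b)$vpaths)
      if (!length(sp)) {
        status[k] <- "unsupported"
      } else {
        status[k] <- "indirect"
        paths[[k]] <- lapply(sp, function(v) igraph::V(reference$graph)$name[v])
        plen[k] <- length(paths[[k]][[1]]) - 1L
      }
    }
  }
  edges <- data.frame(from = from, to = to, status = status,
                      path_length = plen, stringsAsFactors = FALSE)
  structure(list(edges = edges, paths = paths,
                 counts = list(direct = sum(status == "direct"),
                               indirect = sum(status == "indirect"),
                               unsupported = sum(status == "unsupported"),
                               total = length(status))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "validation: %d predicted edges — %d direct, %d indirect, %d unsupported\n",
    total, direct, indirect, unsupported)))
  invisible(x)
}

#' Shortest-path evidence subnetwork
#'
#' The subgraph of the reference network that carries the validation
#' evidence: every direct-validated predicted edge, plus every node and edge
#' lying on any recorded shortest path of an indirect-validated edge.
#'
#' @param report a [classify_edges()] report.
#' @param reference the [load_reference()] network the report was computed
#'   against.
#' @return A list with `nodes` and `edges` (data frame `from`, `to`,
#'   endpoints sorted), a sub-network of `reference`.
#' @export
evidence_subnetwork <- function(report, reference) {
  stopifnot(inherits(report, "validation_report"),
            inherits(reference, "reference_network"))
  nodes <- character(0)
  edges <- character(0)
  for (k in seq_len(nrow(report$edges))) {
    if (report$edges$status[k] == "unsupported") next
    for (pth in report$paths[[k]]) {
      nodes <- c(nodes, pth)
      if (length(pth) > 1) {
        a <- pth[-length(pth)]; b <- pth[-1]
        edges <- c(edges, paste(pmin(a, b), pmax(a, b), sep = "~"))
      }
    }
  }
  edges <- sort(unique(edges))
  parts <- strsplit(edges, "~", fixed = TRUE)
  list(nodes = sort(unique(nodes)),
       edges = data.frame(from = vapply(parts, `[`, "", 1),
                          to = vapply(parts, `[`, "", 2),
                          stringsAsFactors = FALSE))
}
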