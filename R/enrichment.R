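#' Hypergeometric over-representation test
#'
#' Tests whether a gene set is over-represented in a selected signature,
#' against the hypergeometric null on the gene universe: with `N` universe
#' genes of which `K` belong to the set, and a signature of size `n`
#' containing `k` set members, the p-value is the upper tail
#' `P(X >= k)` (including the observed count). Gene symbols are matched
#' case-insensitively; the set is restricted to the universe before testing.
#'
#' @param signature character vector of selected genes (must lie in the
#'   universe).
#' @param set character vector, the gene set.
#' @param universe character vector of all tested genes.
#' @return List with `k`, `n`, `K`, `N`, `overlap` (the overlapping
#'   symbols), and `p`.
#' @export
hypergeom_overlap_test <- function(signature, set, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(signature)) stop("empty signature")
  universe <- unique(toupper(universe))
  signature <- unique(toupper(signature))
  set <- intersect(unique(toupper(set)), universe)
  if (!all(signature %in% universe))
    stop("signature genes missing from the universe: ",
         paste(head(setdiff(signature, universe), 5), collapse = ", "))
  k <- length(intersect(signature, set))
  N <- length(universe); K <- length(set); n <- length(signature)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N,
       overlap = intersect(signature, set), p = p)
}

#' Absolute-mean permutation enrichment test
#'
#' Enrichment-score variant for perturbation signatures in which set members
#' may move in either direction: the enrichment score is the mean absolute
#' differential-expression statistic of the set members,
#' `ES = mean(|score|)`, and its significance is assessed against
#' `n_perm` random draws of equally many gene names from the scored universe
#' (permutation of gene labels). The p-value uses the add-one convention
#' `p = (1 + #(null ES >= ES)) / (1 + n_perm)` and so is never zero.
#'
#' @param scores named numeric vector: differential-expression statistic per
#'   gene (the pipeline feeds the moderated t by default).
#' @param set character vector of set genes; all must be scored.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return List with `es`, `p`, `n_perm`, `set_size`, and the permutation
#'   null vector `null_es`.
#' @export
abs_mean_enrichment <- function(scores, set, n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  names(scores) <- toupper(names(scores))
  set <- unique(toupper(set))
  missing <- setdiff(set, names(scores))
  if (length(missing))
    stop("set genes missing from the score vector: ",
         paste(missing, collapse = ", "))
  a <- abs(scores)
  es <- mean(a[set])
  m <- length(set); M <- length(a)
  local_seed(seed)
  null_es <- vapply(seq_len(n_perm),
                    function(i) mean(a[sample.int(M, m)]), numeric(1))
  p <- (1 + sum(null_es >= es)) / (1 + n_perm)
  list(es = es, p = p, n_perm = n_perm, set_size = m, null_es = null_es)
}

#' Pro/anti apoptosis partition bookkeeping
#'
#' Counts the pro-apoptotic set, the anti-apoptotic set, their overlap
#' (genes annotated in both directions), and the union total.
#'
#' @param pro,anti character vectors of gene symbols.
#' @return List with `n_pro`, `n_anti`, `n_both`, `n_total`.
#' @export
partition_counts <- function(pro, anti) {
  pro <- unique(toupper(pro)); anti <- unique(toupper(anti))
  n_both <- length(intersect(pro, anti))
  list(n_pro = length(pro), n_anti = length(anti), n_both = n_both,
       n_total = length(pro) + length(anti) - n_both)
}
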