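#' Linear-Gaussian structural equation model parameters
#'
#' A `sem_params` object holds the generating model of a gene module: each
#' node is normally distributed with mean linear in its parents,
#' `g_i ~ N(sum_j beta_{j,i} * parent_j + alpha_i, sigma2_i)`. It is the
#' ground truth against which structure recovery is measured.
#'
#' @param dag a [dag()] over the module genes.
#' @param beta data frame with columns `from`, `to`, `coef`; every row must
#'   be an edge of `dag`.
#' @param alpha named numeric vector of intercepts (one per node; missing
#'   entries default to 0).
#' @param sigma2 named numeric vector of positive noise variances (missing
#'   entries default to 1).
#' @return An object of class `sem_params`.
#' @export
sem_params <- function(dag, beta = NULL, alpha = NULL, sigma2 = NULL) {
  stopifnot(inherits(dag, "dag"))
  nodes <- dag$nodes
  B <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (!is.null(beta) && nrow(beta) > 0) {
    for (r in seq_len(nrow(beta))) {
      f <- as.character(beta$from[r]); t <- as.character(beta$to[r])
      if (!isTRUE(dag$amat[f, t]))
        stop("beta given for non-edge ", f, " -> ", t)
      B[f, t] <- beta$coef[r]
    }
  }
  a <- setNames(rep(0, length(nodes)), nodes)
  if (!is.null(alpha)) a[names(alpha)] <- alpha
  s2 <- setNames(rep(1, length(nodes)), nodes)
  if (!is.null(sigma2)) s2[names(sigma2)] <- sigma2
  if (any(s2 <= 0)) stop("all noise variances must be positive")
  structure(list(dag = dag, B = B, alpha = a, sigma2 = s2),
            class = "sem_params")
}

#' Draw random SEM coefficients for a given structure
#'
#' Coefficient magnitudes are uniform on `beta_range` with random sign; this
#' is the default signal regime of the package's structure-recovery
#' experiments (`|beta|` in `[0.5, 1.5]`, unit noise variance).
#'
#' @param dag a [dag()].
#' @param beta_range length-2 numeric, magnitude range of coefficients.
#' @param sigma2 scalar noise variance applied to every node.
#' @param seed integer seed.
#' @return A `sem_params` object.
#' @export
random_sem_params <- function(dag, beta_range = c(0.5, 1.5), sigma2 = 1,
                              seed = 1) {
  e <- dag_edges(dag)
  local_seed(seed)
  coefs <- if (nrow(e)) {
    runif(nrow(e), beta_range[1], beta_range[2]) *
      sample(c(-1, 1), nrow(e), replace = TRUE)
  } else numeric(0)
  sem_params(dag, beta = cbind(e, coef = coefs),
             sigma2 = setNames(rep(sigma2, length(dag$nodes)), dag$nodes))
}

#' Simulate i.i.d. samples from a linear-Gaussian SEM
#'
#' Nodes are visited in topological order; each draws its value as the linear
#' combination of its parents plus Gaussian noise. Columns are independent
#' samples.
#'
#' @param sem a [sem_params()] object.
#' @param n_samples number of samples (columns), >= 1.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return Numeric matrix, genes x samples, rows in the dag's node order.
#' @export
simulate_sem <- function(sem, n_samples, seed) {
  stopifnot(inherits(sem, "sem_params"))
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("n_samples must be >= 1")
  n_samples <- as.integer(n_samples)
  nodes <- sem$dag$nodes
  ord <- topological_order(sem$dag)
  X <- matrix(NA_real_, length(nodes), n_samples,
              dimnames = list(nodes, paste0("S", seq_len(n_samples))))
  local_seed(seed)
  for (v in ord) {
    pa <- dag_parents(sem$dag, v)
    mu <- rep(sem$alpha[[v]], n_samples)
    if (length(pa))
      mu <- mu + drop(crossprod(X[pa, , drop = FALSE], sem$B[pa, v]))
    X[v, ] <- mu + rnorm(n_samples, 0, sqrt(sem$sigma2[[v]]))
  }
  if (anyNA(X)) stop("internal consistency error: cycle in SEM dag")
  X
}

#' Closed-form covariance implied by a SEM
#'
#' For `x = B^T x + e` with independent noise `e ~ N(0, diag(sigma2))`, the
#' implied covariance is `(I - B^T)^{-1} diag(sigma2) (I - B^T)^{-T}`. Serves
#' as the analytic oracle for [simulate_sem()].
#'
#' @param sem a [sem_params()] object.
#' @return Symmetric positive-definite matrix in the dag's node order.
#' @export
implied_covariance <- function(sem) {
  stopifnot(inherits(sem, "sem_params"))
  n <- length(sem$dag$nodes)
  A <- solve(diag(n) - t(sem$B))
  S <- A %*% diag(sem$sigma2, n) %*% t(A)
  dimnames(S) <- list(sem$dag$nodes, sem$dag$nodes)
  S
}

#' Generate a CMAP-like synthetic dataset with known ground truth
#'
#' Emulates a pooled drug-perturbation compendium at desk scale: a background
#' of null genes (i.i.d. Gaussian, no group effect), signature genes whose
#' perturbed-group mean is shifted by a per-gene effect `delta`, and a gene
#' module whose joint distribution follows a known linear-Gaussian SEM (the
#' structure-recovery target). Matching apoptosis gene sets (pro / anti, with
#' overlap) and a reference interaction network containing the SEM skeleton
#' plus decoy nodes and two-hop paths are returned alongside, so that every
#' downstream stage — differential expression, enrichment, network learning,
#' consensus, validation — can be exercised without any download.
#'
#' Defaults mirror the proportions of a pooled single-cell-line perturbation
#' compendium: 1,000 background genes, 178 shifted signature genes, a 13-gene
#' module, 100 control + 400 perturbed samples, effect magnitudes in
#' `[0.06, 0.32]` (log2 units, random sign) and residual noise SD 0.5.
#'
#' @param n_background number of null genes.
#' @param n_signature number of mean-shifted signature genes.
#' @param sem a [sem_params()] for the module; default: a 13-node, 15-edge
#'   random structure with `|beta|` in `[0.5, 1.5]`, unit noise.
#' @param n_control,n_perturbed samples per group.
#' @param delta_range length-2 numeric: magnitude range of the signature
#'   shifts (sign is random).
#' @param noise_sd residual SD of background and signature genes.
#' @param baseline baseline expression level added to every non-module gene.
#' @param sem_delta_range magnitude range of the perturbed-group mean shift
#'   applied to module genes, in units of each gene's implied marginal SD,
#'   so the module shows up in the differential-expression signature
#'   (within-group covariance is untouched); `NULL` disables it.
#' @param probes_per_gene 1 for one probe per gene; larger values emit
#'   `probes_per_gene` probe rows per gene (gene value plus probe noise) and
#'   a probe-to-gene map, to exercise probe collapsing.
#' @param apo_sig_frac fraction of non-module signature genes added to the
#'   apoptosis gene set.
#' @param apo_background number of null genes added to the apoptosis set.
#' @param n_decoys decoy nodes added to the reference network.
#' @param seed master integer seed; all internal draws use named substreams.
#' @return A list with elements `expr` (genes or probes x samples matrix),
#'   `design` (data frame: `sample`, `group`), `truth` (list: `sem`,
#'   `signature` data frame with per-gene `delta`, `null_genes`,
#'   `sem_deltas`), `gene_sets` (named list: `apoptosis_pro`,
#'   `apoptosis_anti`), `reference` (data frame edge list), and
#'   `probe2gene` (`NULL` unless `probes_per_gene > 1`).
#' @export
simulate_cmap_like <- function(n_background = 1000, n_signature = 178,
                               sem = NULL, n_control = 100, n_perturbed = 400,
                               delta_range = c(0.06, 0.32), noise_sd = 0.5,
                               baseline = 7, sem_delta_range = c(0.5, 0.8),
                               probes_per_gene = 1, apo_sig_frac = 0.2,
                               apo_background = 50, n_decoys = 10, seed = 1) {
  if (n_background < 1 || n_signature < 0 || n_control < 1 || n_perturbed < 1)
    stop("counts must be positive")
  if (is.null(sem)) {
    g <- sample_dag_n_edges(paste0("APO", sprintf("%02d", 1:13)), 15,
                            substream_seed(seed, "sem-structure"))
    sem <- random_sem_params(g, seed = substream_seed(seed, "sem-params"))
  }
  stopifnot(inherits(sem, "sem_params"))
  bg_genes <- sprintf("BG%04d", seq_len(n_background))
  sig_genes <- if (n_signature > 0) sprintf("SIG%03d", seq_len(n_signature)) else character(0)
  sem_genes <- sem$dag$nodes
  if (length(intersect(c(bg_genes, sig_genes), sem_genes)))
    stop("overlapping gene-id namespaces between SEM and generated genes")

  n <- n_control + n_perturbed
  samples <- sprintf("S%04d", seq_len(n))
  group <- rep(c("control", "perturbed"), c(n_control, n_perturbed))
  design <- data.frame(sample = samples, group = group,
                       stringsAsFactors = FALSE)
  perturbed <- group == "perturbed"

  local_seed(substream_seed(seed, "background"))
  bg <- matrix(rnorm(n_background * n, baseline, noise_sd), n_background, n,
               dimnames = list(bg_genes, samples))

  local_seed(substream_seed(seed, "signature"))
  delta <- if (n_signature > 0) {
    runif(n_signature, delta_range[1], delta_range[2]) *
      sample(c(-1, 1), n_signature, replace = TRUE)
  } else numeric(0)
  sig <- matrix(rnorm(n_signature * n, baseline, noise_sd),
                max(n_signature, 0), n, dimnames = list(sig_genes, samples))
  if (n_signature > 0) sig[, perturbed] <- sig[, perturbed] + delta

  mod <- simulate_sem(sem, n, substream_seed(seed, "sem-data"))
  colnames(mod) <- samples
  sem_deltas <- NULL
  if (!is.null(sem_delta_range)) {
    # module genes are heteroscedastic (noise plus parent propagation), so
    # their shifts are drawn in units of each gene's implied marginal SD
    local_seed(substream_seed(seed, "sem-shift"))
    sdg <- sqrt(diag(implied_covariance(sem)))
    sem_deltas <- setNames(
      runif(length(sem_genes), sem_delta_range[1], sem_delta_range[2]) *
        sample(c(-1, 1), length(sem_genes), replace = TRUE) * sdg[sem_genes],
      sem_genes)
    mod[, perturbed] <- mod[, perturbed] + sem_deltas
  }
  expr <- rbind(bg, sig, mod)

  # apoptosis gene sets: the module plus a slice of signature and background
  local_seed(substream_seed(seed, "gene-sets"))
  apo <- c(sem_genes,
           if (n_signature > 0) sample(sig_genes, round(apo_sig_frac * n_signature)),
           sample(bg_genes, min(apo_background, n_background)))
  side <- sample(c("pro", "anti"), length(apo), replace = TRUE)
  both <- sample(apo, max(1, round(0.06 * length(apo))))
  gene_sets <- list(apoptosis_pro = sort(unique(c(apo[side == "pro"], both))),
                    apoptosis_anti = sort(unique(c(apo[side == "anti"], both))))

  # reference network: true skeleton + decoys + planted two-hop paths between
  # non-adjacent module genes, so direct AND indirect validation cases exist
  local_seed(substream_seed(seed, "reference"))
  skel <- dag_edges(sem$dag)
  dec <- if (n_decoys > 0) sprintf("DEC%02d", seq_len(n_decoys)) else character(0)
  ref <- skel
  if (length(dec)) {
    adj <- sem$dag$amat | t(sem$dag$amat)
    nonadj <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    n_paths <- min(length(dec), nrow(nonadj))
    pick <- nonadj[sample(nrow(nonadj), n_paths), , drop = FALSE]
    for (k in seq_len(n_paths)) {
      u <- sem_genes[pick[k, 1]]; w <- sem_genes[pick[k, 2]]
      ref <- rbind(ref, data.frame(from = c(u, dec[k]), to = c(dec[k], w)))
    }
    if (length(dec) > 1) {
      extra <- t(utils::combn(dec, 2))[sample(choose(length(dec), 2),
                                              min(5, choose(length(dec), 2))), ,
                                       drop = FALSE]
      ref <- rbind(ref, data.frame(from = extra[, 1], to = extra[, 2]))
    }
  }

  probe2gene <- NULL
  if (probes_per_gene > 1) {
    genes <- rownames(expr)
    probe2gene <- data.frame(
      probe = paste0(rep(genes, each = probes_per_gene), "_p",
                     seq_len(probes_per_gene)),
      gene = rep(genes, each = probes_per_gene), stringsAsFactors = FALSE)
    local_seed(substream_seed(seed, "probes"))
    expr <- expr[probe2gene$gene, , drop = FALSE] +
      matrix(rnorm(nrow(probe2gene) * n, 0, 0.1), nrow(probe2gene), n)
    rownames(expr) <- probe2gene$probe
  }

  list(expr = expr, design = design,
       truth = list(sem = sem,
                    signature = data.frame(gene = sig_genes, delta = delta,
                                           stringsAsFactors = FALSE),
                    null_genes = bg_genes, sem_deltas = sem_deltas),
       gene_sets = gene_sets, reference = ref, probe2gene = probe2gene)
}
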