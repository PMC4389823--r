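#' Two-group linear model fit per gene
#'
#' Fits, for every row of the expression matrix, the pooled two-group linear
#' model (intercept plus a binary perturbation indicator): the coefficient is
#' `logFC = mean(perturbed) - mean(control)` and `s2` is the pooled residual
#' variance on `n - 2` degrees of freedom. All compounds are pooled into one
#' perturbed group ("complete pooling"); no per-compound terms are fitted.
#'
#' @param expr probes/genes x samples numeric matrix.
#' @param design data frame with columns `sample`, `group` (values
#'   `control` / `perturbed`) covering the columns of `expr`.
#' @return Data frame with columns `probe`, `logFC`, `s2`, `df`.
#' @export
fit_group_model <- function(expr, design) {
  if (!all(colnames(expr) %in% design$sample))
    stop("design does not cover all samples")
  grp <- design$group[match(colnames(expr), design$sample)]
  if (!all(grp %in% c("control", "perturbed")))
    stop("groups must be 'control' or 'perturbed'")
  nc <- sum(grp == "control"); np <- sum(grp == "perturbed")
  if (nc < 1 || np < 1) stop("invalid design: both groups must be non-empty")
  n <- nc + np
  if (n < 3) stop("zero residual degrees of freedom: need >= 3 samples")
  C <- expr[, grp == "control", drop = FALSE]
  P <- expr[, grp == "perturbed", drop = FALSE]
  mc <- rowMeans(C); mp <- rowMeans(P)
  rss <- rowSums((C - mc)^2) + rowSums((P - mp)^2)
  data.frame(probe = rownames(expr), logFC = mp - mc, s2 = rss / (n - 2),
             df = n - 2, row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_2` of
#' the hierarchical variance model `s2 ~ s0_2 * F(d, d0)` by moment matching
#' on `log s2` (the estimator of the moderated-t method, via
#' [limma::fitFDist()]). `d0` may be infinite when the sample variances are
#' under-dispersed relative to chi-square sampling noise. With fewer than 10
#' positive variances no moderation is attempted (`d0 = 0`).
#'
#' @param s2 numeric vector of residual variances.
#' @param d residual degrees of freedom shared by all rows.
#' @return List with elements `d0` and `s0_2`.
#' @export
estimate_eb_hyperparams <- function(s2, d) {
  s2 <- s2[is.finite(s2)]
  pos <- s2[s2 > 0]
  if (length(unique(signif(pos, 12))) == 1L && length(pos) == length(s2))
    return(list(d0 = Inf, s0_2 = pos[1]))
  if (length(pos) < 10) {
    warning("fewer than 10 positive variances; falling back to no moderation")
    return(list(d0 = 0, s0_2 = stats::median(pos)))
  }
  fit <- limma::fitFDist(s2, df1 = d)
  list(d0 = fit$df2, s0_2 = fit$scale)
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each row's variance toward the prior value,
#' `s2_tilde = (d0 * s0_2 + d * s2) / (d0 + d)`, and forms
#' `t = logFC / sqrt(s2_tilde * (1/n_c + 1/n_p))` with a two-sided p-value on
#' `d + d0` degrees of freedom (standard normal when `d0` is infinite). With
#' `d0 = 0` this is exactly the classical pooled two-sample t-test.
#'
#' @param fit data frame from [fit_group_model()].
#' @param hyper list from [estimate_eb_hyperparams()].
#' @param n_control,n_perturbed group sizes.
#' @return `fit` with added columns `s2_tilde`, `t`, `p`, and a logical
#'   `degenerate` flag marking rows with zero moderated variance (infinite t,
#'   p = 0).
#' @export
moderated_t <- function(fit, hyper, n_control, n_perturbed) {
  d <- fit$df; d0 <- hyper$d0
  s2t <- if (is.infinite(d0)) rep(hyper$s0_2, nrow(fit)) else
    (d0 * hyper$s0_2 + d * fit$s2) / (d0 + d)
  sefac <- 1 / n_control + 1 / n_perturbed
  tt <- fit$logFC / sqrt(s2t * sefac)
  p <- 2 * pt(-abs(tt), df = d + d0)
  degen <- s2t <= 0
  if (any(degen)) {
    tt[degen] <- sign(fit$logFC[degen]) * Inf
    p[degen] <- 0
  }
  cbind(fit, data.frame(s2_tilde = s2t, t = tt, p = p, degenerate = degen))
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)`. The number of tests `m` defaults to the length
#' of `p` and may be larger (for example the full probe-set count of the
#' platform when only a subset of rows is supplied).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m number of tests, at least `length(p)`.
#' @return Adjusted p-values, order-preserving, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be >= length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Collapse a probe-level table to genes
#'
#' One row per gene; the probe with the smallest raw p-value represents the
#' gene. Probes absent from the mapping are dropped with a warning.
#'
#' @param table data frame with at least `probe` and `p` columns.
#' @param probe2gene data frame with columns `probe`, `gene`.
#' @return The table with a `gene` column, one row per gene.
#' @export
collapse_to_genes <- function(table, probe2gene) {
  idx <- match(table$probe, probe2gene$probe)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " probes without a gene mapping were dropped")
    table <- table[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  table$gene <- probe2gene$gene[idx]
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$gene),
                        function(i) i[which.min(table$p[i])]), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the differential-expression signature
#'
#' Rows with adjusted p-value strictly below `alpha`, split by the sign of
#' the log fold-change.
#'
#' @param table data frame with `adjusted_p`, `logFC` and a `gene` (or
#'   `probe`) column.
#' @param alpha significance threshold on the adjusted p-value.
#' @return List with character vectors `up` and `down`.
#' @export
select_signature <- function(table, alpha = 0.05) {
  id <- if ("gene" %in% names(table)) table$gene else table$probe
  sel <- !is.na(table$adjusted_p) & table$adjusted_p < alpha
  list(up = id[sel & table$logFC > 0], down = id[sel & table$logFC < 0])
}

#' Full differential-expression stage
#'
#' Convenience wrapper chaining [fit_group_model()],
#' [estimate_eb_hyperparams()], [moderated_t()], [bonferroni()] and
#' optionally [collapse_to_genes()].
#'
#' @inheritParams fit_group_model
#' @param probe2gene optional probe-to-gene map.
#' @param m number of tests for the Bonferroni multiplier; defaults to the
#'   number of rows tested.
#' @return Data frame with columns `gene`, `probe`, `logFC`, `t`, `p`,
#'   `adjusted_p`, `direction` (and the intermediate columns), ordered by
#'   raw p-value.
#' @export
run_diffexpr <- function(expr, design, probe2gene = NULL, m = nrow(expr)) {
  fit <- fit_group_model(expr, design)
  grp <- design$group[match(colnames(expr), design$sample)]
  hyper <- estimate_eb_hyperparams(fit$s2, fit$df[1])
  tab <- moderated_t(fit, hyper, sum(grp == "control"), sum(grp == "perturbed"))
  tab$adjusted_p <- bonferroni(tab$p, m)
  if (is.null(probe2gene)) tab$gene <- tab$probe else
    tab <- collapse_to_genes(tab, probe2gene)
  tab$direction <- ifelse(tab$logFC > 0, "up", "down")
  attr(tab, "hyper") <- hyper
  tab[order(tab$p), c("gene", "probe", "logFC", "s2", "df", "s2_tilde",
                      "t", "p", "adjusted_p", "direction")]
}
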