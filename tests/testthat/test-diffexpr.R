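mk_design <- function(nc, np) {
  data.frame(sample = sprintf("S%03d", seq_len(nc + np)),
             group = rep(c("control", "perturbed"), c(nc, np)))
}

test_that("two-group fit matches noiseless and symmetric expectations", {
  expr <- matrix(c(0, 0, 1, 1), 1, dimnames = list("g1", sprintf("S%03d", 1:4)))
  fit <- fit_group_model(expr, mk_design(2, 2))
  expect_equal(fit$logFC, 1)
  expect_equal(fit$s2, 0)
  expect_equal(fit$df, 2)
  # swapping labels negates the coefficient
  d2 <- mk_design(2, 2)
  d2$group <- rev(d2$group)
  expect_equal(fit_group_model(expr, d2)$logFC, -1)
  expect_error(fit_group_model(expr, data.frame(sample = colnames(expr),
                                                group = rep("control", 4))),
               "non-empty")
})

test_that("two-group fit equals the closed-form least-squares oracle", {
  set.seed(31)
  expr <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("g", 1:5), sprintf("S%03d", 1:20)))
  des <- mk_design(8, 12)
  fit <- fit_group_model(expr, des)
  for (i in 1:5) {
    y <- expr[i, ]
    x <- as.numeric(des$group == "perturbed")
    ols <- lm(y ~ x)
    expect_equal(fit$logFC[i], unname(coef(ols)[2]), tolerance = 1e-12)
    expect_equal(fit$s2[i], sum(resid(ols)^2) / ols$df.residual,
                 tolerance = 1e-12)
  }
})

test_that("variance hyperparameter estimation recovers known truth", {
  set.seed(7)
  d <- 16; d0 <- 4; s0_2 <- 1
  s2 <- s0_2 * (rchisq(10000, d) / d) / (rchisq(10000, d0) / d0)
  h <- estimate_eb_hyperparams(s2, d)
  expect_lt(abs(h$d0 - d0) / d0, 0.2)
  expect_lt(abs(h$s0_2 - s0_2) / s0_2, 0.05)
  # degenerate dispersion: identical variances pin the prior
  h2 <- estimate_eb_hyperparams(rep(0.25, 50), 10)
  expect_identical(h2$d0, Inf)
  expect_equal(h2$s0_2, 0.25)
  # too few rows: refuse to moderate
  expect_warning(h3 <- estimate_eb_hyperparams(c(0.2, 0.4), 10), "fewer")
  expect_equal(h3$d0, 0)
})

test_that("moderated t reduces to the classical pooled t when d0 = 0", {
  set.seed(12)
  expr <- matrix(rnorm(8 * 14), 8, 14,
                 dimnames = list(paste0("g", 1:8), sprintf("S%03d", 1:14)))
  des <- mk_design(6, 8)
  fit <- fit_group_model(expr, des)
  tab <- moderated_t(fit, list(d0 = 0, s0_2 = 1), 6, 8)
  for (i in 1:8) {
    tt <- t.test(expr[i, 7:14], expr[i, 1:6], var.equal = TRUE)
    expect_equal(tab$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t and p match a row-by-row formula evaluation", {
  set.seed(13)
  expr <- matrix(rnorm(30 * 12), 30, 12,
                 dimnames = list(paste0("g", 1:30), sprintf("S%03d", 1:12)))
  des <- mk_design(5, 7)
  fit <- fit_group_model(expr, des)
  h <- list(d0 = 3.7, s0_2 = 0.8)
  tab <- moderated_t(fit, h, 5, 7)
  for (i in 1:30) {
    s2t <- (h$d0 * h$s0_2 + fit$df[i] * fit$s2[i]) / (h$d0 + fit$df[i])
    tstar <- fit$logFC[i] / sqrt(s2t * (1 / 5 + 1 / 7))
    expect_equal(tab$t[i], tstar, tolerance = 1e-10)
    expect_equal(tab$p[i], 2 * pt(-abs(tstar), fit$df[i] + h$d0),
                 tolerance = 1e-10)
    # shrinkage keeps the moderated variance between s2 and s0_2
    expect_gte(s2t, min(fit$s2[i], h$s0_2) - 1e-12)
    expect_lte(s2t, max(fit$s2[i], h$s0_2) + 1e-12)
  }
})

test_that("full moderated pipeline agrees with the limma reference fit", {
  set.seed(14)
  expr <- matrix(rnorm(200 * 24, sd = rep(runif(200, 0.5, 2), 24)), 200, 24,
                 dimnames = list(paste0("g", 1:200), sprintf("S%03d", 1:24)))
  des <- mk_design(10, 14)
  tab <- run_diffexpr(expr, des)
  design_mat <- cbind(1, as.numeric(des$group == "perturbed"))
  ebfit <- limma::eBayes(limma::lmFit(expr, design_mat))
  ord <- match(tab$probe, rownames(expr))
  expect_equal(tab$t, ebfit$t[ord, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tab$p, ebfit$p.value[ord, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("bonferroni adjustment reproduces platform-scale worked examples", {
  # raw p times the 22,268 probe sets of the array, to 3 significant figures
  expect_equal(signif(bonferroni(8.88e-10, 22268), 3), 1.98e-05)
  expect_equal(signif(bonferroni(1.87e-10, 22268), 3), 4.16e-06)
  expect_equal(signif(bonferroni(1.41e-06, 22268), 3), 3.14e-02)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), ">=")
  # monotone and never below the raw p
  set.seed(5)
  p <- runif(40)
  adj <- bonferroni(p, 100)
  expect_true(all(adj >= p))
  expect_identical(order(adj[order(p)]), seq_along(p)) # order-preserving
})

test_that("probe collapsing keeps the most significant probe per gene", {
  tab <- data.frame(probe = c("p1", "p2", "p3"),
                    p = c(1e-3, 1e-8, 0.5), logFC = c(1, 2, 3))
  map <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("G1", "G1", "G2"))
  out <- collapse_to_genes(tab, map)
  expect_equal(out$probe[out$gene == "G1"], "p2")
  expect_equal(nrow(out), 2)
  # identity mapping leaves the table unchanged
  idmap <- data.frame(probe = tab$probe, gene = tab$probe)
  out2 <- collapse_to_genes(tab, idmap)
  expect_equal(out2[names(tab)], tab)
  # unmapped probes are dropped with a warning
  expect_warning(out3 <- collapse_to_genes(tab, map[1:2, ]), "dropped")
  expect_equal(nrow(out3), 1)
})

test_that("generated probe triplicates collapse to exactly one row per gene", {
  sim <- simulate_cmap_like(n_background = 30, n_signature = 10,
                            n_control = 8, n_perturbed = 12,
                            probes_per_gene = 3, seed = 21)
  tab <- run_diffexpr(sim$expr, sim$design, probe2gene = sim$probe2gene)
  expect_equal(nrow(tab), 30 + 10 + 13)
  expect_false(anyDuplicated(tab$gene) > 0)
})

test_that("signature selection splits by sign and honors the threshold", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    logFC = c(2, -1, 0.5, -2),
                    adjusted_p = c(0.01, 0.04, 0.2, 0.06))
  sig <- select_signature(tab, 0.05)
  expect_equal(sig$up, "a")
  expect_equal(sig$down, "b")
  expect_length(unlist(select_signature(tab, 0)), 0)
  expect_setequal(unlist(select_signature(tab, 1.01)), tab$gene)
})

test_that("signature recovery on shifted genes is high with controlled FWER", {
  # balanced 500-sample design, shifts >= 0.2 (log2 units), noise SD 0.5
  res <- vapply(1:20, function(r) {
    sim <- simulate_cmap_like(n_background = 1000, n_signature = 178,
                              n_control = 250, n_perturbed = 250,
                              delta_range = c(0.2, 0.32), seed = 1000 + r)
    tab <- run_diffexpr(sim$expr, sim$design)
    sig <- unlist(select_signature(tab, 0.05))
    c(recall = mean(sim$truth$signature$gene %in% sig),
      any_fp = any(sim$truth$null_genes %in% sig))
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.9)
  # Bonferroni FWER guarantee, allowing binomial sampling noise at n = 20
  expect_lte(sum(res["any_fp", ]), qbinom(0.995, 20, 0.05))
})
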