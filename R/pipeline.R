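#' Pipeline configuration
#'
#' Resolves the configuration of an end-to-end run. Defaults follow the
#' workflow's standard settings: signature threshold `alpha = 0.05`,
#' `n_perm = 10000` permutations for the enrichment test, 2 hill-climb
#' restarts, `B = 200` bootstrap replicates, central 95% score interval and
#' a 75% edge-confidence threshold. Any subset can be overridden via a YAML
#' file (`config`) and/or named arguments (`...`, highest precedence).
#'
#' @param outdir directory for all artifacts.
#' @param config optional path to a YAML file of overrides.
#' @param ... named overrides (e.g. `B = 100`, `seed = 7`,
#'   `simulate = list(n_background = 200)`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, config = NULL, ...) {
  cfg <- list(
    outdir = outdir,
    seed = 1,
    alpha = 0.05,
    n_perm = 10000,
    prior = list(mu0 = 0, nu = 1, a0 = 1, b0 = 1),
    n_restarts = 2,
    B = 200,
    score_level = 0.95,
    edge_threshold = 0.75,
    simulate = list() # forwarded to simulate_cmap_like()
  )
  if (!is.null(config)) cfg <- modifyList(cfg, yaml::read_yaml(config))
  dots <- list(...)
  if (length(dots)) cfg <- modifyList(cfg, dots)
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$n_perm >= 1,
            cfg$B >= 1, cfg$n_restarts >= 1,
            cfg$score_level > 0, cfg$score_level <= 1,
            cfg$edge_threshold >= 0, cfg$edge_threshold <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# Small FNV-1a content hash for provenance headers (config echo).
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "outdir")]), collapse = "")
  h <- 216613626
  for (k in utf8ToInt(s)) h <- ((h + k) * 16777619) %% 2^31
  sprintf("%08x", h)
}

provenance <- function(cfg, stage) {
  sprintf("apoptonet stage=%s config=%s seed=%d",
          stage, config_hash(cfg), as.integer(cfg$seed))
}

artifact <- function(cfg, name) file.path(cfg$outdir, name)

require_artifact <- function(cfg, name, producer) {
  p <- artifact(cfg, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': run stage '", producer,
         "' first", call. = FALSE)
  p
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic data with ground truth), `diffexpr`
#' (moderated-t table and signature), `enrich` (hypergeometric and
#' absolute-mean permutation enrichment of each gene set), `learn`
#' (bootstrap structure learning over signature genes inside the apoptosis
#' sets), `consensus` (score-interval filter, edge confidence, thresholded
#' network), `validate` (classification of consensus edges against the
#' reference network and the evidence subnetwork). Every artifact is a TSV
#' (or GMT/SIF) with a provenance comment naming the stage, a config hash,
#' and the master seed; re-running a stage with identical inputs, config
#' and seed reproduces its outputs byte for byte.
#'
#' @param stage one of `"simulate"`, `"diffexpr"`, `"enrich"`, `"learn"`,
#'   `"consensus"`, `"validate"`.
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a named list of the stage's artifact paths (plus the
#'   stage's main in-memory result as attribute `"result"`).
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(cfg),
         diffexpr = stage_diffexpr(cfg),
         enrich = stage_enrich(cfg),
         learn = stage_learn(cfg),
         consensus = stage_consensus(cfg),
         validate = stage_validate(cfg),
         stop("unknown stage: ", stage))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg) {
  stages <- c("simulate", "diffexpr", "enrich", "learn", "consensus",
              "validate")
  out <- lapply(stages, run_stage, cfg = cfg)
  names(out) <- stages
  invisible(out)
}

stage_simulate <- function(cfg) {
  sim <- do.call(simulate_cmap_like,
                 c(cfg$simulate, list(seed = cfg$seed)))
  hdr <- provenance(cfg, "simulate")
  write_expression_tsv(sim$expr, artifact(cfg, "expr.tsv"), hdr)
  write_design_tsv(sim$design, artifact(cfg, "design.tsv"), hdr)
  write_gmt(sim$gene_sets, artifact(cfg, "gene_sets.gmt"))
  write_edge_tsv(sim$reference, artifact(cfg, "reference.tsv"), hdr)
  truth <- list(
    sem_nodes = sim$truth$sem$dag$nodes,
    sem_edges = dag_edges(sim$truth$sem$dag),
    signature = sim$truth$signature,
    sem_deltas = as.list(sim$truth$sem_deltas))
  jsonlite::write_json(truth, artifact(cfg, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$probe2gene))
    write_edge_tsv(sim$probe2gene, artifact(cfg, "probe2gene.tsv"), hdr)
  res <- invisible(list(expr = artifact(cfg, "expr.tsv"),
                        design = artifact(cfg, "design.tsv"),
                        gene_sets = artifact(cfg, "gene_sets.gmt"),
                        reference = artifact(cfg, "reference.tsv"),
                        truth = artifact(cfg, "truth.json")))
  attr(res, "result") <- sim
  res
}

stage_diffexpr <- function(cfg) {
  expr <- read_expression_tsv(require_artifact(cfg, "expr.tsv", "simulate"))
  design <- read_design_tsv(require_artifact(cfg, "design.tsv", "simulate"))
  p2g_path <- artifact(cfg, "probe2gene.tsv")
  p2g <- if (file.exists(p2g_path)) read_edge_tsv(p2g_path) else NULL
  tab <- run_diffexpr(expr, design, probe2gene = p2g)
  sig <- select_signature(tab, cfg$alpha)
  hdr <- provenance(cfg, "diffexpr")
  write_edge_tsv(tab, artifact(cfg, "de_table.tsv"), hdr)
  writeLines(sig$up, artifact(cfg, "signature_up.txt"))
  writeLines(sig$down, artifact(cfg, "signature_down.txt"))
  res <- list(de_table = artifact(cfg, "de_table.tsv"),
              signature_up = artifact(cfg, "signature_up.txt"),
              signature_down = artifact(cfg, "signature_down.txt"))
  attr(res, "result") <- list(table = tab, signature = sig)
  invisible(res)
}

read_de_table <- function(cfg) {
  tab <- read.delim(require_artifact(cfg, "de_table.tsv", "diffexpr"),
                    comment.char = "#", stringsAsFactors = FALSE)
  tab
}

stage_enrich <- function(cfg) {
  tab <- read_de_table(cfg)
  sets <- read_gmt(require_artifact(cfg, "gene_sets.gmt", "simulate"))
  universe <- tab$gene
  signature <- tab$gene[tab$adjusted_p < cfg$alpha]
  scores <- setNames(tab$t, tab$gene)
  rows <- lapply(names(sets), function(nm) {
    hg <- hypergeom_overlap_test(signature, sets[[nm]], universe)
    gs <- abs_mean_enrichment(scores, intersect(toupper(sets[[nm]]),
                                                toupper(universe)),
                              n_perm = cfg$n_perm,
                              seed = substream_seed(cfg$seed,
                                                    paste0("gsea:", nm)))
    data.frame(set = nm, k = hg$k, n = hg$n, K = hg$K, N = hg$N,
               hypergeom_p = hg$p, es = gs$es, perm_p = gs$p,
               n_perm = gs$n_perm)
  })
  out <- do.call(rbind, rows)
  write_edge_tsv(out, artifact(cfg, "enrichment.tsv"),
                 provenance(cfg, "enrich"))
  res <- list(enrichment = artifact(cfg, "enrichment.tsv"))
  attr(res, "result") <- out
  invisible(res)
}

# Genes carried into network learning: the differential-expression signature
# intersected with the union of the apoptosis gene sets.
analysis_genes <- function(cfg) {
  tab <- read_de_table(cfg)
  sets <- read_gmt(require_artifact(cfg, "gene_sets.gmt", "simulate"))
  apo <- unique(toupper(unlist(sets)))
  sig <- toupper(tab$gene[tab$adjusted_p < cfg$alpha])
  genes <- tab$gene[toupper(tab$gene) %in% intersect(sig, apo)]
  if (length(genes) < 3)
    stop("fewer than 3 signature genes fall in the apoptosis sets; ",
         "cannot learn a network")
  genes
}

stage_learn <- function(cfg) {
  expr <- read_expression_tsv(require_artifact(cfg, "expr.tsv", "simulate"))
  genes <- analysis_genes(cfg)
  prior <- do.call(gaussian_prior, cfg$prior)
  ens <- bootstrap_learn(expr[genes, , drop = FALSE], prior, B = cfg$B,
                         seed = substream_seed(cfg$seed, "learn"),
                         n_restarts = cfg$n_restarts)
  hdr <- provenance(cfg, "learn")
  edges <- do.call(rbind, lapply(seq_along(ens$networks), function(r) {
    e <- dag_edges(ens$networks[[r]]$dag)
    if (nrow(e)) cbind(replicate = r, e) else NULL
  }))
  if (is.null(edges))
    edges <- data.frame(replicate = integer(0), from = character(0),
                        to = character(0))
  write_edge_tsv(edges, artifact(cfg, "ensemble_edges.tsv"),
                 c(hdr, paste0("nodes: ", paste(genes, collapse = ","))))
  write_edge_tsv(data.frame(replicate = seq_len(ens$B), score = ens$scores),
                 artifact(cfg, "ensemble_scores.tsv"), hdr)
  res <- list(ensemble_edges = artifact(cfg, "ensemble_edges.tsv"),
              ensemble_scores = artifact(cfg, "ensemble_scores.tsv"))
  attr(res, "result") <- ens
  invisible(res)
}

# Rebuild a minimal ensemble from the learn-stage artifacts.
read_ensemble <- function(cfg) {
  epath <- require_artifact(cfg, "ensemble_edges.tsv", "learn")
  spath <- require_artifact(cfg, "ensemble_scores.tsv", "learn")
  hdr <- grep("^# nodes:", readLines(epath, n = 5), value = TRUE)
  nodes <- strsplit(sub("^# nodes: *", "", hdr[1]), ",", fixed = TRUE)[[1]]
  edges <- read_edge_tsv(epath)
  scores <- read.delim(spath, comment.char = "#")
  networks <- lapply(seq_len(nrow(scores)), function(r) {
    e <- edges[edges$replicate == r, c("from", "to"), drop = FALSE]
    structure(list(dag = dag(nodes, e), family_scores = NULL,
                   total = scores$score[r]), class = "scored_network")
  })
  structure(list(networks = networks, scores = scores$score,
                 B = nrow(scores), n_samples = NA_integer_,
                 seed = cfg$seed, retained = seq_len(nrow(scores))),
            class = "bn_ensemble")
}

stage_consensus <- function(cfg) {
  ens <- read_ensemble(cfg)
  ens <- filter_score_interval(ens, cfg$score_level)
  conf <- edge_confidence(ens)
  net <- build_consensus(conf, cfg$edge_threshold)
  hdr <- provenance(cfg, "consensus")
  write_edge_tsv(conf$edges, artifact(cfg, "edge_confidence.tsv"), hdr)
  write_edge_tsv(net$edges, artifact(cfg, "consensus_edges.tsv"), hdr)
  write_sif(net$edges, artifact(cfg, "consensus.sif"))
  res <- list(edge_confidence = artifact(cfg, "edge_confidence.tsv"),
              consensus_edges = artifact(cfg, "consensus_edges.tsv"),
              consensus_sif = artifact(cfg, "consensus.sif"))
  attr(res, "result") <- net
  invisible(res)
}

stage_validate <- function(cfg) {
  net_edges <- read_edge_tsv(require_artifact(cfg, "consensus_edges.tsv",
                                              "consensus"))
  ref <- load_reference(require_artifact(cfg, "reference.tsv", "simulate"))
  rep <- classify_edges(net_edges, ref)
  sub <- evidence_subnetwork(rep, ref)
  hdr <- provenance(cfg, "validate")
  write_edge_tsv(rep$edges, artifact(cfg, "validation.tsv"), hdr)
  write_edge_tsv(sub$edges, artifact(cfg, "evidence_subnetwork.tsv"),
                 c(hdr, paste0("nodes: ", paste(sub$nodes, collapse = ","))))
  res <- list(validation = artifact(cfg, "validation.tsv"),
              evidence_subnetwork = artifact(cfg, "evidence_subnetwork.tsv"))
  attr(res, "result") <- list(report = rep, subnetwork = sub)
  invisible(res)
}
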