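test_that("bootstrap ensembles have the configured size and are reproducible", {
  set.seed(61)
  X <- matrix(rnorm(3 * 60), 3, 60,
              dimnames = list(paste0("n", 1:3), paste0("s", 1:60)))
  e1 <- bootstrap_learn(X, B = 1, seed = 4)
  expect_s3_class(e1, "bn_ensemble")
  expect_length(e1$networks, 1)
  a <- bootstrap_learn(X, B = 5, seed = 9)
  b <- bootstrap_learn(X, B = 5, seed = 9)
  expect_identical(lapply(a$networks, function(n) n$dag$amat),
                   lapply(b$networks, function(n) n$dag$amat))
  expect_identical(a$scores, b$scores)
  expect_error(bootstrap_learn(X, B = 0), "B must be")
})

test_that("strong signal: replicates recover every true edge; consensus is clean", {
  g <- sample_dag_n_edges(paste0("APO", sprintf("%02d", 1:13)), 15, seed = 21)
  sem <- random_sem_params(g, seed = 22)
  X <- simulate_sem(sem, 2000, seed = 23)
  ens <- bootstrap_learn(X, B = 20, seed = 5, n_restarts = 2)
  per <- vapply(ens$networks, function(nw)
    unlist(skeleton_metrics(nw$dag, g)[c("recall", "precision")]), numeric(2))
  expect_true(all(per["recall", ] == 1))
  # greedy local optima may retain covered spurious edges per replicate,
  # but they do not replicate: the 75% consensus removes them all
  net <- build_consensus(edge_confidence(filter_score_interval(ens, 0.95)),
                         0.75)
  m <- skeleton_metrics(net, g)
  expect_equal(m$precision, 1)
  expect_gte(m$recall, 0.75)
})

test_that("score-interval filtering uses the central empirical quantiles", {
  dags <- replicate(40, dag(c("A", "B")), simplify = FALSE)
  ens <- fake_ensemble(dags, scores = 1:40)
  # direct quantile computation oracle (type-7): [2.95, 38.05] -> 3..38
  f <- filter_score_interval(ens, 0.9)
  expect_equal(f$retained, 3:38)
  # identical scores or level 1: everything retained
  ens2 <- fake_ensemble(dags[1:5], scores = rep(2, 5))
  expect_equal(filter_score_interval(ens2, 0.5)$retained, 1:5)
  expect_equal(filter_score_interval(ens, 1)$retained, 1:40)
  expect_error(filter_score_interval(ens, 0), "level")
})

test_that("edge confidence counts directed and skeleton frequencies", {
  nodes <- c("A", "B", "C")
  ab <- dag(nodes, data.frame(from = "A", to = "B"))
  ba <- dag(nodes, data.frame(from = "B", to = "A"))
  # identical replicates: confidence 1 for the edge, 0 elsewhere
  conf <- edge_confidence(fake_ensemble(list(ab, ab, ab)))
  expect_equal(conf$directed["A", "B"], 1)
  expect_equal(sum(conf$directed), 1)
  # edge in 3 of 4 replicates
  conf2 <- edge_confidence(fake_ensemble(list(ab, ab, ab, dag(nodes))))
  expect_equal(conf2$directed["A", "B"], 0.75)
  # direction flips: directed 0.5/0.5, skeleton 1.0
  conf3 <- edge_confidence(fake_ensemble(list(ab, ba, ab, ba)))
  expect_equal(conf3$directed["A", "B"], 0.5)
  expect_equal(conf3$directed["B", "A"], 0.5)
  expect_equal(conf3$skeleton["A", "B"], 1)
  expect_true(all(conf3$edges$skeleton_conf >=
                    conf3$edges$directed_conf))
})

test_that("consensus thresholding is strict and resolves direction conflicts", {
  nodes <- c("A", "B", "C")
  mk <- function(...) dag(nodes, data.frame(...))
  # hand-built confidence table: A->B 0.8, B->C 0.75, C->A 0.6
  dirmat <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  dirmat["A", "B"] <- 0.8; dirmat["B", "C"] <- 0.75; dirmat["C", "A"] <- 0.6
  conf <- structure(list(
    edges = data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                       directed_conf = c(0.8, 0.75, 0.6),
                       skeleton_conf = c(0.8, 0.75, 0.6)),
    directed = dirmat, skeleton = dirmat + t(dirmat), n_retained = 20),
    class = "edge_confidence")
  net <- build_consensus(conf, 0.75) # strict: only A->B survives
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")
  net2 <- build_consensus(conf, 0.75, strict = FALSE)
  expect_setequal(paste(net2$edges$from, net2$edges$to),
                  c("A B", "B C"))
  # extreme thresholds
  expect_equal(nrow(build_consensus(conf, 1)$edges), 0)
  expect_equal(nrow(build_consensus(conf, 0)$edges), 3)
  # direction conflict: keep the stronger direction; flag exact ties
  ab <- mk(from = "A", to = "B"); ba <- mk(from = "B", to = "A")
  conf4 <- edge_confidence(fake_ensemble(list(ab, ab, ba, ab)))
  net4 <- build_consensus(conf4, 0.5)
  expect_equal(nrow(net4$edges), 1)
  expect_equal(net4$edges$from, "A")
  conf5 <- edge_confidence(fake_ensemble(list(ab, ba)))
  net5 <- build_consensus(conf5, 0.4)
  expect_equal(nrow(net5$edges), 1)
  expect_true(net5$edges$tie_flag)
})

test_that("all confidences are proper frequencies over retained replicates", {
  set.seed(62)
  X <- matrix(rnorm(4 * 80), 4, 80,
              dimnames = list(paste0("n", 1:4), paste0("s", 1:80)))
  ens <- bootstrap_learn(X, B = 12, seed = 11)
  ens <- filter_score_interval(ens, 0.95)
  conf <- edge_confidence(ens)
  expect_true(all(conf$edges$directed_conf >= 0 & conf$edges$directed_conf <= 1))
  union_edges <- unique(do.call(rbind, lapply(ens$networks[ens$retained],
                                              function(n) dag_edges(n$dag))))
  net <- build_consensus(conf, 0.3)
  if (nrow(net$edges))
    expect_true(all(paste(net$edges$from, net$edges$to) %in%
                      paste(union_edges$from, union_edges$to)))
})

test_that("vanishing signal empties the consensus at the default threshold", {
  g <- sample_dag_n_edges(5, 5, seed = 63)
  sem <- random_sem_params(g, beta_range = c(0, 0), seed = 64) # beta = 0
  X <- simulate_sem(sem, 200, seed = 65)
  ens <- bootstrap_learn(X, B = 25, seed = 13)
  net <- build_consensus(edge_confidence(filter_score_interval(ens, 0.95)),
                         0.75)
  expect_equal(nrow(net$edges), 0)
})
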