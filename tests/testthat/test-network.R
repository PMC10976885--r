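test_that("selection proportions behave at the penalty extremes", {
  set.seed(1)
  X <- matrix(rnorm(200 * 5), 200, 5)
  cfg <- stability_config(K = 20, seed = 3)
  tab <- selection_proportions(X, 10, cfg)
  expect_true(all(tab$proportion == 0))
  tab2 <- selection_proportions(X, 0.05, cfg)
  expect_true(all(tab2$count == round(tab2$proportion * 20)))
  expect_error(selection_proportions(X, -1, cfg), "positive")
})

test_that("a strong planted partial correlation is selected almost always", {
  set.seed(2)
  n <- 500
  # v1, v2 with partial correlation 0.6; eight independent noise variables
  Th <- diag(10)
  Th[1, 2] <- Th[2, 1] <- -0.6
  S <- solve(Th)
  D <- diag(1 / sqrt(diag(S)))
  X <- mtess:::rmvnorm_chol(n, D %*% S %*% D)
  colnames(X) <- paste0("v", 1:10)
  tab <- selection_proportions(scale(X), 0.05, stability_config(K = 50,
                                                                seed = 5))
  prop12 <- tab$proportion[tab$node1 == "v1" & tab$node2 == "v2"]
  expect_gt(prop12, 0.9)
})

test_that("subsampled selection is monotone non-increasing in the penalty", {
  set.seed(4)
  X <- mtess:::rmvnorm_chol(300, diag(6) * 0.5 + 0.5)
  cfg <- stability_config(K = 10, seed = 7)
  subs <- mtess:::subsample_rows(300, 10, 0.5, 7)
  qs <- vapply(c(0.6, 0.3, 0.1, 0.03), function(l)
    attr(selection_proportions(scale(X), l, cfg, subsamples = subs), "q"), 0)
  # non-increasing in lambda up to the tiny support wobbles the glasso path
  # can produce near the dense end
  expect_true(all(diff(qs) >= -0.5))
  expect_gt(qs[4], qs[1])
})

test_that("the stability score rewards separated classifications", {
  K <- 100
  # all counts at K/2: everything unstable, no stability evidence
  expect_lt(stability_score(rep(K / 2, 40), 0.9, K), 1e-8)
  # half at K, half at 0: strongly separated
  sep <- stability_score(rep(c(K, 0), 20), 0.9, K)
  expect_gt(sep, stability_score(rep(K / 2, 40), 0.9, K))
  # permutation invariance
  set.seed(8)
  cnt <- rbinom(30, K, 0.3)
  expect_equal(stability_score(cnt, 0.8, K),
               stability_score(sample(cnt), 0.8, K))
  # all zero counts: defined (all stably excluded)
  expect_true(is.finite(stability_score(rep(0, 10), 0.9, K)))
  expect_error(stability_score(cnt, 0.4, K), "pi")
})

test_that("score is maximal at fully separated proportions for fixed mu", {
  K <- 100
  base <- c(rep(K, 10), rep(0, 30))          # mu = 0.25, all 0/1
  mixed <- c(rep(K, 9), 60, 40, rep(0, 29))  # same mu, two unstable edges
  expect_gt(stability_score(base, 0.9, K), stability_score(mixed, 0.9, K))
})

test_that("the PFER bound follows its closed form", {
  expect_equal(pfer_bound(sqrt(36), 1, 36), 1)
  expect_equal(pfer_bound(0, 0.8, 100), 0)
  # monotone decreasing in pi, exploding toward pi = 0.5
  pis <- seq(0.55, 1, by = 0.05)
  b <- pfer_bound(5, pis, 50)
  expect_true(all(diff(b) < 0))
  expect_gt(pfer_bound(5, 0.5001, 50), 1e3 * pfer_bound(5, 1, 50))
  expect_error(pfer_bound(5, 0.5, 50), "exceed")
})

test_that("duplicated columns are selected with proportion one", {
  set.seed(10)
  x <- rnorm(120)
  X <- cbind(a = x, b = x + rnorm(120, sd = 1e-6), c = rnorm(120),
             d = rnorm(120))
  cfg <- stability_config(K = 20, pi_grid = 1.0, pfer_max = 1e6, seed = 2)
  net <- calibrate_network(X, cfg)
  ed <- net$edges
  expect_true(ed$stable[ed$node1 == "a" & ed$node2 == "b"])
})

test_that("planted two-block structure yields only within-block edges", {
  nodesA <- paste0("A", 1:6)
  nodesB <- paste0("B", 1:6)
  edgesA <- cbind(nodesA[1:5], nodesA[2:6])
  edgesB <- cbind(nodesB[1:5], nodesB[2:6])
  sA <- generate_graph_gaussian(nodesA, edgesA, 500, 0.4, seed = 21)
  sB <- generate_graph_gaussian(nodesB, edgesB, 500, 0.4, seed = 22)
  X <- cbind(sA$data, sB$data)
  expect_warning(
    net <- calibrate_network(X, stability_config(K = 50, pfer_max = 20,
                                                 seed = 4),
                             blocks = rep(c("A", "B"), each = 6)),
    "no stable edges there")
  ed <- net$edges[net$edges$stable, ]
  expect_gt(nrow(ed), 0)
  expect_false(any(grepl("between", ed$block_pair)))
  expect_lte(net$pfer, 20)
})

test_that("a trait-panel graph is recovered with high sensitivity", {
  g <- default_trait_graph()
  sim <- generate_graph_gaussian(colnames(default_trait_corr()), g,
                                 n = 941, partial = 0.35, seed = 11)
  net <- calibrate_network(sim$data,
                           stability_config(K = 50, pfer_max = 10, seed = 2))
  sens <- sum(net$adjacency & sim$adjacency) / sum(sim$adjacency)
  expect_gte(sens, 0.8)
  expect_lte(net$pfer, 10)
  deg <- rowSums(net$adjacency)
  expect_true(all(deg[c("BMI", "WC", "TG", "HDLC", "SBP", "DBP")] >= 2))
})

test_that("community detection matches obvious structure", {
  # two disjoint triangles
  adj <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  }
  cm <- detect_communities(adj, seed = 1)
  expect_equal(length(unique(cm$membership)), 2)
  expect_equal(length(unique(cm$membership[1:3])), 1)
  expect_equal(length(unique(cm$membership[4:6])), 1)
  # edgeless graph: singleton communities
  cm0 <- detect_communities(matrix(0, 4, 4,
                                   dimnames = list(letters[1:4],
                                                   letters[1:4])))
  expect_equal(length(unique(cm0$membership)), 4)
  # partition modularity is at least the singleton partition's
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  singleton <- igraph::modularity(g, seq_len(6))
  expect_gte(cm$modularity, singleton)
})

test_that("calibrated networks can be written as edge list and GraphML", {
  set.seed(10)
  X <- mtess:::rmvnorm_chol(300, diag(4) * 0.4 + 0.6)
  colnames(X) <- paste0("v", 1:4)
  net <- calibrate_network(X, stability_config(K = 20, seed = 1))
  net <- detect_communities(net, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, tsv, gml)
  ed <- read.delim(tsv)
  expect_equal(nrow(ed), 6)
  expect_true(file.exists(gml))
})
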