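test_that("magnitude respects the measure conventions", {
  expect_equal(magnitude(expression_dataset(c(g1 = -2), "LOG2_RATIO")),
               c(g1 = 2))
  expect_equal(magnitude(expression_dataset(c(g1 = 0.99), "ONE_MINUS_P")),
               c(g1 = 0.99))
  expect_equal(magnitude(expression_dataset(c(g1 = 1, g2 = 0),
                                            "INDICATOR")),
               c(g1 = 1, g2 = 0))
})

test_that("rank_transform gives average-tie normalized ranks", {
  expect_equal(rank_transform(c(g1 = 0.9, g2 = 0.2, g3 = 0.9, g4 = 0.1)),
               c(g1 = 0.875, g2 = 0.5, g3 = 0.875, g4 = 0.25))
  n <- 7
  expect_equal(unname(rank_transform(setNames(rep(1, n), paste0("g", 1:n)))),
               rep((n + 1) / (2 * n), n))
  # sorting oracle on 1000 seeded tie-free values
  set.seed(13)
  x <- setNames(sample(runif(1000)), paste0("g", 1:1000))
  r <- rank_transform(x)
  expect_equal(unname(r[order(x)]), seq_len(1000) / 1000)
})

test_that("project_to_nodes takes the max over measured genes", {
  g <- pathway_graph("p", nodes = c("a", "b", "c"),
                     node_genes = list(a = c("g1", "g2"), b = "g3",
                                       c = "gX"))
  rho <- c(g1 = 0.2, g2 = 0.9, g3 = 0.4)
  pn <- project_to_nodes(g, rho)
  expect_equal(pn, c(a = 0.9, b = 0.4))  # node c unmeasured -> dropped
  # one measured gene per node: identity re-keyed
  g1 <- pathway_graph("q", nodes = c("a", "b"),
                      node_genes = list(a = "g1", b = "g3"))
  expect_equal(unname(project_to_nodes(g1, rho)), unname(rho[c("g1", "g3")]))
})

test_that("pathway_statistic matches hand and oracle evaluation", {
  cfg <- enrichment_config(lambda_decay = 0.5, max_distance = 3)
  # two nodes, one edge
  g2 <- pathway_graph("p2", nodes = c("a", "b"), edges = rbind(c("a", "b")),
                      node_genes = list(a = "g1", b = "g2"))
  expect_equal(pathway_statistic(g2, c(a = 0.5, b = 1.0),
                                 node_distances(g2), cfg), 2.0)
  # path a-b-c with rho (1.0, 0.5, 0.25): hand value 2.5
  g3 <- pathway_graph("p3", nodes = c("a", "b", "c"),
                      edges = rbind(c("a", "b"), c("b", "c")),
                      node_genes = list(a = "g1", b = "g2", c = "g3"))
  rho <- c(a = 1.0, b = 0.5, c = 0.25)
  d3 <- node_distances(g3)
  expect_equal(pathway_statistic(g3, rho, d3, cfg), 2.5)
  expect_equal(pathway_statistic(g3, rho, d3, cfg),
               oracle_pathway_statistic(rho, d3, 0.5, 3))
  # edgeless graph: no pair terms
  g0 <- pathway_graph("p0", nodes = c("a", "b", "c"),
                      node_genes = list(a = "g1", b = "g2", c = "g3"))
  expect_equal(pathway_statistic(g0, rho, node_distances(g0), cfg),
               sum(rho))
  # random graphs against the nested-loop oracle
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    nodes <- paste0("n", seq_len(n))
    pairs <- t(combn(nodes, 2))
    edges <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    ng <- setNames(as.list(paste0("g", seq_len(n))), nodes)
    g <- pathway_graph("r", nodes = nodes, edges = edges, node_genes = ng)
    rho <- setNames(runif(n), nodes)
    lam <- runif(1, 0.1, 1)
    D <- sample(1:4, 1)
    cfg_r <- enrichment_config(lambda_decay = lam, max_distance = D)
    d <- node_distances(g)
    expect_equal(pathway_statistic(g, rho, d, cfg_r),
                 oracle_pathway_statistic(rho, d, lam, D))
  }
  # mean_rank variant
  cfg_m <- enrichment_config(statistic = "mean_rank")
  expect_equal(pathway_statistic(g3, rho, d3, cfg_m), mean(rho))
  expect_error(pathway_statistic(g3, numeric(0), d3, cfg), "not evaluable")
})

test_that("permutation_pvalue handles degenerate and extreme cases", {
  g <- pathway_graph("p", nodes = c("a", "b"), edges = rbind(c("a", "b")),
                     node_genes = list(a = "g1", b = "g2"))
  # full tie: every permuted statistic equals the observed one -> p = 1
  rho_tie <- rank_transform(setNames(rep(1, 10), paste0("g", 1:10)))
  res <- permutation_pvalue(g, rho_tie,
                            enrichment_config(permutations = 99, seed = 1))
  expect_equal(res$p_value, 1)
  expect_true(res$evaluable)
  expect_equal(res$n_measured_genes, 2L)
  # pathway disjoint from the measured universe -> not evaluable
  rho_other <- c(zz = 0.5)
  res0 <- permutation_pvalue(g, rho_other,
                             enrichment_config(permutations = 9, seed = 1))
  expect_false(res0$evaluable)
  expect_equal(res0$n_measured_genes, 0L)
  expect_true(is.na(res0$p_value))
  # planted top genes: no permutation can beat the maximum -> p = 1/(R+1)
  uni_rho <- rank_transform(setNames(c(runif(1998), 1.5, 1.6),
                                     paste0("g", c(3:2000, 1, 2))))
  res1 <- permutation_pvalue(g, uni_rho,
                             enrichment_config(permutations = 999, seed = 3))
  expect_equal(res1$p_value, 1 / 1000)
})

test_that("permutation estimate agrees with exhaustive enumeration", {
  # universe of 3 measured genes, pathway of 1 node / 1 gene: the exact
  # null P(S_perm >= S_obs) is the fraction of universe values >= obs
  g <- pathway_graph("p1", nodes = "a", node_genes = list(a = "g2"))
  rho <- rank_transform(c(g1 = 0.1, g2 = 0.7, g3 = 0.3))
  R <- 2000
  res <- permutation_pvalue(g, rho,
                            enrichment_config(permutations = R, seed = 8))
  p_exact <- mean(rho >= rho[["g2"]])  # = 1/3
  se <- sqrt(p_exact * (1 - p_exact) / R)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / (R + 1))
})

test_that("p-values are invariant under monotone transforms of measures", {
  uni <- filter_universe(tiny_universe())
  set.seed(17)
  vals <- setNames(runif(40), c(unique(unlist(lapply(uni$pathways,
                                                     pathway_genes))),
                                paste0("bg", 1:32)))
  cfg <- enrichment_config(permutations = 199, seed = 5)
  r1 <- enrich_all(uni, expression_dataset(vals, "ONE_MINUS_P"), cfg)
  warped <- vals^5  # strictly monotone on [0, 1]
  r2 <- enrich_all(uni, expression_dataset(warped, "ONE_MINUS_P"), cfg)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("mean_rank and topology_weighted give identical p-values on an
           edgeless graph", {
  # per pathway the two statistics differ by a constant factor under any
  # reassignment, so the permutation p-values coincide exactly
  g0 <- pathway_graph("e0", nodes = c("a", "b", "c"),
                      node_genes = list(a = "g1", b = "g2", c = "g3"))
  uni <- pathway_universe(list(g0))
  set.seed(23)
  vals <- setNames(runif(50), paste0("g", 1:50))
  ds <- expression_dataset(vals, "ONE_MINUS_P")
  p_tw <- enrich_all(uni, ds, enrichment_config(
    permutations = 499, seed = 7, lambda_decay = 1e-9,
    max_distance = 1))$p_value
  p_mr <- enrich_all(uni, ds, enrichment_config(
    permutations = 499, seed = 7, statistic = "mean_rank"))$p_value
  expect_equal(p_tw, p_mr)
})

test_that("enrich_all is deterministic and flags non-evaluable pathways", {
  uni <- filter_universe(tiny_universe())
  set.seed(2)
  vals <- setNames(runif(30), paste0("bg", 1:30))  # disjoint from pathways
  ds <- expression_dataset(vals, "ONE_MINUS_P")
  res <- enrich_all(uni, ds, enrichment_config(permutations = 9, seed = 1))
  expect_equal(nrow(res), uni$M)
  expect_true(all(!res$evaluable))
  # determinism: identical seeds give identical results
  ds2 <- simulate_dataset(uni, "Q1", delta = 0.5, seed = 4,
                          n_background_genes = 100)
  cfg <- enrichment_config(permutations = 99, seed = 12)
  expect_identical(enrich_all(uni, ds2, cfg), enrich_all(uni, ds2, cfg))
})
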