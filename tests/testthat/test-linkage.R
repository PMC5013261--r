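test_that("hypergeom_cdf matches enumeration and handles the support", {
  expect_equal(hypergeom_cdf(-1, 10, 3, 3), 0)
  expect_equal(hypergeom_cdf(3, 10, 3, 3), 1)
  # C(4,2) = 6 draws; exactly one avoids both successes
  expect_equal(hypergeom_cdf(0, 4, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_error(hypergeom_cdf(1, 5, 6, 2), "invalid")
  expect_error(hypergeom_cdf(1, 5, 2, 6), "invalid")
  # symmetry in K and N, and agreement with stats::phyper
  set.seed(3)
  for (i in 1:50) {
    M <- sample(2:40, 1)
    K <- sample(0:M, 1)
    N <- sample(0:M, 1)
    x <- sample(-1:min(K, N), 1)
    expect_equal(hypergeom_cdf(x, M, K, N), hypergeom_cdf(x, M, N, K),
                 tolerance = 1e-12)
    expect_equal(hypergeom_cdf(x, M, K, N), phyper(x, K, M - K, N),
                 tolerance = 1e-12)
  }
})

test_that("link_probability reproduces worked and derived examples", {
  expect_equal(round(link_probability(5, 161, 13, 17), 4), 0.0055)
  expect_equal(round(link_probability(5, 161, 13, 11), 4), 0.0005)
  expect_equal(link_probability(0, 161, 13, 17), 1.0)
  expect_equal(link_probability(2, 5, 2, 2), 0.1, tolerance = 1e-12)
  # identical 5-pathway sets in M = 161: p = 1/C(161, 5)
  expect_equal(link_probability(5, 161, 5, 5), 1 / choose(161, 5),
               tolerance = 1e-9)
  expect_error(link_probability(3, 10, 2, 5), "exceeds")
})

test_that("link_probability equals the subset-enumeration oracle for all
           M <= 12", {
  for (M in 1:12) {
    for (K in 0:M) {
      for (N in 0:M) {
        for (X in 0:min(K, N)) {
          expect_equal(link_probability(X, M, K, N),
                       oracle_link_probability(X, M, K, N),
                       tolerance = 1e-12,
                       label = sprintf("X=%d M=%d K=%d N=%d", X, M, K, N))
        }
      }
    }
  }
})

test_that("link_probability is monotone in X and symmetric in K and N", {
  set.seed(7)
  for (i in 1:40) {
    M <- sample(5:60, 1)
    K <- sample(1:M, 1)
    N <- sample(1:M, 1)
    xs <- 0:min(K, N)
    ps <- vapply(xs, link_probability, numeric(1), M = M, K = K, N = N)
    expect_true(all(diff(ps) <= 1e-12))
    X <- sample(xs, 1)
    expect_equal(link_probability(X, M, K, N),
                 link_probability(X, M, N, K), tolerance = 1e-12)
  }
})

test_that("association_table applies the include list", {
  df <- data.frame(gene_id = c("g1", "g2", "g3", "g3"),
                   disease_class = c("cancer", "unknown", "cancer",
                                     "cancer"))
  expect_message(at <- association_table(df, include_list = "cancer"),
                 "ignoring 1 record")
  expect_equal(nrow(at), 2L)  # duplicate record dedup'd
  expect_equal(attr(at, "classes"), "cancer")
})

test_that("exposure_pathway_sets thresholds strictly", {
  res <- data.frame(pathway_id = c("P1", "P2", "P3"),
                    p_value = c(0.049, 0.05, 0.2),
                    evaluable = TRUE)
  expect_equal(exposure_pathway_sets(res, "B")$size, 1L)  # strict <
  expect_equal(exposure_pathway_sets(res, "B")$pathway_ids, "P1")
  res$evaluable <- FALSE
  expect_equal(exposure_pathway_sets(res, "B")$size, 0L)
  res$evaluable <- TRUE
  expect_equal(exposure_pathway_sets(res, "B", alpha = 0)$size, 0L)
})

test_that("disease_pathway_sets recovers a planted disease pathway", {
  # disease genes exactly cover pathway P01 in a 20-pathway universe: the
  # indicator statistic is maximal, so P01 must enter the set at p = 1/(R+1)
  uni <- filter_universe(make_universe(universe_params(n_pathways = 20),
                                       seed = 5)$universe)
  assoc <- association_table(data.frame(
    gene_id = pathway_genes(uni$pathways$P01),
    disease_class = "planted"))
  sets <- disease_pathway_sets(assoc, uni,
                               enrichment_config(permutations = 999,
                                                 seed = 2))
  expect_true("P01" %in% sets$planted$pathway_ids)
  # a disease hitting no pathway yields an empty set with a warning
  assoc2 <- association_table(data.frame(gene_id = "not_a_gene",
                                         disease_class = "ghost"))
  expect_warning(sets2 <- disease_pathway_sets(assoc2, uni,
                            enrichment_config(permutations = 9, seed = 1)),
                 "no associated gene")
  expect_equal(sets2$ghost$size, 0L)
  # alpha = 1 admits every evaluable pathway whose p is below 1 (the
  # threshold is strict, and a discrete permutation null can hit p = 1)
  sets3 <- disease_pathway_sets(assoc, uni,
                                enrichment_config(permutations = 9,
                                                  seed = 1), alpha = 1)
  res3 <- attr(sets3$planted, "results")
  expect_equal(sets3$planted$size, sum(res3$evaluable & res3$p_value < 1))
  expect_gt(sets3$planted$size, 0L)
})

test_that("link_exposure_disease counts overlap and validates ids", {
  uni <- filter_universe(tiny_universe())
  es <- pathway_set("B", "exposure", c("Q1", "Q2"))
  dsd <- pathway_set("cancer", "disease", c("Q2"))
  lr <- link_exposure_disease(es, dsd, uni)
  expect_equal(lr$X, 1L)
  expect_equal(lr$M, uni$M)
  expect_equal(lr$K, 2L)
  expect_equal(lr$N, 1L)
  expect_equal(attr(lr, "shared_pathway_ids"), "Q2")
  expect_equal(lr$p_value, link_probability(1, uni$M, 2, 1))
  # disjoint and empty sets
  expect_equal(link_exposure_disease(
    pathway_set("B", "exposure", "Q1"),
    pathway_set("d", "disease", "Q2"), uni)$p_value, 1.0)
  empty <- link_exposure_disease(pathway_set("B", "exposure"),
                                 dsd, uni)
  expect_equal(empty$K, 0L)
  expect_equal(empty$p_value, 1.0)
  # stray id is a hard error when a universe is supplied
  expect_error(link_exposure_disease(
    pathway_set("B", "exposure", "ZZ"), dsd, uni), "absent from the universe")
  # plain integer M skips validation
  expect_equal(link_exposure_disease(es, dsd, 161)$M, 161L)
})

test_that("null linkage p-values are super-uniform", {
  M <- 50
  N <- 8
  disease <- paste0("P", 1:N)
  ids <- paste0("P", 1:M)
  set.seed(19)
  ps <- replicate(2000, {
    K <- sample(0:15, 1)
    es <- pathway_set("x", "exposure", sample(ids, K))
    X <- length(intersect(es$pathway_ids, disease))
    link_probability(X, M, K, N)
  })
  expect_lte(mean(ps < 0.05), 0.07)
})
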