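test_that("ARI and NMI match their oracles on random small partitions", {
  expect_identical(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_identical(ari(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)  # label renaming
  expect_identical(nmi(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(nmi(c(1, 1, 2, 2), c(5, 5, 5, 5)), 0)  # constant partition

  a4 <- c(0, 0, 1, 1); b4 <- c(0, 1, 0, 1)
  expect_equal(ari(a4, b4), oracle_ari(a4, b4), tolerance = 1e-12)
  expect_equal(nmi(a4, b4), oracle_nmi(a4, b4), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
    # symmetry
    expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  }
})

test_that("ARI agrees with the established mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:3, 30, replace = TRUE); b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("expected ARI over random shuffles is near zero", {
  set.seed(9)
  a <- rep(1:4, each = 10)
  scores <- replicate(200, ari(a, sample(a)))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("label maps are matched by key, and mismatches are errors", {
  a <- c(x = 1, y = 1, z = 2)
  b <- c(z = 5, x = 4, y = 4)  # same partition, different order and names
  expect_identical(ari(a, b), 1)
  expect_identical(nmi(a, b), 1)
  expect_error(ari(a, c(x = 1, y = 1, w = 2)), "key sets differ")
})

test_that("k-means separates well-separated blobs", {
  se <- make_separable_embeddings(n_per_cluster = 15, k = 2, separation = 10,
                                  dim = 2, seed = 21)
  cl <- cluster_pags(se$embedding, method = "kmeans", k = 2, seed = 1)
  expect_identical(ari(cl$labels, se$labels), 1)
  expect_identical(cl$k_effective, 2L)
  # determinism for a fixed seed
  cl2 <- cluster_pags(se$embedding, method = "kmeans", k = 2, seed = 1)
  expect_identical(cl$labels, cl2$labels)
})

test_that("girvan-newman's first split separates two bridged cliques", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("v", 1:10)
  cl <- cluster_pags(g, method = "girvan_newman", k = 2)
  expect_identical(ari(cl$labels,
                       stats::setNames(rep(1:2, each = 5), paste0("v", 1:10))), 1)
})

test_that("spectral clustering recovers both assortative and disassortative blocks", {
  asso <- generate_sbm(sbm_spec(80, c(0.5, 0.5), 0.5, 0.05, seed = 3))
  cl <- cluster_pags(asso$graph, method = "spectral", k = 2, seed = 1)
  expect_gt(ari(cl$labels, asso$labels), 0.9)
  dis <- generate_sbm(sbm_spec(80, c(0.5, 0.5), 0.05, 0.5, seed = 4))
  cl2 <- cluster_pags(dis$graph, method = "spectral", k = 2, seed = 1)
  expect_gt(ari(cl2$labels, dis$labels), 0.9)
})

test_that("louvain finds the planted communities without a k", {
  sbm <- generate_sbm(sbm_spec(90, c(0.5, 0.5), 0.4, 0.02, seed = 6))
  cl <- cluster_pags(sbm$graph, method = "louvain", seed = 2)
  expect_gt(ari(cl$labels, sbm$labels), 0.9)
})

test_that("hdbscan labels blobs and falls back to noise on tiny inputs", {
  se <- make_separable_embeddings(n_per_cluster = 25, k = 2, separation = 8,
                                  dim = 4, seed = 5)
  cl <- cluster_pags(se$embedding, method = "hdbscan", min_cluster_size = 5)
  core <- cl$labels[cl$labels != -1L]
  expect_identical(cl$k_effective, 2L)
  expect_gt(length(core) / length(cl$labels), 0.8)
  expect_identical(ari(core, se$labels[names(core)]), 1)
  # 4 points with min_cluster_size = 5: nothing is dense enough
  tiny <- embedding_matrix(matrix(rnorm(8), 4, 2), paste0("t", 1:4))
  expect_true(all(cluster_pags(tiny, method = "hdbscan")$labels == -1L))
})

test_that("input/method type mismatches and oversized k are rejected", {
  se <- make_separable_embeddings(n_per_cluster = 5, k = 2, dim = 2, seed = 1)
  g <- igraph::make_full_graph(4)
  expect_error(cluster_pags(se$embedding, method = "louvain"), "graph form")
  expect_error(cluster_pags(g, method = "kmeans", k = 2), "embeddings")
  expect_error(cluster_pags(se$embedding, method = "kmeans", k = 50), "exceeds")
  expect_error(cluster_pags(se$embedding, method = "agglomerative"), "requires k")
})
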