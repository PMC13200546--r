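two_clique_net <- function() {
  # two 10-cliques (shared gene pools) joined by one bridge PAG that
  # overlaps both; a padding PAG of unique genes keeps the universe large
  # enough that the bridge overlaps are significant (and stays isolated)
  p1 <- lapply(1:10, function(i) pag(paste0("a", i), paste0("g", 1:20)))
  p2 <- lapply(1:10, function(i) pag(paste0("b", i), paste0("h", 1:20)))
  bridge <- pag("bridge", c(paste0("g", 1:10), paste0("h", 1:10)))
  pad <- pag("pad", paste0("z", 1:60))
  build_mtype_network(pag_collection(c(p1, p2, list(bridge, pad))))
}

test_that("l2_normalize fixes row norms and preserves zero rows", {
  m <- embedding_matrix(rbind(c(1, 0), c(3, 4), c(0, 0)), c("u", "v", "z"))
  n <- l2_normalize(m)
  expect_equal(n$vectors["u", ], c(1, 0))
  expect_equal(n$vectors["v", ], c(0.6, 0.8))
  expect_equal(n$vectors["z", ], c(0, 0))
  r <- l2_normalize(matrix(rnorm(50), 10, 5))
  expect_equal(unname(sqrt(rowSums(r^2))), rep(1, 10), tolerance = 1e-12)
})

test_that("offline encoder is deterministic and vocabulary-sensitive", {
  enc <- hash_text_encoder(dim = 64)
  texts <- c("mitotic spindle assembly", "mitotic spindle checkpoint",
             "lipid storage vacuole")
  v1 <- enc(texts); v2 <- enc(texts)
  expect_identical(v1, v2)
  # identical texts -> identical rows
  same <- enc(c("x y z", "x y z"))
  expect_identical(same[1, ], same[2, ])
  # shared vocabulary scores higher than disjoint
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cos(v1[1, ], v1[2, ]), cos(v1[1, ], v1[3, ]))
  # empty text -> zero row
  expect_equal(enc("")[1, ], rep(0, 64))
})

test_that("encode_descriptions propagates encoder failures with id context", {
  boom <- function(texts) stop("backend down")
  expect_error(encode_descriptions(c(A = "x"), boom), "A")
})

test_that("PCA alignment reports retained variance per the eigenvalue oracle", {
  # exact rank-2 data: full variance in 2 components
  set.seed(1)
  base <- matrix(rnorm(40), 20, 2)
  X <- base %*% matrix(rnorm(12), 2, 6)
  m <- embedding_matrix(X, paste0("r", 1:20), source = "semantic")
  out <- pca_align(m, 2)
  expect_equal(attr(out, "retained_variance"), 1, tolerance = 1e-9)
  expect_equal(unname(sqrt(rowSums(out$vectors^2))), rep(1, 20),
               tolerance = 1e-9)

  # isotropic data: retained variance tracks the eigenvalue-sum oracle and
  # a warning marks the shortfall below 95%
  set.seed(2)
  Y <- matrix(rnorm(10000 * 40), 10000, 40)
  my <- embedding_matrix(Y, paste0("r", 1:10000), source = "semantic")
  ev <- eigen(stats::cov(Y), symmetric = TRUE, only.values = TRUE)$values
  expect_warning(out2 <- pca_align(my, 8), "variance")
  expect_equal(attr(out2, "retained_variance"), sum(ev[1:8]) / sum(ev),
               tolerance = 1e-9)
  expect_equal(attr(out2, "retained_variance"), 8 / 40, tolerance = 0.25)
})

test_that("full-dimensional PCA is a rotation: pairwise distances preserved", {
  set.seed(3)
  X <- matrix(rnorm(15 * 6), 15, 6)
  m <- embedding_matrix(X, paste0("r", 1:15), source = "semantic")
  pc <- stats::prcomp(X, center = TRUE)
  expect_equal(as.matrix(dist(pc$x)), as.matrix(dist(scale(X, scale = FALSE))),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(pca_align(m, 7), "too large")
})

test_that("graph embedding separates cliques, zeroes isolated nodes, and is deterministic", {
  net <- two_clique_net()
  cfg <- walk_config(dim = 16, walk_length = 30, seed = 11)
  for (seed in c(11, 12, 13)) {
    cfg$seed <- seed
    e <- embed_graph(net, cfg)
    v <- e$vectors
    a <- v[paste0("a", 1:10), ]; b <- v[paste0("b", 1:10), ]
    within <- (mean(a %*% t(a)) + mean(b %*% t(b))) / 2
    between <- mean(a %*% t(b))
    expect_gt(within, between + 0.2)
  }
  # isolated node gets a zero vector
  iso <- pag_collection(list(pag("A", paste0("g", 1:5)),
                             pag("B", paste0("g", 1:5)),
                             pag("L", paste0("z", 1:5))),
                        universe = c(paste0("g", 1:5), paste0("z", 1:5)))
  ei <- embed_graph(build_mtype_network(iso), walk_config(dim = 8, seed = 1))
  expect_equal(unname(ei$vectors["L", ]), rep(0, 8))
  expect_gt(sum(ei$vectors["A", ]^2), 0.99)
  # bitwise determinism
  cfg$seed <- 99
  expect_identical(embed_graph(net, cfg)$vectors, embed_graph(net, cfg)$vectors)
})

test_that("every non-isolated node starts exactly walks_per_node walks", {
  net <- two_clique_net()
  g <- as_igraph(net)
  n_active <- sum(igraph::degree(g) > 0)
  expect_identical(n_active, 21L)  # both cliques plus the bridge; pad isolated
  cfg <- walk_config(walks_per_node = 7, walk_length = 5, seed = 2)
  w <- random_walks(net, cfg)
  starts <- table(w[, 1])
  expect_true(all(starts == 7))
  expect_identical(length(starts), n_active)
})

test_that("with p = q = 1 on an unweighted graph walks reduce to the simple random walk", {
  g <- igraph::graph_from_edgelist(rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                                         c(4, 5)), directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:5)
  cfg <- walk_config(walk_length = 400, walks_per_node = 6, return_p = 1,
                     inout_q = 1, weighted = FALSE, seed = 5)
  w <- random_walks(g, cfg)
  trans <- table(from = w[, -ncol(w)], to = w[, -1])
  emp <- trans / rowSums(trans)
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (v in 1:5) for (u in 1:5) {
    want <- if (adj[v, u] > 0) 1 / deg[v] else 0
    got <- if (as.character(u) %in% colnames(emp)) emp[as.character(v),
                                                      as.character(u)] else 0
    expect_equal(unname(got), unname(want), tolerance = 0.05)
  }
})

test_that("embedding TSV round-trips", {
  net <- two_clique_net()
  e <- embed_graph(net, walk_config(dim = 8, walk_length = 10, seed = 3))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_tsv(e, tf)
  back <- read_embedding_tsv(tf, source = "graph")
  expect_identical(back$row_ids, e$row_ids)
  expect_equal(back$vectors, e$vectors, tolerance = 1e-12, ignore_attr = TRUE)
})
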