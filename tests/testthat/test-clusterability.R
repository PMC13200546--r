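test_that("SBM degenerate probabilities give complete / disconnected graphs", {
  full <- generate_sbm(sbm_spec(10, c(0.5, 0.5), 1, 1, seed = 1))
  expect_identical(igraph::ecount(full$graph), choose(10, 2))
  split <- generate_sbm(sbm_spec(10, c(0.5, 0.5), 1, 0, seed = 2))
  expect_identical(igraph::ecount(split$graph), 2 * choose(5, 2))
  comp <- igraph::components(split$graph)
  expect_equal(as.integer(comp$no), 2L)
  expect_identical(ari(comp$membership, split$labels), 1)
})

test_that("SBM edge count matches the binomial expectation within 3 sigma", {
  for (cell in list(c(0.3, 0.1), c(0.6, 0.4), c(0.9, 0.2))) {
    sbm <- generate_sbm(sbm_spec(200, c(0.5, 0.5), cell[1], cell[2],
                                 seed = round(1000 * cell[1] + 10 * cell[2])))
    n_within <- 2 * choose(100, 2); n_between <- 100 * 100
    mu <- cell[1] * n_within + cell[2] * n_between
    sigma <- sqrt(cell[1] * (1 - cell[1]) * n_within +
                  cell[2] * (1 - cell[2]) * n_between)
    expect_lt(abs(igraph::ecount(sbm$graph) - mu), 3 * sigma)
  }
})

test_that("degree correction reduces to the SBM at unit weights and skews degrees", {
  spec_plain <- sbm_spec(100, c(0.5, 0.5), 0.3, 0.1, seed = 5)
  spec_ones <- sbm_spec(100, c(0.5, 0.5), 0.3, 0.1,
                        degree_correction = rep(1, 100), seed = 5)
  expect_identical(igraph::as_adjacency_matrix(generate_dcsbm(spec_ones)$graph),
                   igraph::as_adjacency_matrix(generate_sbm(spec_plain)$graph))

  # heavy-tailed weights widen the degree distribution at matched density
  plain_var <- dc_var <- numeric(20)
  for (i in 1:20) {
    pl <- generate_sbm(sbm_spec(100, c(0.5, 0.5), 0.3, 0.1, seed = 100 + i))
    theta <- function(n) { w <- (1:n)^-0.8; w / mean(w) }
    dc <- generate_dcsbm(sbm_spec(100, c(0.5, 0.5), 0.3, 0.1,
                                  degree_correction = theta, seed = 100 + i))
    plain_var[i] <- var(igraph::degree(pl$graph))
    dc_var[i] <- var(igraph::degree(dc$graph))
  }
  expect_gt(mean(dc_var), 2 * mean(plain_var))

  # zero-weight node is isolated
  w0 <- c(0, rep(1, 49))
  dc0 <- generate_dcsbm(sbm_spec(50, c(0.5, 0.5), 0.8, 0.8,
                                 degree_correction = w0, seed = 3))
  expect_identical(igraph::degree(dc0$graph)[1], c(v1 = 0))
})

test_that("clustering-coefficient features match exhaustive triangle counting", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(cc_features(k3), c(cc_mean = 1, cc_spread = 0))
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(cc_features(star), c(cc_mean = 0, cc_spread = 0))
  # square with one diagonal
  adj <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3), c(4, 5))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cc <- oracle_local_cc(adj)
  expect_equal(unname(cc_features(g)["cc_mean"]), mean(cc), tolerance = 1e-12)
  expect_equal(unname(cc_features(g)["cc_spread"]), sd(cc), tolerance = 1e-12)
  expect_equal(unname(cc_features(g, spread = "var")["cc_spread"]), var(cc),
               tolerance = 1e-12)
})

test_that("planted-partition labeling binarizes ARI at tau", {
  split <- generate_sbm(sbm_spec(40, c(0.5, 0.5), 1, 0, seed = 7))
  lab <- label_graph(split$graph, split$labels, tau = 0.7, seed = 1)
  expect_identical(lab$ari_raw, 1)
  expect_identical(lab$label_bin, 1L)
  expect_identical(label_graph(split$graph, split$labels, tau = 0)$label_bin, 1L)

  # no planted structure: ARI near zero, label 0 (clipped to [0,1])
  flat <- generate_sbm(sbm_spec(100, c(0.5, 0.5), 0.3, 0.3, seed = 8))
  lab0 <- label_graph(flat$graph, flat$labels, tau = 0.7, seed = 1)
  expect_lt(lab0$ari_raw, 0.2)
  expect_gte(lab0$ari_raw, 0)
  expect_identical(lab0$label_bin, 0L)
})

test_that("training-set construction records the sweep design", {
  ts <- build_training_set(grid = c(0.2, 0.8), replicates = 2, n_nodes = 60,
                           seed = 9)
  expect_identical(nrow(ts$X), 8L)
  expect_identical(colnames(ts$X), c("cc_mean", "cc_spread"))
  expect_identical(ts$y_bin, as.integer(ts$y_raw >= ts$tau))
  expect_true(all(ts$y_raw >= 0 & ts$y_raw <= 1))
  expect_identical(sort(unique(ts$design$p_intra)), c(0.2, 0.8))
})

test_that("clusterable-labeled graphs have higher clustering coefficients", {
  ts <- build_training_set(grid = seq(0.2, 1, by = 0.2), replicates = 2,
                           n_nodes = 80, seed = 10)
  expect_true(any(ts$y_bin == 1) && any(ts$y_bin == 0))
  # ordering property: assortative clusterable graphs are triangle-rich
  asso <- ts$design$p_intra > ts$design$p_inter
  expect_gt(mean(ts$X[ts$y_bin == 1 & asso, "cc_mean"]),
            mean(ts$X[ts$y_bin == 0, "cc_mean"]))
})

test_that("all model kinds fit a linearly separable toy exactly", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  colnames(X) <- c("cc_mean", "cc_spread")
  ts <- structure(list(X = X, y_raw = rep(c(0, 1), each = 30),
                       y_bin = rep(c(0L, 1L), each = 30), tau = 0.7,
                       design = NULL, features = "cc", seed = 1),
                  class = "cdi_training_set")
  m <- train_cdi(ts, model_kinds = c("logistic", "svm", "random_forest", "knn",
                                     "gradient_boosting", "mlp"),
                 split_seed = 3)
  core <- m$metrics[m$metrics$kind %in% c("logistic", "svm", "random_forest",
                                          "knn"), ]
  expect_true(all(core$accuracy == 1))
  expect_true(all(core$f1 == 1))
  expect_true(all(m$metrics$accuracy >= 0.9))
  # degenerate labels are rejected
  ts$y_bin <- rep(1L, 60)
  expect_error(train_cdi(ts), "degenerate")
})

test_that("the CDI separates blocked from unstructured graphs", {
  m <- shared_cdi_model()
  expect_identical(m$kind, "random_forest")
  pos <- vapply(1:15, function(i) cdi_score(m,
    generate_sbm(sbm_spec(120, c(0.5, 0.5), 0.9, 0.05, seed = 500 + i))$graph),
    numeric(1))
  neg <- vapply(1:15, function(i) cdi_score(m,
    generate_sbm(sbm_spec(120, c(0.5, 0.5), 0.2, 0.2, seed = 600 + i))$graph),
    numeric(1))
  expect_true(all(pos >= 0 & pos <= 1) && all(neg >= 0 & neg <= 1))
  expect_gt(mean(pos), 0.9)
  expect_lt(mean(neg), 0.5)
  expect_gt(oracle_auc(pos, neg), 0.9)
})

test_that("retraining at nearby tau moves test accuracy by less than 0.1", {
  base <- shared_cdi_model()
  acc <- function(tau) {
    ts <- build_training_set(replicates = 3, n_nodes = 120, tau = tau,
                             seed = 4242)
    train_cdi(ts, model_kinds = "random_forest", split_seed = 7)$metrics$accuracy
  }
  expect_lt(abs(acc(0.65) - base$metrics$accuracy), 0.1)
  expect_lt(abs(acc(0.75) - base$metrics$accuracy), 0.1)
})

test_that("CDI models round-trip through their serialized form", {
  m <- shared_cdi_model()
  tf <- withr::local_tempfile()
  write_cdi_model(m, tf)
  expect_true(file.exists(paste0(tf, ".json")))
  back <- read_cdi_model(tf)
  g <- generate_sbm(sbm_spec(120, c(0.5, 0.5), 0.8, 0.1, seed = 77))$graph
  expect_identical(cdi_score(back, g), cdi_score(m, g))
})
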