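test_that("hypergeometric tail matches exhaustive combinatorial summation", {
  expect_identical(hypergeometric_overlap_pvalue(0, 5, 5, 100), 1)
  expect_equal(hypergeometric_overlap_pvalue(5, 5, 5, 10), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap_pvalue(2, 3, 4, 10),
               oracle_hyper_upper(2, 3, 4, 10), tolerance = 1e-12)
})

test_that("hypergeometric pmf sums to one and the tail is monotone in k", {
  for (cfg in list(c(5, 5, 10), c(3, 7, 12), c(6, 6, 9))) {
    n_a <- cfg[1]; n_b <- cfg[2]; N <- cfg[3]
    ks <- max(0, n_a + n_b - N):min(n_a, n_b)
    pmf <- choose(n_a, ks) * choose(N - n_a, n_b - ks) / choose(N, n_b)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    tail <- vapply(ks, hypergeometric_overlap_pvalue, numeric(1),
                   n_a = n_a, n_b = n_b, N = N)
    expect_true(all(diff(tail) <= 1e-15))
  }
})

test_that("infeasible overlap configurations are domain errors", {
  expect_error(hypergeometric_overlap_pvalue(6, 5, 5, 10), "feasible range")
  expect_error(hypergeometric_overlap_pvalue(0, 9, 9, 10), "feasible range")
  expect_error(hypergeometric_overlap_pvalue(1, 11, 5, 10), "n_a")
})

test_that("m-type network edges follow the overlap test", {
  # disjoint sets: nodes retained, zero edges
  net0 <- build_mtype_network(make_collection(list(A = c("g1", "g2"),
                                                   B = c("g3", "g4"))))
  expect_identical(nrow(net0$edges), 0L)
  expect_length(net0$node_ids, 2)

  # identical 5-gene sets in a 10-gene universe: p = 1/252
  col <- pag_collection(list(pag("A", paste0("g", 1:5)),
                             pag("B", paste0("g", 1:5))),
                        universe = paste0("g", 1:10))
  net <- build_mtype_network(col, p_cutoff = 0.05)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(net$edges$weight, -log10(1 / 252), tolerance = 1e-12)
  expect_identical(net$edges$overlap, 5L)
})

test_that("only significantly overlapping pairs gain edges", {
  # three sets in a 20-gene universe; only A-B overlap strongly
  col <- pag_collection(list(pag("A", paste0("g", 1:6)),
                             pag("B", paste0("g", 1:6)),
                             pag("C", c("g6", paste0("g", 15:19)))),
                        universe = paste0("g", 1:20))
  # brute-force pairwise p-values with the enumeration oracle
  p_ab <- oracle_hyper_upper(6, 6, 6, 20)
  p_ac <- oracle_hyper_upper(1, 6, 6, 20)
  expect_lt(p_ab, 0.05); expect_gt(p_ac, 0.05)
  net <- build_mtype_network(col, p_cutoff = 0.05)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(sort(c(net$edges$i, net$edges$j)), c("A", "B"))
})

test_that("build_mtype_network is symmetric under collection permutation", {
  sets <- list(A = paste0("g", 1:8), B = paste0("g", 5:12),
               C = paste0("g", 10:17), D = paste0("g", 3:9))
  net1 <- build_mtype_network(make_collection(sets), p_cutoff = 1)
  net2 <- build_mtype_network(make_collection(sets[c(3, 1, 4, 2)]), p_cutoff = 1)
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$i, e$j), pmax(e$i, e$j), e$overlap,
               signif(e$p_value, 12)))
  }
  expect_identical(key(net1), key(net2))
})

test_that("threshold_network filters edges but never nodes", {
  sets <- list(A = paste0("g", 1:8), B = paste0("g", 5:12),
               C = paste0("g", 10:17), D = paste0("g", 3:9))
  net <- build_mtype_network(make_collection(sets), p_cutoff = 1)
  expect_gt(nrow(net$edges), 2)
  expect_identical(threshold_network(net, 0)$edges, net$edges)
  none <- threshold_network(net, Inf)
  expect_identical(nrow(none$edges), 0L)
  expect_identical(none$node_ids, net$node_ids)
  mid <- stats::median(net$edges$weight)
  kept <- threshold_network(net, mid)
  expect_identical(nrow(kept$edges), sum(net$edges$weight >= mid))
})

test_that("network TSV and GraphML round trips preserve structure", {
  net <- build_mtype_network(make_collection(list(
    A = paste0("g", 1:8), B = paste0("g", 5:12), Z = "g99")), p_cutoff = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, tf)
  back <- read_network_tsv(tf, node_ids = net$node_ids,
                           universe_size = net$universe_size)
  expect_equal(back$edges, net$edges, tolerance = 1e-12)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(as.integer(igraph::vcount(g)), 3L)
  expect_equal(as.integer(igraph::ecount(g)), nrow(net$edges))
})
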