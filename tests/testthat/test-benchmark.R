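test_that("parent eligibility respects the inclusive/exclusive regime bounds", {
  # term with exactly 5 children: eligible for 5-10; with 10: not
  ch <- c(paste0("f", 1:5), paste0("t", 1:10), "m5", "m10")
  pa <- c(rep("m5", 5), rep("m10", 10), "root", "root")
  dag <- ontology_dag(ch, pa)
  expect_identical(eligible_parents(dag, "SPAG_5_10"), "m5")
  expect_identical(eligible_parents(dag, "SPAG_10_100"), "m10")

  dag2 <- toy_dag()
  cnt <- lengths(term_children(dag2))
  expect_identical(eligible_parents(dag2, "SPAG_5_10"),
                   sort(names(cnt)[cnt >= 5 & cnt < 10]))
})

test_that("pair enumeration matches a brute-force constraint check on the toy DAG", {
  dag <- toy_dag()
  groups <- enumerate_pairs(dag, regime = "SPAG_5_10", root = "root")
  got <- sort(vapply(groups, function(g) paste(sort(g$parent_ids),
                                               collapse = "+"), character(1)))

  # independent O(n^2) oracle straight from the constraint definitions
  bounds <- c(5, 10)
  kids <- split(dag$edges[, "child"], dag$edges[, "parent"])
  pars <- split(dag$edges[, "parent"], dag$edges[, "child"])
  depth <- igraph::distances(dag$graph, v = "root", mode = "in")[1, ]
  elig <- names(kids)[lengths(lapply(kids, unique)) >= bounds[1] &
                      lengths(lapply(kids, unique)) < bounds[2]]
  want <- character(0)
  for (x in elig) for (y in elig) {
    if (x >= y) next
    if (depth[x] != depth[y]) next
    if (length(intersect(pars[[x]], pars[[y]]))) next
    sh <- intersect(kids[[x]], kids[[y]])
    mx <- setdiff(kids[[x]], sh); my <- setdiff(kids[[y]], sh)
    if (length(mx) < bounds[1] || length(mx) >= bounds[2]) next
    if (length(my) < bounds[1] || length(my) >= bounds[2]) next
    want <- c(want, paste(sort(c(x, y)), collapse = "+"))
  }
  expect_identical(got, sort(want))

  # the expected structure, spelled out: p1/p2 share parent A, p5 is
  # level-mismatched, so only p1/p2 x p3/p4 pairs and (p3, p4) survive;
  # (p3, p4) loses shared child x1 from both member lists
  expect_identical(got, c("p1+p3", "p1+p4", "p2+p3", "p2+p4", "p3+p4"))
  p34 <- groups[[which(got == "p3+p4")]]
  expect_false("x1" %in% p34$members)
})

test_that("every enumerated group satisfies the group invariants", {
  dag <- toy_dag()
  depth <- term_depths(dag, "root")
  for (g in enumerate_pairs(dag, regime = "SPAG_5_10", root = "root")) {
    expect_identical(unname(depth[g$parent_ids[1]]), g$level)
    expect_identical(unname(depth[g$parent_ids[2]]), g$level)
    expect_false(g$parent_ids[1] == g$parent_ids[2])
    pars <- term_parents(dag, g$parent_ids)
    expect_length(intersect(pars[[1]], pars[[2]]), 0)
    kids <- term_children(dag, g$parent_ids)
    for (i in seq_along(g$members)) {
      owner <- g$parent_ids[g$labels[i]]
      other <- setdiff(g$parent_ids, owner)
      expect_true(g$members[i] %in% kids[[owner]])
      expect_false(g$members[i] %in% kids[[other]])
    }
    sizes <- table(g$labels)
    expect_true(all(sizes >= 5 & sizes < 10))
  }
  # degenerate inputs
  expect_error(enumerate_pairs(dag, root = "missing"), "root")
  lone <- ontology_dag(c(paste0("k", 1:6), "p"), c(rep("p", 6), "root"))
  expect_identical(enumerate_pairs(lone, "SPAG_5_10", root = "root"), list())
})

test_that("group evaluation reflects the available signal", {
  fix <- make_fixture("clusterable", seed = 41)
  grp <- enumerate_pairs(fix$dag, root = "root")[[1]]
  ev <- evaluate_group(grp, fix$collection, fix$descriptions, alpha = 0.8,
                       seed = 3)
  expect_identical(ev$ari, 1)
  expect_identical(ev$nmi, 1)

  # identical genes and identical text across both parents: no signal
  fix0 <- make_fixture(fixture_spec(within_parent_gene_overlap = 1,
                                    between_parent_gene_overlap = 1,
                                    shared_vocab_fraction = 1, seed = 42))
  grp0 <- enumerate_pairs(fix0$dag, root = "root")[[1]]
  ev0 <- evaluate_group(grp0, fix0$collection, fix0$descriptions, alpha = 0.8,
                        seed = 3)
  expect_lt(abs(ev0$ari), 0.3)

  # alpha direction on a graph-signal-only fixture
  fg <- make_fixture("graph_only", seed = 43)
  gg <- enumerate_pairs(fg$dag, root = "root")[[1]]
  a0 <- evaluate_group(gg, fg$collection, fg$descriptions, alpha = 0, seed = 3)
  a1 <- evaluate_group(gg, fg$collection, fg$descriptions, alpha = 1, seed = 3)
  expect_gt(a0$ari, a1$ari)
})

test_that("the repeated-sampling protocol is reproducible and respects its bounds", {
  se <- make_separable_embeddings(n_per_cluster = 30, k = 4, separation = 10,
                                  dim = 6, seed = 44)
  res <- repeated_sampling_protocol(se$embedding, se$labels, n_trials = 25,
                                    max_per_category = 20, seed = 9)
  expect_identical(unname(res$summary["ari_mean"]), 1)
  expect_identical(unname(res$summary["ari_sd"]), 0)
  expect_identical(nrow(res$trials), 25L)
  expect_true(all(res$trials$n <= 40))
  res2 <- repeated_sampling_protocol(se$embedding, se$labels, n_trials = 25,
                                     max_per_category = 20, seed = 9)
  expect_identical(res$trials, res2$trials)

  # shuffled labels: permutation null, mean ARI near zero
  shuffled <- stats::setNames(sample(se$labels), names(se$labels))
  null <- repeated_sampling_protocol(se$embedding, shuffled, n_trials = 25,
                                     seed = 10)
  expect_lt(abs(null$summary["ari_mean"]), 0.15)
})
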