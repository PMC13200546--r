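# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: combinatorial sums via choose(), pair counting
# via explicit loops, entropies straight from the contingency table.

# upper-tail hypergeometric by exhaustive pmf summation
oracle_hyper_upper <- function(k, n_a, n_b, N) {
  xs <- k:min(n_a, n_b)
  sum(choose(n_a, xs) * choose(N - n_a, n_b - xs)) / choose(N, n_b)
}

# ARI by brute-force pair enumeration (2x2 pair-agreement table)
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

# NMI from the contingency table, entropies by hand
oracle_nmi <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  p <- tab / n
  pi_ <- rowSums(p); pj_ <- colSums(p)
  H <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  if (H(pi_) == 0 || H(pj_) == 0) return(0)
  mi <- 0
  for (i in seq_along(pi_)) for (j in seq_along(pj_)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pi_[i] * pj_[j]))
  }
  unname(mi / ((H(pi_) + H(pj_)) / 2))
}

# rank-statistic AUROC
oracle_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# local clustering coefficient by exhaustive triangle / wedge counting
oracle_local_cc <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    tri <- 0
    for (x in seq_along(nb)) for (y in seq_along(nb)) {
      if (x < y && adj[nb[x], nb[y]] == 1) tri <- tri + 1
    }
    tri / choose(length(nb), 2)
  })
}

# a compact CDI model shared by tests that only need *some* trained model;
# trained once per session (reduced sweep: 3 replicates, 120-node graphs)
shared_cdi_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- build_training_set(replicates = 3, n_nodes = 120, seed = 4242)
      cache <<- train_cdi(ts, model_kinds = "random_forest", split_seed = 7)
    }
    cache
  }
})

make_collection <- function(sets) {
  pag_collection(lapply(names(sets), function(id) pag(id, sets[[id]])))
}

# A ~40-term toy ontology with known structure:
# root -> A, B, C; parents p1, p2 under A (sharing it), p3 under B, p4 under
# C; p5 sits directly under root (level-mismatched with the others);
# p1..p5 have 6, 5, 6, 5, 6 children; child "x1" is shared by p3 and p4.
toy_dag <- function() {
  ch <- c("A", "B", "C", "p5",
          "p1", "p2", "p3", "p4",
          paste0("a", 1:6), paste0("b", 1:5), paste0("c", 1:6),
          paste0("d", 1:5), paste0("e", 1:6), "x1", "x1")
  pa <- c("root", "root", "root", "root",
          "A", "A", "B", "C",
          rep("p1", 6), rep("p2", 5), rep("p3", 6),
          rep("p4", 5), rep("p5", 6), "p3", "p4")
  ontology_dag(ch, pa)
}
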