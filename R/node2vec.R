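#' Random-walk / skip-gram configuration
#'
#' Hyperparameters for graph embedding: biased second-order random walks
#' followed by skip-gram training with negative sampling. Defaults follow
#' common practice for node2vec-style embeddings on gene-set networks:
#' walk length 80, 10 walks per node, context window 10, 5 negative samples,
#' return parameter `p = 1.0`, in-out parameter `q = 0.25` (a `q < 1` biases
#' walks outward, emphasizing community structure).
#'
#' @param walk_length Steps per walk.
#' @param walks_per_node Walks started from every non-isolated node.
#' @param window Skip-gram context window.
#' @param negative_samples Negative samples per positive pair.
#' @param return_p Return parameter `p` (> 0).
#' @param inout_q In-out parameter `q` (> 0).
#' @param dim Embedding dimension (64 or 256 are the usual choices).
#' @param epochs Skip-gram passes over the walk corpus.
#' @param learning_rate Initial SGD learning rate (decays linearly).
#' @param weighted Use edge weights as unnormalized transition preferences;
#'   set `FALSE` to walk on the unweighted skeleton.
#' @param seed Integer seed; the embedding is bit-reproducible given the
#'   seed and graph.
#' @return A `walk_config` list.
#' @export
walk_config <- function(walk_length = 80, walks_per_node = 10, window = 10,
                        negative_samples = 5, return_p = 1.0, inout_q = 0.25,
                        dim = 64, epochs = 5, learning_rate = 0.025,
                        weighted = TRUE, seed = 1) {
  stopifnot(walk_length >= 1, walks_per_node >= 1, window >= 1,
            negative_samples >= 0, return_p > 0, inout_q > 0,
            dim >= 1, epochs >= 1, learning_rate > 0)
  structure(list(walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window),
                 negative_samples = as.integer(negative_samples),
                 return_p = return_p, inout_q = inout_q,
                 dim = as.integer(dim), epochs = as.integer(epochs),
                 learning_rate = learning_rate, weighted = isTRUE(weighted),
                 seed = as.integer(seed)),
            class = "walk_config")
}

# CSR adjacency (0-based, sorted neighbor lists) from a pag_network or igraph
as_csr <- function(g) {
  if (inherits(g, "pag_network")) g <- as_igraph(g)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight %||% rep(1, nrow(el))
  if (is.null(igraph::E(g)$weight)) w <- rep(1, nrow(el))
  from <- c(el[, 1], el[, 2]); to <- c(el[, 2], el[, 1]); ww <- c(w, w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; ww <- ww[o]
  deg <- tabulate(from, nbins = n)
  offsets <- c(0L, cumsum(deg))
  list(offsets = as.integer(offsets), nbrs = as.integer(to - 1L),
       wts = as.numeric(ww), n = n,
       names = igraph::V(g)$name %||% as.character(seq_len(n)))
}

#' Generate biased second-order random walks
#'
#' Each non-isolated node starts exactly `walks_per_node` walks. The
#' transition law from node `v`, having arrived from `u`, weights each
#' neighbor `x` by `w(v,x) * bias(x)` where bias is `1/p` for returning to
#' `u`, `1` for common neighbors of `u` and `v`, and `1/q` otherwise. With
#' `p = q = 1` on an unweighted graph this is the simple random walk.
#'
#' @param net A `pag_network` or `igraph` graph.
#' @param cfg A [walk_config()].
#' @return Integer matrix of node indices (1-based; NA where a walk stopped
#'   at a neighborless node), with node names in
#'   `attr(, "node_names")`.
#' @export
random_walks <- function(net, cfg = walk_config()) {
  csr <- as_csr(net)
  if (!cfg$weighted) csr$wts[] <- 1
  deg <- diff(csr$offsets)
  starts0 <- rep(which(deg > 0) - 1L, each = cfg$walks_per_node)
  if (!length(starts0)) {
    w <- matrix(NA_integer_, 0, cfg$walk_length)
    attr(w, "node_names") <- csr$names
    return(w)
  }
  w <- n2v_walks(csr$offsets, csr$nbrs, csr$wts, as.integer(starts0),
                 cfg$walk_length, cfg$return_p, cfg$inout_q,
                 as.numeric(cfg$seed))
  w[w < 0] <- NA_integer_
  w <- w + 1L
  attr(w, "node_names") <- csr$names
  w
}

#' Graph embedding by random walks + skip-gram
#'
#' Runs [random_walks()] and trains skip-gram with negative sampling on the
#' walk corpus. One row per node, in network node order; isolated nodes
#' (degree zero) receive an all-zero vector so that no PAG is dropped.
#' Rows are L2-normalized. Deterministic for a fixed seed.
#'
#' @param net A `pag_network` or `igraph` graph.
#' @param cfg A [walk_config()].
#' @return An `embedding_matrix` with `source = "graph"`.
#' @export
embed_graph <- function(net, cfg = walk_config()) {
  csr <- as_csr(net)
  if (!cfg$weighted) csr$wts[] <- 1
  deg <- diff(csr$offsets)
  starts0 <- rep(which(deg > 0) - 1L, each = cfg$walks_per_node)
  if (length(starts0)) {
    walks <- n2v_walks(csr$offsets, csr$nbrs, csr$wts, as.integer(starts0),
                       cfg$walk_length, cfg$return_p, cfg$inout_q,
                       as.numeric(cfg$seed))
    vec <- sgns_train(walks, csr$n, cfg$dim, cfg$window,
                      cfg$negative_samples, cfg$epochs, cfg$learning_rate,
                      as.numeric(cfg$seed))
  } else {
    vec <- matrix(0, csr$n, cfg$dim)
  }
  vec[deg == 0, ] <- 0  # isolated nodes: zero-vector rule
  rownames(vec) <- csr$names
  l2_normalize(embedding_matrix(vec, csr$names, source = "graph"))
}
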