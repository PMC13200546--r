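#' Specification of a synthetic (DC-)SBM graph
#'
#' Two-block (or multi-block) stochastic block model: every within-block
#' pair is connected independently with probability `p_intra`, every
#' between-block pair with `p_inter`. Optional per-node degree weights turn
#' it into a degree-corrected SBM (edge probability scaled by the product
#' of endpoint weights, clipped to `[0, 1]`); all-ones weights reduce
#' exactly to the plain SBM.
#'
#' @param n_nodes Number of nodes.
#' @param block_proportions Positive vector summing to 1 (default equal
#'   two blocks).
#' @param p_intra,p_inter Within- / between-block edge probabilities.
#' @param degree_correction Optional per-node expected-degree weights
#'   (length `n_nodes`), or a single function applied to generate them.
#' @param seed Integer seed.
#' @return A `sbm_spec` list.
#' @export
sbm_spec <- function(n_nodes = 200, block_proportions = c(0.5, 0.5),
                     p_intra = 0.3, p_inter = 0.1,
                     degree_correction = NULL, seed = 1) {
  stopifnot(n_nodes >= 2, all(block_proportions > 0),
            abs(sum(block_proportions) - 1) < 1e-8,
            p_intra >= 0, p_intra <= 1, p_inter >= 0, p_inter <= 1)
  if (!is.null(degree_correction) && !is.function(degree_correction)) {
    stopifnot(length(degree_correction) == n_nodes, all(degree_correction >= 0))
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 block_proportions = block_proportions,
                 p_intra = p_intra, p_inter = p_inter,
                 degree_correction = degree_correction,
                 seed = as.integer(seed)),
            class = "sbm_spec")
}

block_sizes <- function(spec) {
  k <- length(spec$block_proportions)
  sizes <- floor(spec$block_proportions * spec$n_nodes)
  # distribute the rounding remainder over the first blocks
  rem <- spec$n_nodes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  as.integer(sizes)
}

#' Generate a stochastic block model graph
#'
#' @param spec An [sbm_spec()] (without degree correction).
#' @return List with `graph` (igraph, undirected, no self-loops) and
#'   `labels` (integer planted block per node).
#' @export
generate_sbm <- function(spec) {
  spec$degree_correction <- NULL
  generate_dcsbm(spec)
}

#' Generate a degree-corrected stochastic block model graph
#'
#' Each pair (i, j) is an edge with probability
#' `min(1, theta_i * theta_j * p_block(i, j))`; with all `theta = 1` this
#' is the plain SBM. A node with weight 0 is isolated.
#'
#' @param spec An [sbm_spec()]; `degree_correction` supplies the weights
#'   (vector, or a function of `n_nodes`).
#' @return List with `graph` and planted `labels`.
#' @export
generate_dcsbm <- function(spec) {
  stopifnot(inherits(spec, "sbm_spec"))
  n <- spec$n_nodes
  sizes <- block_sizes(spec)
  labels <- rep(seq_along(sizes), sizes)
  theta <- spec$degree_correction
  if (is.function(theta)) theta <- with_seed(derive_seed(spec$seed, "theta"), theta(n))
  pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  p <- ifelse(labels[pairs[, 1]] == labels[pairs[, 2]], spec$p_intra, spec$p_inter)
  if (!is.null(theta)) {
    p <- pmin(1, theta[pairs[, 1]] * theta[pairs[, 2]] * p)
  }
  keep <- with_seed(spec$seed, stats::runif(nrow(pairs)) < p)
  el <- pairs[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  list(graph = g, labels = stats::setNames(labels, igraph::V(g)$name))
}

#' Clustering-coefficient features of a graph
#'
#' The local clustering coefficient of a node is its closed-triangle to
#' wedge ratio (0 for nodes of degree < 2). The feature vector used by the
#' clusterability classifier is the mean and standard deviation of this
#' distribution over all nodes; the variance is available for the
#' alternative parameterization.
#'
#' @param graph An `igraph` graph (or `pag_network`).
#' @param spread `"sd"` (default) or `"var"`.
#' @return Named numeric vector `c(cc_mean, cc_spread)`.
#' @export
cc_features <- function(graph, spread = c("sd", "var")) {
  spread <- match.arg(spread)
  if (inherits(graph, "pag_network")) graph <- as_igraph(graph)
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  s <- if (length(cc) > 1) stats::sd(cc) else 0
  if (spread == "var") s <- s^2
  c(cc_mean = mean(cc), cc_spread = s)
}

# extended feature set for the CDI-beta variant: clustering-coefficient
# summary plus density, degree distribution shape, global transitivity,
# degree assortativity and largest-component fraction
graph_features_extended <- function(graph) {
  if (inherits(graph, "pag_network")) graph <- as_igraph(graph)
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  cc <- cc_features(graph)
  dens <- igraph::edge_density(graph)
  sk <- if (stats::sd(deg) > 0) {
    mean((deg - mean(deg))^3) / stats::sd(deg)^3
  } else 0
  assort <- suppressWarnings(igraph::assortativity_degree(graph))
  if (!is.finite(assort)) assort <- 0
  comp <- igraph::components(graph)
  trans <- igraph::transitivity(graph, type = "global")
  if (!is.finite(trans)) trans <- 0
  c(cc, density = dens, deg_mean = mean(deg), deg_sd = stats::sd(deg),
    deg_skew = sk, transitivity = trans, assortativity = assort,
    giant_frac = max(comp$csize) / n)
}

#' Label a graph as clusterable from planted-partition recovery
#'
#' Clusters the graph by spectral clustering with k set to the number of
#' planted blocks, scores the recovery with ARI, and binarizes at `tau`:
#' the graph is "clusterable" iff the planted partition is recovered with
#' ARI at least `tau`. The raw ARI is clipped to `[0, 1]`.
#'
#' @param graph An `igraph` graph.
#' @param planted_labels Integer vector of planted block labels.
#' @param tau ARI binarization threshold (default 0.7).
#' @param seed Seed for the spectral back-end.
#' @return List with `ari_raw` (clipped to `[0,1]`) and `label_bin` (0/1).
#' @export
label_graph <- function(graph, planted_labels, tau = 0.7, seed = 1) {
  k <- length(unique(planted_labels))
  pred <- spectral_partition(graph, k, seed = seed)
  a <- ari(unname(pred), unname(as.integer(planted_labels)))
  a <- min(max(a, 0), 1)
  list(ari_raw = a, label_bin = as.integer(a >= tau))
}

#' Build a clusterability training set from an SBM sweep
#'
#' Sweeps `p_intra` and `p_inter` over a grid (default 0.1 to 1.0 in steps
#' of 0.1), generates `replicates` graphs per cell, extracts features, and
#' labels each graph by planted-partition recovery ([label_graph()]).
#'
#' @param grid Probability grid for both axes.
#' @param replicates Graphs per (p_intra, p_inter) cell (default 10).
#' @param n_nodes Nodes per graph (default 200).
#' @param block_proportions Block proportions (default equal halves).
#' @param tau ARI binarization threshold (default 0.7).
#' @param features `"cc"` (mean/sd of the local clustering coefficient) or
#'   `"extended"` (CDI-beta feature set).
#' @param degree_correction Optional degree-correction generator (function
#'   of n) applied to every graph, for DC-SBM sweeps.
#' @param seed Sweep seed; every graph derives its own reproducible seed.
#' @return Object of class `cdi_training_set`: `X` (feature matrix), `y_raw`
#'   (ARI in `[0,1]`), `y_bin`, `tau`, and the `design` table.
#' @export
build_training_set <- function(grid = seq(0.1, 1.0, by = 0.1), replicates = 10,
                               n_nodes = 200, block_proportions = c(0.5, 0.5),
                               tau = 0.7, features = c("cc", "extended"),
                               degree_correction = NULL, seed = 1) {
  features <- match.arg(features)
  featfun <- if (features == "cc") cc_features else graph_features_extended
  cells <- expand.grid(p_intra = grid, p_inter = grid, rep = seq_len(replicates))
  X <- NULL; y_raw <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    gseed <- derive_seed(seed, paste("sbm", cells$p_intra[i], cells$p_inter[i],
                                     cells$rep[i]))
    spec <- sbm_spec(n_nodes, block_proportions, cells$p_intra[i],
                     cells$p_inter[i], degree_correction, seed = gseed)
    sbm <- generate_dcsbm(spec)
    f <- featfun(sbm$graph)
    if (is.null(X)) X <- matrix(0, nrow(cells), length(f),
                                dimnames = list(NULL, names(f)))
    X[i, ] <- f
    y_raw[i] <- label_graph(sbm$graph, sbm$labels, tau = tau,
                            seed = derive_seed(gseed, "label"))$ari_raw
  }
  structure(list(X = X, y_raw = y_raw, y_bin = as.integer(y_raw >= tau),
                 tau = tau, design = cells, features = features, seed = seed),
            class = "cdi_training_set")
}

#' @export
print.cdi_training_set <- function(x, ...) {
  cat(sprintf("<cdi_training_set> %d graphs, %d features (%s), %.0f%% clusterable (tau=%.2f)\n",
              nrow(x$X), ncol(x$X), x$features, 100 * mean(x$y_bin), x$tau))
  invisible(x)
}
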