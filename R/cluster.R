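#' Cluster PAG embeddings or networks
#'
#' One front door over the clustering back-ends. Embedding input
#' (`embedding_matrix`) supports `kmeans`, `agglomerative` (Ward linkage on
#' Euclidean distances) and `hdbscan`; graph input (`pag_network` or
#' `igraph`) supports `spectral`, `louvain` and `girvan_newman`. Applying a
#' graph method to an embedding (or vice versa) is a type error.
#'
#' `hdbscan` may label insufficiently dense points as noise (`-1`);
#' `louvain` chooses its own number of communities; `girvan_newman` removes
#' edges by betweenness and is cut at the first split reaching `k`
#' communities.
#'
#' @param x An `embedding_matrix`, `pag_network`, or `igraph` graph.
#' @param method One of `"kmeans"`, `"agglomerative"`, `"hdbscan"`,
#'   `"spectral"`, `"louvain"`, `"girvan_newman"`.
#' @param k Number of clusters (required by kmeans / agglomerative /
#'   spectral / girvan_newman).
#' @param min_cluster_size HDBSCAN minimum cluster membership (default 5).
#' @param seed Seed for the stochastic back-ends (k-means initialization,
#'   Louvain); results are deterministic given the seed.
#' @return Object of class `pag_clustering`: `labels` (named integer
#'   vector, `-1` = noise), `k_effective` (number of non-noise clusters),
#'   `method`, `params`, `seed`.
#' @export
cluster_pags <- function(x, method = c("kmeans", "agglomerative", "hdbscan",
                                       "spectral", "louvain", "girvan_newman"),
                         k = NULL, min_cluster_size = 5, seed = 1) {
  method <- match.arg(method)
  graph_methods <- c("spectral", "louvain", "girvan_newman")
  is_graph <- inherits(x, "pag_network") || inherits(x, "igraph")
  is_emb <- inherits(x, "embedding_matrix")
  if (!is_graph && !is_emb) {
    stop("x must be an embedding_matrix, pag_network, or igraph", call. = FALSE)
  }
  if (method %in% graph_methods && !is_graph) {
    stop(method, " operates on the graph form, not on embeddings", call. = FALSE)
  }
  if (!(method %in% graph_methods) && !is_emb) {
    stop(method, " operates on embeddings, not on the graph form", call. = FALSE)
  }
  needs_k <- method %in% c("kmeans", "agglomerative", "spectral", "girvan_newman")
  if (needs_k) {
    if (is.null(k)) stop(method, " requires k", call. = FALSE)
    n <- if (is_emb) nrow(x$vectors) else
      igraph::vcount(if (inherits(x, "igraph")) x else as_igraph(x))
    if (k > n) stop(sprintf("k = %d exceeds the %d points available", k, n),
                    call. = FALSE)
  }
  labels <- switch(method,
    kmeans = {
      cl <- with_seed(seed, stats::kmeans(x$vectors, centers = k, nstart = 10))
      stats::setNames(as.integer(cl$cluster), x$row_ids)
    },
    agglomerative = {
      hc <- stats::hclust(stats::dist(x$vectors), method = "ward.D2")
      stats::setNames(as.integer(stats::cutree(hc, k = k)), x$row_ids)
    },
    hdbscan = {
      hdbscan_labels(x$vectors, min_cluster_size = min_cluster_size)
    },
    spectral = {
      g <- if (inherits(x, "igraph")) x else as_igraph(x)
      stats::setNames(spectral_partition(g, k, seed = seed),
                      igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))))
    },
    louvain = {
      g <- if (inherits(x, "igraph")) x else as_igraph(x)
      cl <- with_seed(seed, igraph::cluster_louvain(g))
      stats::setNames(as.integer(igraph::membership(cl)),
                      igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))))
    },
    girvan_newman = {
      g <- if (inherits(x, "igraph")) x else as_igraph(x)
      # edge betweenness treats weights as distances, the wrong semantics
      # for -log10(p) affinities; run it on the unweighted skeleton
      cl <- igraph::cluster_edge_betweenness(g, weights = NA)
      stats::setNames(as.integer(igraph::cut_at(cl, no = k)),
                      igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))))
    })
  k_eff <- length(unique(labels[labels != -1L]))
  structure(list(labels = labels, k_effective = k_eff, method = method,
                 params = list(k = k, min_cluster_size = min_cluster_size),
                 seed = seed),
            class = "pag_clustering")
}

#' @export
print.pag_clustering <- function(x, ...) {
  noise <- sum(x$labels == -1L)
  cat(sprintf("<pag_clustering> %s: %d items in %d cluster(s)%s\n",
              x$method, length(x$labels), x$k_effective,
              if (noise) sprintf(", %d noise", noise) else ""))
  invisible(x)
}

# Spectral partition of a (possibly weighted) graph. Works on the symmetric
# normalized adjacency M = D^{-1/2} A D^{-1/2} and feeds k-means the k
# eigenvectors of largest |eigenvalue|: large positive eigenvalues capture
# assortative (community) block structure, large negative ones capture
# disassortative (bipartite-like) block structure, so both kinds of planted
# partition are recoverable. Rows of the spectral embedding are normalized
# to the unit sphere before k-means.
spectral_partition <- function(g, k, seed = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr =
    if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL))
  n <- nrow(A)
  d <- rowSums(A)
  dh <- ifelse(d > 0, 1 / sqrt(d), 0)
  M <- A * (dh %o% dh)
  ev <- eigen(M, symmetric = TRUE)
  pick <- order(abs(ev$values), decreasing = TRUE)[seq_len(k)]
  U <- ev$vectors[, pick, drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  cl <- with_seed(seed, stats::kmeans(U, centers = k, nstart = 10))
  as.integer(cl$cluster)
}

check_label_alignment <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) {
      stop("label vectors differ in length and carry no names", call. = FALSE)
    }
    return(list(a = a, b = b))
  }
  if (!setequal(names(a), names(b))) {
    off <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("label key sets differ, e.g. ", paste(utils::head(off, 3), collapse = ", "),
         call. = FALSE)
  }
  list(a = a, b = b[names(a)])
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pairwise agreement computed from the contingency table:
#' `(sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E` the expected index under random label permutation. Ranges over
#' `[-1, 1]`; random labelings score about 0, identical partitions exactly
#' 1. Invariant to label renaming; symmetric. Noise labels (`-1`) are
#' treated as an ordinary cluster.
#'
#' @param a,b Label vectors; if named, keys are matched (and must agree).
#' @return The ARI.
#' @export
ari <- function(a, b) {
  al <- check_label_alignment(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  if (n < 2) return(1)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical-by-pairs
  (sij - expected) / denom
}

#' Normalized Mutual Information between two partitions
#'
#' Mutual information of the label contingency table normalized by the
#' arithmetic mean of the two label entropies. Bounded in `[0, 1]`;
#' identical partitions score 1, independent ones 0. If either partition is
#' constant (zero entropy) the score is 0 by convention. Symmetric and
#' invariant to label renaming.
#'
#' @param a,b Label vectors; if named, keys are matched (and must agree).
#' @return The NMI.
#' @export
nmi <- function(a, b) {
  al <- check_label_alignment(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (hx == 0 || hy == 0) return(0)
  # equivalent partitions (a one-to-one block match) score exactly 1
  if (all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)) return(1)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  mi / ((hx + hy) / 2)
}

#' Write cluster labels as a two-column TSV (id, label)
#' @param clustering A `pag_clustering` (or named label vector).
#' @param path Output path.
#' @export
write_labels_tsv <- function(clustering, path) {
  labels <- if (inherits(clustering, "pag_clustering")) clustering$labels else clustering
  writeLines(c("id\tlabel", paste(names(labels), labels, sep = "\t")), path)
  invisible(path)
}
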