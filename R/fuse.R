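#' Fuse graph and semantic embeddings
#'
#' Blend mode computes the convex combination
#' `D_f = (1 - alpha) * D_g + alpha * D_s` row by row; `alpha = 0`
#' reproduces the graph embedding exactly and `alpha = 1` the semantic one.
#' Concat mode returns `[sqrt(1 - alpha) * D_g , sqrt(alpha) * D_s]`, whose
#' inner products are the same alpha-weighted combination of the two
#' sources' inner products.
#'
#' @param d_g Graph `embedding_matrix`.
#' @param d_s Semantic `embedding_matrix`; must carry identical, identically
#'   ordered row ids (blend mode additionally requires equal dimension).
#' @param alpha Mixing weight in `[0, 1]`; larger favors the semantic space.
#' @param mode `"blend"` (default) or `"concat"`.
#' @param normalize L2-normalize the fused rows afterwards (default FALSE).
#' @return An `embedding_matrix` with `source = "fused"`.
#' @export
fuse <- function(d_g, d_s, alpha, mode = c("blend", "concat"),
                 normalize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(d_g, "embedding_matrix"), inherits(d_s, "embedding_matrix"))
  if (length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  if (!identical(d_g$row_ids, d_s$row_ids)) {
    off <- which(d_g$row_ids != d_s$row_ids[seq_along(d_g$row_ids)])[1]
    detail <- if (length(d_g$row_ids) != length(d_s$row_ids)) {
      sprintf("row counts differ (%d vs %d)", length(d_g$row_ids), length(d_s$row_ids))
    } else {
      sprintf("first mismatch at row %d: '%s' vs '%s'",
              off, d_g$row_ids[off], d_s$row_ids[off])
    }
    stop("embeddings are not aligned: ", detail, call. = FALSE)
  }
  if (mode == "blend") {
    if (d_g$dim != d_s$dim) {
      stop(sprintf("blend mode requires equal dimensions (%d vs %d); PCA-align first",
                   d_g$dim, d_s$dim), call. = FALSE)
    }
    v <- (1 - alpha) * d_g$vectors + alpha * d_s$vectors
  } else {
    v <- cbind(sqrt(1 - alpha) * d_g$vectors, sqrt(alpha) * d_s$vectors)
    colnames(v) <- NULL
  }
  out <- embedding_matrix(v, d_g$row_ids, source = "fused")
  if (normalize) out <- l2_normalize(out)
  out
}

#' Grid search for the fusion weight alpha
#'
#' For each alpha on the grid, fuses the two embeddings, clusters the
#' members of every benchmark group (with k = the group's number of
#' parents), and scores the partition against the ground-truth parent
#' labels. The alpha maximizing mean ARI wins; ties break toward the larger
#' (more semantic) alpha.
#'
#' @param d_g,d_s Aligned graph and semantic embeddings covering every
#'   group member.
#' @param groups List of benchmark groups (see [enumerate_pairs()] /
#'   [make_fixture()]); each has `members` and `labels`.
#' @param grid Ordered vector of alpha values (default 0, 0.1, ..., 1).
#' @param method Clustering back-end for the evaluation (default
#'   agglomerative, the most reliable back-end on ontology benchmarks).
#' @param mode Fusion mode passed to [fuse()].
#' @param seed Seed for the clustering back-end.
#' @return List with `best_alpha` and `score_table` (data frame of alpha,
#'   mean_ari, mean_nmi).
#' @export
grid_search_alpha <- function(d_g, d_s, groups, grid = seq(0, 1, by = 0.1),
                              method = "agglomerative", mode = "blend",
                              seed = 1) {
  stopifnot(length(grid) >= 1)
  grid <- sort(unique(grid))
  rows <- lapply(grid, function(a) {
    fused <- fuse(d_g, d_s, alpha = a, mode = mode)
    sc <- vapply(groups, function(g) {
      emb <- subset_embedding(fused, g$members)
      k <- length(unique(g$labels))
      cl <- cluster_pags(emb, method = method, k = k, seed = seed)
      truth <- stats::setNames(g$labels, g$members)
      c(ari(cl$labels, truth), nmi(cl$labels, truth))
    }, numeric(2))
    data.frame(alpha = a, mean_ari = mean(sc[1, ]), mean_nmi = mean(sc[2, ]))
  })
  tab <- do.call(rbind, rows)
  best <- max(tab$alpha[tab$mean_ari == max(tab$mean_ari)])
  list(best_alpha = best, score_table = tab)
}
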