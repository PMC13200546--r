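#' Consensus matrix over resampled clustering runs
#'
#' Runs the inner clusterer on `n_resamples` random subsamples of the rows
#' and records, for every pair of items, the fraction of co-sampled runs in
#' which they landed in the same cluster. Pairs never co-sampled are
#' imputed 0 (their count is reported in `attr(, "never_cosampled")`).
#'
#' @param data An `embedding_matrix` (or plain numeric matrix).
#' @param k Number of clusters for the inner clusterer.
#' @param n_resamples Number of subsampled runs (>= 2; default 100).
#' @param subsample_fraction Fraction of rows per run (default 0.8).
#' @param clusterer Inner clusterer: `"hclust"` (Ward linkage, the consensus
#'   clustering canon) or `"kmeans"`.
#' @param seed Seed controlling the subsampling and inner clusterer.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
consensus_matrix <- function(data, k, n_resamples = 100,
                             subsample_fraction = 0.8,
                             clusterer = c("hclust", "kmeans"), seed = 1) {
  clusterer <- match.arg(clusterer)
  X <- if (inherits(data, "embedding_matrix")) data$vectors else as.matrix(data)
  stopifnot(n_resamples >= 2, subsample_fraction > 0, subsample_fraction <= 1)
  n <- nrow(X)
  m <- max(2L, floor(subsample_fraction * n))
  co <- matrix(0, n, n); cnt <- matrix(0, n, n)
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      Xi <- X[idx, , drop = FALSE]
      cl <- if (clusterer == "hclust") {
        stats::cutree(stats::hclust(stats::dist(Xi), method = "ward.D2"),
                      k = min(k, m))
      } else {
        stats::kmeans(Xi, centers = min(k, m), nstart = 1)$cluster
      }
      cnt[idx, idx] <- cnt[idx, idx] + 1
      for (lab in unique(cl)) {
        mem <- idx[cl == lab]
        co[mem, mem] <- co[mem, mem] + 1
      }
    }
  })
  never <- sum(cnt[upper.tri(cnt)] == 0)
  M <- ifelse(cnt > 0, co / cnt, 0)
  diag(M) <- 1
  dimnames(M) <- list(rownames(X), rownames(X))
  attr(M, "never_cosampled") <- never
  M
}

# area under the empirical CDF of the off-diagonal consensus values,
# integrated over [0, 1]
consensus_cdf_area <- function(M) {
  v <- M[upper.tri(M)]
  xs <- sort(unique(c(0, v, 1)))
  F <- stats::ecdf(v)
  sum(F(xs[-length(xs)]) * diff(xs))
}

# proportion of ambiguous consensus values (strictly between lo and hi)
consensus_pac <- function(M, lo = 0.1, hi = 0.9) {
  v <- M[upper.tri(M)]
  mean(v > lo & v < hi)
}

#' Consensus profile across a range of cluster counts
#'
#' Computes the consensus matrix, the area under the consensus-value CDF
#' and its relative change (delta area) for every candidate k, then selects
#' the cluster count at the onset of the CDF plateau (see [select_k()]).
#'
#' @inheritParams consensus_matrix
#' @param k_range Candidate cluster counts (>= 2 values).
#' @param stability_tolerance Tie margin for the plateau rule (default 0.05).
#' @return Object of class `consensus_profile`: `k_range`, `consensus`
#'   (list of matrices), `cdf_area`, `delta_area`, `pac`, `selected_k`,
#'   `no_structure` flag.
#' @export
consensus_profile <- function(data, k_range = 2:6, n_resamples = 100,
                              subsample_fraction = 0.8,
                              clusterer = "hclust",
                              stability_tolerance = 0.05, seed = 1) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(length(k_range) >= 2)
  mats <- lapply(k_range, function(k)
    consensus_matrix(data, k, n_resamples, subsample_fraction, clusterer,
                     seed = derive_seed(seed, paste0("consensus-k", k))))
  area <- vapply(mats, consensus_cdf_area, numeric(1))
  delta <- c(area[1], diff(area) / area[-length(area)])
  pac <- vapply(mats, consensus_pac, numeric(1))
  sel <- select_k_from_profile(k_range, delta, pac, stability_tolerance)
  structure(list(k_range = k_range, consensus = mats, cdf_area = area,
                 delta_area = delta, pac = pac, selected_k = sel$k,
                 no_structure = sel$no_structure),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile>\n")
  print(data.frame(k = x$k_range, cdf_area = round(x$cdf_area, 3),
                   delta_area = round(x$delta_area, 3), pac = round(x$pac, 3)))
  cat(sprintf("selected k = %d%s\n", x$selected_k,
              if (x$no_structure) " (no stable structure; floor of range)" else ""))
  invisible(x)
}

select_k_from_profile <- function(k_range, delta, pac, tol,
                                  structure_pac = 0.1) {
  if (all(pac > structure_pac)) {
    # no k reaches high consensus: the data carry no stable cluster
    # structure, so report the floor of the range
    return(list(k = k_range[1], no_structure = TRUE))
  }
  # plateau onset: the k after which the relative CDF-area gain collapses.
  # drop(k) = delta(k) - delta(k+1); beyond the scanned range the gain is
  # taken as zero. Candidates within the stability tolerance of the largest
  # drop tie-break toward the smaller k (favor the smaller k that already
  # achieves high consensus).
  drop <- delta - c(delta[-1], 0)
  cand <- which(drop >= max(drop) - tol)
  list(k = k_range[min(cand)], no_structure = FALSE)
}

#' Select the number of clusters from a consensus profile
#'
#' The CDF of consensus values gains area as long as added clusters carve
#' real structure; at the true cluster count the relative gain (delta area)
#' collapses. `select_k` returns the k at that plateau onset, preferring
#' the smaller k on near-ties; when no candidate k achieves high consensus
#' (all PAC values above 0.1) it returns the smallest k in the range and
#' flags the data as unstructured.
#'
#' @param profile A `consensus_profile`, or an embedding passed through to
#'   [consensus_profile()].
#' @param ... Passed to [consensus_profile()] when `profile` is raw data.
#' @return Selected k (integer).
#' @export
select_k <- function(profile, ...) {
  if (!inherits(profile, "consensus_profile")) {
    profile <- consensus_profile(profile, ...)
  }
  profile$selected_k
}
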