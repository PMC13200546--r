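# Hierarchical density-based clustering (HDBSCAN) on an embedding matrix.
#
# Steps: (1) core distance of every point = distance to its
# min_samples-th nearest other point; (2) mutual-reachability distance
# mr(i,j) = max(core_i, core_j, d_ij); (3) single-linkage hierarchy over mr
# (equivalent to the minimum spanning tree construction); (4) condense the
# dendrogram with the min_cluster_size rule (sub-threshold splits are
# "fall-outs", not new clusters); (5) extract the most stable antichain of
# clusters by excess of mass, where stability(C) = sum over points of
# (lambda_exit - lambda_birth) with lambda = 1/distance. Points never
# captured by a selected cluster are noise (-1). The root is never selected,
# so data with no sub-structure comes back as all noise.

hdbscan_labels <- function(X, min_cluster_size = 5, min_samples = min_cluster_size) {
  n <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(n))
  if (n < min_cluster_size) {
    return(stats::setNames(rep(-1L, n), ids))
  }
  D <- as.matrix(stats::dist(X))
  # k-th nearest *other* point; the self-distance 0 occupies the first slot
  core <- apply(D, 1, function(row) sort(row)[min(min_samples, n - 1) + 1])
  # mutual reachability
  MR <- pmax(D, outer(core, core, pmax))
  diag(MR) <- 0
  hc <- stats::hclust(stats::as.dist(MR), method = "single")

  # -- condense the merge tree ------------------------------------------
  merge <- hc$merge; height <- hc$height
  n_merges <- nrow(merge)
  lam <- function(h) 1 / max(h, 1e-12)
  members <- vector("list", n_merges)  # point indices under each merge node
  for (m in seq_len(n_merges)) {
    kids <- merge[m, ]
    pts <- integer(0)
    for (kid in kids) {
      pts <- c(pts, if (kid < 0) -kid else members[[kid]])
    }
    members[[m]] <- pts
  }

  # cluster records built during the top-down walk
  clus_parent <- integer(0)   # parent cluster id (0 = none / root's parent)
  clus_birth <- numeric(0)    # birth lambda
  clus_stab <- numeric(0)     # accumulated stability
  point_cluster <- integer(n) # condensed cluster each point fell out of
  point_lambda <- numeric(n)

  new_cluster <- function(parent, birth) {
    clus_parent[[length(clus_parent) + 1]] <<- parent
    clus_birth[[length(clus_birth) + 1]] <<- birth
    clus_stab[[length(clus_stab) + 1]] <<- 0
    length(clus_parent)
  }
  fall_out <- function(pts, cluster, lambda) {
    point_cluster[pts] <<- cluster
    point_lambda[pts] <<- lambda
    clus_stab[[cluster]] <<- clus_stab[[cluster]] +
      length(pts) * (min(lambda, 1e12) - clus_birth[[cluster]])
  }
  node_size <- function(kid) if (kid < 0) 1L else length(members[[kid]])
  node_points <- function(kid) if (kid < 0) -kid else members[[kid]]

  root_cluster <- new_cluster(0L, 0)
  # iterative stack walk from the root merge
  stack <- list(list(node = n_merges, cluster = root_cluster))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cluster
    h <- height[node]; l <- lam(h)
    kids <- merge[node, ]
    sizes <- c(node_size(kids[1]), node_size(kids[2]))
    big <- sizes >= min_cluster_size
    if (all(big)) {
      for (kid in kids) {
        child <- new_cluster(cl, l)
        if (kid < 0) {
          fall_out(-kid, child, l)  # unreachable: size >= min_cluster_size > 1
        } else {
          stack[[length(stack) + 1]] <- list(node = kid, cluster = child)
        }
      }
    } else {
      # sub-threshold children fall out of the current cluster at this level;
      # a single surviving big child continues as the same cluster
      for (i in 1:2) {
        kid <- kids[i]
        if (big[i]) {
          stack[[length(stack) + 1]] <- list(node = kid, cluster = cl)
        } else {
          fall_out(node_points(kid), cl, l)
        }
      }
    }
  }

  # -- excess-of-mass selection -----------------------------------------
  n_clus <- length(clus_parent)
  children <- split(seq_len(n_clus), clus_parent)
  selected <- rep(FALSE, n_clus)
  subtree_val <- numeric(n_clus)
  # process bottom-up (children always created after parents, so reverse order)
  for (cl in rev(seq_len(n_clus))) {
    kids <- children[[as.character(cl)]] %||% integer(0)
    kid_val <- sum(subtree_val[kids])
    if (cl == root_cluster) {
      subtree_val[cl] <- kid_val
    } else if (!length(kids) || clus_stab[cl] >= kid_val) {
      selected[cl] <- TRUE
      deselect <- kids
      while (length(deselect)) {
        selected[deselect] <- FALSE
        deselect <- unlist(lapply(deselect, function(d)
          children[[as.character(d)]] %||% integer(0)))
      }
      subtree_val[cl] <- clus_stab[cl]
    } else {
      subtree_val[cl] <- kid_val
    }
  }

  # -- labelling ---------------------------------------------------------
  # a point belongs to the selected ancestor (or self) of its record cluster
  sel_ancestor <- integer(n_clus)
  for (cl in seq_len(n_clus)) {
    a <- cl
    sel_ancestor[cl] <- 0L
    while (a != 0L) {
      if (selected[a]) { sel_ancestor[cl] <- a; break }
      a <- clus_parent[a]
    }
  }
  lab <- sel_ancestor[point_cluster]
  out <- rep(-1L, n)
  keep <- lab != 0L
  if (any(keep)) {
    out[keep] <- as.integer(factor(lab[keep]))
  }
  stats::setNames(out, ids)
}
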