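#' Parents eligible for a benchmark regime
#'
#' A term is an eligible benchmark parent when its direct is-a child count
#' c satisfies the regime bounds: `5 <= c < 10` for the small super-PAG
#' regime (`"SPAG_5_10"`), `10 <= c < 100` for the main regime
#' (`"SPAG_10_100"`). Bounds are inclusive below and exclusive above.
#'
#' @param dag An `ontology_dag`.
#' @param regime `"SPAG_10_100"` (default) or `"SPAG_5_10"`.
#' @return Character vector of eligible term ids (lexicographic order).
#' @export
eligible_parents <- function(dag, regime = c("SPAG_10_100", "SPAG_5_10")) {
  regime <- match.arg(regime)
  bounds <- regime_bounds(regime)
  ch <- term_children(dag)
  cnt <- lengths(ch)
  sort(names(cnt)[cnt >= bounds[1] & cnt < bounds[2]])
}

regime_bounds <- function(regime) {
  switch(regime, SPAG_5_10 = c(5L, 10L), SPAG_10_100 = c(10L, 100L),
         stop("unknown regime: ", regime, call. = FALSE))
}

#' Enumerate level-matched, parent-unique benchmark pairs
#'
#' Considers every unordered pair of eligible parents and keeps those that
#' are (i) level-matched: both lie at the same shortest-path depth from
#' `root` (for multi-parent terms the minimum depth is used); and
#' (ii) parent-unique: the two terms do not share an immediate parent.
#' The group's members are the direct children of exactly one of the two
#' parents (children under both are ambiguous and excluded), labeled by
#' parent index; pairs whose member counts fall outside the regime bounds
#' after exclusion are dropped. Ordering is deterministic (lexicographic by
#' the pair's ids).
#'
#' @param dag An `ontology_dag`.
#' @param regime Benchmark regime, see [eligible_parents()].
#' @param root Root term for depth computation.
#' @return List of `benchmark_group` objects: `parent_ids`, `members`,
#'   `labels` (1/2 = parent index), `regime`, `root_id`, `level`.
#' @export
enumerate_pairs <- function(dag, regime = "SPAG_10_100", root = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  root <- root %||% (if (length(dag$roots) == 1) dag$roots else
    stop("multiple roots; specify `root`", call. = FALSE))
  if (!root %in% dag$nodes) stop("root not in ontology: ", root, call. = FALSE)
  bounds <- regime_bounds(regime)
  elig <- eligible_parents(dag, regime)
  if (length(elig) < 2) return(list())
  depth <- term_depths(dag, root)
  ch <- term_children(dag, elig)
  pa <- term_parents(dag, elig)
  groups <- list()
  for (a in seq_len(length(elig) - 1)) {
    for (b in (a + 1):length(elig)) {
      ta <- elig[a]; tb <- elig[b]
      if (is.na(depth[ta]) || is.na(depth[tb]) || depth[ta] != depth[tb]) next
      if (length(intersect(pa[[ta]], pa[[tb]]))) next
      shared <- intersect(ch[[ta]], ch[[tb]])
      mem_a <- setdiff(ch[[ta]], shared)
      mem_b <- setdiff(ch[[tb]], shared)
      ok <- function(m) length(m) >= bounds[1] && length(m) < bounds[2]
      if (!ok(mem_a) || !ok(mem_b)) next
      groups[[length(groups) + 1]] <- structure(list(
        parent_ids = c(ta, tb),
        members = c(mem_a, mem_b),
        labels = c(rep(1L, length(mem_a)), rep(2L, length(mem_b))),
        regime = regime, root_id = root,
        level = unname(depth[ta])), class = "benchmark_group")
    }
  }
  groups
}

#' @export
print.benchmark_group <- function(x, ...) {
  cat(sprintf("<benchmark_group> %s vs %s (level %d, %d + %d members, %s)\n",
              x$parent_ids[1], x$parent_ids[2], x$level,
              sum(x$labels == 1L), sum(x$labels == 2L), x$regime))
  invisible(x)
}

#' Run the fusion pipeline on one benchmark group
#'
#' The group's member PAGs are cut out of the collection, the m-type
#' network is rebuilt over them (against the full collection universe),
#' graph and semantic embeddings are computed and fused at `alpha`, the
#' fused space is clustered with k = the group's number of parents, and
#' the partition is scored against the parent labels.
#'
#' @param group A `benchmark_group`.
#' @param collection A `pag_collection` containing every member.
#' @param descriptions Named id -> text vector (defaults to the
#'   collection's own descriptions).
#' @param alpha Fusion weight (default 0.8, the semantic-leaning optimum).
#' @param method Clustering back-end (default `"agglomerative"`).
#' @param walk Walk configuration; the default shortens the walks to match
#'   small benchmark graphs.
#' @param encoder Text encoder port (default offline hash encoder).
#' @param seed Seed for embedding and clustering.
#' @return List with `ari`, `nmi`, and the `clustering`.
#' @export
evaluate_group <- function(group, collection, descriptions = NULL,
                           alpha = 0.8, method = "agglomerative",
                           walk = walk_config(dim = 16, walk_length = 20,
                                              walks_per_node = 10),
                           encoder = hash_text_encoder(), seed = 1) {
  stopifnot(inherits(group, "benchmark_group"),
            inherits(collection, "pag_collection"))
  ids <- group$members
  missing <- setdiff(ids, pag_ids(collection))
  if (length(missing)) {
    stop("collection lacks member PAG(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  sub <- pag_collection(collection$pags[ids], universe = collection$universe)
  net <- build_mtype_network(sub)
  walk$seed <- derive_seed(seed, "embed")
  d_g <- embed_graph(net, walk)
  texts <- (descriptions %||% collection_descriptions(collection))[ids]
  texts[is.na(texts)] <- ""
  names(texts) <- ids
  d_s_raw <- encode_descriptions(texts, encoder)
  target <- min(walk$dim, length(ids) - 1, d_s_raw$dim)
  d_s <- suppressWarnings(pca_align(d_s_raw, target))
  if (target < walk$dim) {  # pad so blend dimensions agree on tiny groups
    pad <- matrix(0, length(ids), walk$dim - target)
    d_s <- embedding_matrix(cbind(d_s$vectors, pad), ids, "semantic", TRUE)
  }
  d_g <- subset_embedding(d_g, ids)
  fused <- fuse(d_g, d_s, alpha = alpha)
  k <- length(unique(group$labels))
  cl <- cluster_pags(fused, method = method, k = k,
                     seed = derive_seed(seed, "cluster"))
  truth <- stats::setNames(group$labels, ids)
  list(ari = ari(cl$labels, truth), nmi = nmi(cl$labels, truth),
       clustering = cl)
}

#' Repeated random-sampling evaluation protocol
#'
#' In each of `n_trials` independent trials, `categories_per_trial`
#' categories are drawn uniformly at random, up to `max_per_category`
#' items are sampled without replacement from each, and the sampled
#' embedding rows are clustered (agglomerative, k = number of drawn
#' categories) and scored against the category labels. Per-trial results
#' are retained for full reproducibility.
#'
#' @param embedding An `embedding_matrix` covering all labeled items.
#' @param labels Named category labels for (a superset of) the embedding
#'   rows.
#' @param n_trials Number of trials (default 300).
#' @param categories_per_trial Categories drawn per trial (default 2).
#' @param max_per_category Maximum items sampled per category (default 20).
#' @param method Clustering back-end (default `"agglomerative"`).
#' @param seed Protocol seed.
#' @return List with `summary` (mean and sd of ARI and NMI) and `trials`
#'   (one row per trial).
#' @export
repeated_sampling_protocol <- function(embedding, labels, n_trials = 300,
                                       categories_per_trial = 2,
                                       max_per_category = 20,
                                       method = "agglomerative", seed = 1) {
  stopifnot(inherits(embedding, "embedding_matrix"))
  labels <- labels[names(labels) %in% embedding$row_ids]
  cats <- split(names(labels), unname(labels))
  if (length(cats) < categories_per_trial) {
    stop("fewer categories than categories_per_trial", call. = FALSE)
  }
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    tseed <- derive_seed(seed, paste0("trial", t))
    drawn <- with_seed(tseed, {
      chosen <- sample(names(cats), categories_per_trial)
      lapply(chosen, function(cat)
        sample(cats[[cat]], min(max_per_category, length(cats[[cat]]))))
    })
    ids <- unlist(drawn)
    truth <- stats::setNames(rep(seq_along(drawn), lengths(drawn)), ids)
    emb <- subset_embedding(embedding, ids)
    cl <- cluster_pags(emb, method = method, k = categories_per_trial,
                       seed = derive_seed(tseed, "cluster"))
    rows[[t]] <- data.frame(trial = t, n = length(ids),
                            ari = ari(cl$labels, truth),
                            nmi = nmi(cl$labels, truth))
  }
  trials <- do.call(rbind, rows)
  list(summary = c(ari_mean = mean(trials$ari), ari_sd = stats::sd(trials$ari),
                   nmi_mean = mean(trials$nmi), nmi_sd = stats::sd(trials$nmi)),
       trials = trials)
}
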