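#' Upper-tail hypergeometric overlap p-value
#'
#' Significance of observing an overlap of at least `k` genes between a set
#' of size `n_a` and a set of size `n_b` drawn from a universe of `N` genes:
#' `P(X >= k)` for `X ~ Hypergeometric(N, n_a, n_b)`. This is the one-sided
#' enrichment tail; an overlap of zero always has p-value 1.
#'
#' @param k Observed overlap count.
#' @param n_a,n_b Sizes of the two gene sets.
#' @param N Universe (background) size.
#' @return Probability in (0, 1].
#' @export
hypergeometric_overlap_pvalue <- function(k, n_a, n_b, N) {
  if (any(c(k, n_a, n_b, N) < 0) || n_a > N || n_b > N) {
    stop("invalid hypergeometric configuration: need 0 <= n_a, n_b <= N",
         call. = FALSE)
  }
  if (k > min(n_a, n_b) || k < max(0, n_a + n_b - N)) {
    stop(sprintf("overlap k=%d outside feasible range [%d, %d]",
                 k, max(0, n_a + n_b - N), min(n_a, n_b)), call. = FALSE)
  }
  # P(X >= k); phyper's upper tail is strict, hence k - 1
  p <- stats::phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Build the co-membership (m-type) PAG-PAG network
#'
#' Every unordered pair of PAGs whose gene overlap reaches `min_overlap`
#' and whose hypergeometric enrichment p-value is at most `p_cutoff` gets an
#' undirected edge weighted by `-log10(p)`. Isolated PAGs are retained as
#' nodes, so the network always covers the full collection.
#'
#' @param collection A [pag_collection()].
#' @param p_cutoff Maximum p-value for an edge (default 0.05).
#' @param min_overlap Minimum shared-gene count for an edge (default 1).
#' @param universe_size Background size `N`; defaults to the size of the
#'   collection's universe.
#' @return Object of class `pag_network`: `node_ids`, `edges` (data frame
#'   with columns i, j, overlap, p_value, weight), `universe_size`.
#' @export
build_mtype_network <- function(collection, p_cutoff = 0.05, min_overlap = 1,
                                universe_size = NULL) {
  stopifnot(inherits(collection, "pag_collection"))
  ids <- pag_ids(collection)
  N <- universe_size %||% length(collection$universe)
  genes <- lapply(collection$pags, function(p) p$genes)
  sizes <- lengths(genes)
  if (any(sizes > N)) stop("universe_size smaller than a member set", call. = FALSE)
  n <- length(ids)
  res <- list(); m <- 0L
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        k <- length(intersect(genes[[a]], genes[[b]]))
        if (k < min_overlap) next
        p <- hypergeometric_overlap_pvalue(k, sizes[a], sizes[b], N)
        if (p > p_cutoff) next
        m <- m + 1L
        res[[m]] <- data.frame(i = ids[a], j = ids[b], overlap = k,
                               p_value = p, weight = -log10(p),
                               stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (m) do.call(rbind, res) else
    data.frame(i = character(0), j = character(0), overlap = integer(0),
               p_value = numeric(0), weight = numeric(0))
  pag_network(ids, edges, N)
}

#' Construct a PAG network from parts
#'
#' Mostly internal; [build_mtype_network()] is the usual entry point.
#'
#' @param node_ids Character vector of node ids.
#' @param edges Data frame with columns `i`, `j`, `overlap`, `p_value`,
#'   `weight`.
#' @param universe_size Background size used for the edge tests.
#' @return A `pag_network`.
#' @export
pag_network <- function(node_ids, edges, universe_size) {
  stopifnot(!anyDuplicated(node_ids))
  if (nrow(edges)) {
    stopifnot(all(edges$i %in% node_ids), all(edges$j %in% node_ids),
              all(edges$i != edges$j), all(edges$weight >= 0))
  }
  structure(list(node_ids = as.character(node_ids), edges = edges,
                 universe_size = universe_size),
            class = "pag_network")
}

#' @export
print.pag_network <- function(x, ...) {
  cat(sprintf("<pag_network> %d nodes, %d edges (universe N=%d)\n",
              length(x$node_ids), nrow(x$edges), x$universe_size))
  invisible(x)
}

#' Drop edges below a weight cutoff
#'
#' Keeps every edge with `weight >= min_weight`; nodes are never dropped,
#' so filtering can only disconnect, not shrink, the network.
#'
#' @param net A `pag_network`.
#' @param min_weight Minimum `-log10(p)` edge weight to keep.
#' @return A filtered `pag_network`.
#' @export
threshold_network <- function(net, min_weight) {
  stopifnot(inherits(net, "pag_network"))
  pag_network(net$node_ids, net$edges[net$edges$weight >= min_weight, , drop = FALSE],
              net$universe_size)
}

#' Convert a PAG network to an igraph object
#'
#' @param net A `pag_network`.
#' @return Undirected `igraph` graph with a `weight` edge attribute; all
#'   nodes present, including isolated ones.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "pag_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("i", "j", "weight")], directed = FALSE,
    vertices = net$node_ids)
}

#' Write a network as a weighted edge-list TSV
#'
#' Columns: i, j, overlap, p_value, weight.
#' @param net A `pag_network`.
#' @param path Output path.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network written by [write_network_tsv()]
#' @param path Edge-list TSV path.
#' @param node_ids Full node set (isolated nodes are not recoverable from the
#'   edge list alone); defaults to the ids present in the edges.
#' @param universe_size Background size; defaults to NA.
#' @return A `pag_network`.
#' @export
read_network_tsv <- function(path, node_ids = NULL, universe_size = NA_integer_) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "integer", "numeric", "numeric"))
  pag_network(node_ids %||% unique(c(edges$i, edges$j)), edges, universe_size)
}

#' Export a network as GraphML
#' @param net A `pag_network`.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
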