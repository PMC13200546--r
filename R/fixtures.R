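#' Specification for synthetic pipeline fixtures
#'
#' Describes a synthetic ontology + gene-set collection + description table
#' with controlled graph signal (gene overlap within vs between parents)
#' and semantic signal (parent-specific vs shared vocabulary), emulating
#' the statistical structure of ontology-derived benchmark groups. Member
#' gene sets are constructed so the within-parent and between-parent
#' overlap fractions are met exactly: all children share a global core of
#' `round(between * genes_per_child)` genes, children of the same parent
#' additionally share a parent core up to `round(within * genes_per_child)`
#' genes, and the remainder of each child is private.
#'
#' @param n_parents Number of parent terms (clusters).
#' @param children_per_parent Length-2 range of children per parent.
#' @param genes_per_child Genes per child set.
#' @param within_parent_gene_overlap Pairwise overlap fraction between
#'   same-parent children, in `[0, 1]`.
#' @param between_parent_gene_overlap Pairwise overlap fraction between
#'   different-parent children; must not exceed the within fraction.
#' @param vocabulary_per_parent Parent-specific vocabulary size.
#' @param description_length Words per description.
#' @param shared_vocab_fraction Fraction of description words drawn from a
#'   globally shared vocabulary (1 = no semantic signal).
#' @param seed Integer seed; generation is deterministic.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_parents = 2, children_per_parent = c(10, 15),
                         genes_per_child = 50,
                         within_parent_gene_overlap = 0.8,
                         between_parent_gene_overlap = 0.0,
                         vocabulary_per_parent = 40,
                         description_length = 30,
                         shared_vocab_fraction = 0.0, seed = 1) {
  stopifnot(n_parents >= 1, length(children_per_parent) == 2,
            children_per_parent[1] >= 2,
            children_per_parent[2] >= children_per_parent[1],
            genes_per_child >= 1,
            within_parent_gene_overlap >= 0, within_parent_gene_overlap <= 1,
            between_parent_gene_overlap >= 0, between_parent_gene_overlap <= 1,
            shared_vocab_fraction >= 0, shared_vocab_fraction <= 1)
  if (between_parent_gene_overlap > within_parent_gene_overlap) {
    stop("between-parent overlap cannot exceed within-parent overlap",
         call. = FALSE)
  }
  structure(list(n_parents = as.integer(n_parents),
                 children_per_parent = as.integer(children_per_parent),
                 genes_per_child = as.integer(genes_per_child),
                 within_parent_gene_overlap = within_parent_gene_overlap,
                 between_parent_gene_overlap = between_parent_gene_overlap,
                 vocabulary_per_parent = as.integer(vocabulary_per_parent),
                 description_length = as.integer(description_length),
                 shared_vocab_fraction = shared_vocab_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Named fixture presets
#'
#' `"clusterable"`: strong graph and semantic signal (high within-parent
#' overlap, disjoint vocabularies). `"no_signal"`: within equals between
#' and fully shared vocabulary, so no pipeline should recover the parents.
#' `"graph_only"`: overlap separates parents but vocabulary is fully
#' shared. `"semantic_only"`: vocabulary separates parents but overlap does
#' not.
#'
#' @param preset Preset name.
#' @param seed Seed forwarded to the spec.
#' @return A `fixture_spec`.
#' @export
fixture_preset <- function(preset = c("clusterable", "no_signal",
                                      "graph_only", "semantic_only"),
                           seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    clusterable = fixture_spec(seed = seed),
    no_signal = fixture_spec(within_parent_gene_overlap = 0.3,
                             between_parent_gene_overlap = 0.3,
                             shared_vocab_fraction = 1.0, seed = seed),
    graph_only = fixture_spec(shared_vocab_fraction = 1.0, seed = seed),
    semantic_only = fixture_spec(within_parent_gene_overlap = 0.3,
                                 between_parent_gene_overlap = 0.3,
                                 shared_vocab_fraction = 0.0, seed = seed))
}

#' Generate a synthetic ontology, gene-set collection and descriptions
#'
#' Builds a small ontology (root, one branch term per parent, the parent
#' terms, and their children as leaves — the branch level keeps parent
#' pairs level-matched without a shared immediate parent), one PAG per
#' child with genes drawn per the overlap design, and a description per
#' child sampled from its parent's vocabulary mixed with the shared
#' vocabulary.
#'
#' @param spec A [fixture_spec()] (or preset name, passed through
#'   [fixture_preset()]).
#' @param seed Optional seed overriding the spec's.
#' @return List with `dag` (ontology_dag), `collection` (pag_collection),
#'   `descriptions` (named character), `labels` (named integer: parent
#'   index per child).
#' @export
make_fixture <- function(spec = fixture_spec(), seed = NULL) {
  if (is.character(spec)) spec <- fixture_preset(spec)
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  g <- spec$genes_per_child
  w <- round(spec$within_parent_gene_overlap * g)
  b <- round(spec$between_parent_gene_overlap * g)

  n_children <- with_seed(derive_seed(spec$seed, "sizes"),
    sample(spec$children_per_parent[1]:spec$children_per_parent[2],
           spec$n_parents, replace = TRUE))

  gene_id <- local({ counter <- 0L; function(n) {
    if (n == 0L) return(character(0))
    out <- paste0("G", counter + seq_len(n)); counter <<- counter + n; out
  }})
  shared_core <- gene_id(b)

  pags <- list(); labels <- integer(0); descriptions <- character(0)
  edges_child <- character(0); edges_parent <- character(0)
  shared_vocab <- paste0("common", seq_len(max(1, spec$vocabulary_per_parent)))
  for (p in seq_len(spec$n_parents)) {
    # each parent sits under its own branch term so that parent pairs are
    # level-matched without sharing an immediate parent
    parent_id <- sprintf("P%02d", p)
    branch_id <- sprintf("B%02d", p)
    edges_child <- c(edges_child, branch_id, parent_id)
    edges_parent <- c(edges_parent, "root", branch_id)
    parent_core <- c(shared_core, gene_id(w - b))
    vocab <- paste0("p", p, "term", seq_len(spec$vocabulary_per_parent))
    for (ci in seq_len(n_children[p])) {
      child_id <- sprintf("P%02d.C%02d", p, ci)
      genes <- c(parent_core, gene_id(g - w))
      n_shared_words <- round(spec$shared_vocab_fraction * spec$description_length)
      words <- with_seed(derive_seed(spec$seed, paste0("desc", child_id)), c(
        sample(shared_vocab, n_shared_words, replace = TRUE),
        sample(vocab, spec$description_length - n_shared_words, replace = TRUE)))
      desc <- paste(words, collapse = " ")
      pags[[child_id]] <- pag(child_id, genes, description = desc)
      labels[child_id] <- p
      descriptions[child_id] <- desc
      edges_child <- c(edges_child, child_id)
      edges_parent <- c(edges_parent, parent_id)
    }
  }
  list(dag = ontology_dag(edges_child, edges_parent),
       collection = pag_collection(pags),
       descriptions = descriptions,
       labels = labels)
}

#' Gaussian-blob embeddings with known cluster structure
#'
#' `k` clusters of `n_per_cluster` points each, centered at `separation`
#' times the first `k` coordinate axes (so clusters are equidistant), with
#' unit spherical noise. Used by the consensus and clustering tests.
#'
#' @param n_per_cluster Points per cluster.
#' @param k Number of clusters (requires `dim >= k`).
#' @param separation Center distance from the origin (0 with `k = 1` gives
#'   a single structureless blob).
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @return List with `embedding` (an `embedding_matrix`) and `labels`.
#' @export
make_separable_embeddings <- function(n_per_cluster = 30, k = 2,
                                      separation = 6, dim = 8, seed = 1) {
  stopifnot(dim >= k, n_per_cluster >= 2, k >= 1)
  X <- with_seed(seed, do.call(rbind, lapply(seq_len(k), function(i) {
    ctr <- rep(0, dim); ctr[i] <- separation
    sweep(matrix(stats::rnorm(n_per_cluster * dim), n_per_cluster, dim),
          2, ctr, "+")
  })))
  ids <- sprintf("item%03d", seq_len(nrow(X)))
  rownames(X) <- ids
  list(embedding = embedding_matrix(X, ids, source = "fused"),
       labels = stats::setNames(rep(seq_len(k), each = n_per_cluster), ids))
}
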