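#' Construct an ontology DAG from child -> parent edges
#'
#' Terms are related by directed is-a edges (child points to parent). The
#' structure must be acyclic and have at least one root (a node with no
#' parent). Multiple parents are allowed (ontologies are DAGs, not trees).
#'
#' @param children,parents Character vectors of equal length: edge i says
#'   `children[i]` is-a `parents[i]`.
#' @param names Optional named character vector of term names.
#' @return Object of class `ontology_dag` with elements `nodes`, `edges`
#'   (two-column character matrix child/parent), `roots`, and the underlying
#'   `igraph` (edges directed child -> parent).
#' @export
ontology_dag <- function(children, parents, names = NULL) {
  children <- as.character(children); parents <- as.character(parents)
  stopifnot(length(children) == length(parents))
  nodes <- unique(c(children, parents))
  g <- igraph::graph_from_data_frame(
    data.frame(from = children, to = parents, stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  if (!igraph::is_dag(g)) {
    cyc <- find_one_cycle(g)
    stop("ontology edges contain a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  outdeg <- igraph::degree(g, mode = "out")
  roots <- names(outdeg)[outdeg == 0]
  if (!length(roots)) stop("ontology has no root", call. = FALSE)
  structure(list(
    nodes = nodes,
    names = names,
    edges = cbind(child = children, parent = parents),
    roots = roots,
    graph = g
  ), class = "ontology_dag")
}

# walk successors until a repeat; report the closed part of the walk
find_one_cycle <- function(g) {
  n <- igraph::vcount(g)
  for (start in seq_len(n)) {
    path <- integer(0)
    v <- start
    repeat {
      if (v %in% path) {
        cyc <- path[which(path == v)[1]:length(path)]
        return(igraph::V(g)$name[c(cyc, v)])
      }
      path <- c(path, v)
      nxt <- igraph::neighbors(g, v, mode = "out")
      if (!length(nxt)) break
      v <- as.integer(nxt[1])
    }
  }
  character(0)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d is-a edges, %d root(s)\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Read an ontology from a child/parent edge-list TSV
#'
#' Two tab-separated columns per line: child id, parent id. A header line
#' starting with `child` is skipped. Cycles are rejected with an error that
#' names one offending cycle.
#'
#' @param path Path to the TSV file.
#' @return An [ontology_dag()].
#' @export
read_ontology_edges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^child\\b", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stop("malformed edge line ", bad[1], call. = FALSE)
  ontology_dag(vapply(parts, `[`, character(1), 1),
               vapply(parts, `[`, character(1), 2))
}

#' Write ontology edges as TSV (inverse of [read_ontology_edges()])
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @export
write_ontology_edges <- function(dag, path) {
  writeLines(c("child\tparent",
               paste(dag$edges[, "child"], dag$edges[, "parent"], sep = "\t")),
             path)
  invisible(path)
}

#' Term depth: shortest-path distance from a root
#'
#' Depth is measured over is-a edges traversed parent -> child; for terms
#' reachable through several parents the minimum (shortest path) is used.
#' `depth(root) = 0`; unreachable terms get `NA`.
#'
#' @param dag An `ontology_dag`.
#' @param root Root term id (defaults to the DAG's single root).
#' @return Named integer vector of depths for all terms.
#' @export
term_depths <- function(dag, root = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (is.null(root)) {
    if (length(dag$roots) != 1L) {
      stop("multiple roots; specify `root`", call. = FALSE)
    }
    root <- dag$roots
  }
  if (!root %in% dag$nodes) stop("root not in ontology: ", root, call. = FALSE)
  d <- igraph::distances(dag$graph, v = root, mode = "in")[1, ]
  d[is.infinite(d)] <- NA_integer_
  stats::setNames(as.integer(d), igraph::V(dag$graph)$name)
}

#' Direct is-a children of each term
#' @param dag An `ontology_dag`.
#' @param terms Terms to report (default all).
#' @return Named list id -> character vector of direct children.
#' @export
term_children <- function(dag, terms = dag$nodes) {
  stopifnot(inherits(dag, "ontology_dag"))
  ch <- split(dag$edges[, "child"], dag$edges[, "parent"])
  out <- lapply(terms, function(t) unique(unname(ch[[t]])) %||% character(0))
  stats::setNames(out, terms)
}

#' Direct is-a parents of each term
#' @param dag An `ontology_dag`.
#' @param terms Terms to report (default all).
#' @return Named list id -> character vector of direct parents.
#' @export
term_parents <- function(dag, terms = dag$nodes) {
  stopifnot(inherits(dag, "ontology_dag"))
  pa <- split(dag$edges[, "parent"], dag$edges[, "child"])
  out <- lapply(terms, function(t) unique(unname(pa[[t]])) %||% character(0))
  stats::setNames(out, terms)
}
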