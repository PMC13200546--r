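#' Construct an embedding matrix
#'
#' A row-indexed numeric matrix tagged with its provenance: `graph` (random
#' walk + skip-gram), `semantic` (text encoder), or `fused` (alpha blend).
#'
#' @param vectors Numeric matrix; rows are items.
#' @param row_ids Character ids, one per row (defaults to rownames).
#' @param source One of `"graph"`, `"semantic"`, `"fused"`.
#' @param l2_normalized Whether rows are unit-norm (zero rows permitted).
#' @return Object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(vectors, row_ids = rownames(vectors),
                             source = c("graph", "semantic", "fused"),
                             l2_normalized = FALSE) {
  source <- match.arg(source)
  vectors <- as.matrix(vectors)
  if (is.null(row_ids)) stop("row_ids required", call. = FALSE)
  row_ids <- as.character(row_ids)
  stopifnot(length(row_ids) == nrow(vectors))
  if (anyDuplicated(row_ids)) stop("duplicate row ids", call. = FALSE)
  if (!all(is.finite(vectors))) stop("non-finite embedding values", call. = FALSE)
  rownames(vectors) <- row_ids
  structure(list(vectors = vectors, row_ids = row_ids, dim = ncol(vectors),
                 source = source, l2_normalized = l2_normalized),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d x %d, source=%s%s\n",
              nrow(x$vectors), x$dim, x$source,
              if (x$l2_normalized) ", L2-normalized" else ""))
  invisible(x)
}

#' @export
dim.embedding_matrix <- function(x) dim(x$vectors)

#' Row-wise L2 normalization
#'
#' Nonzero rows are scaled to unit Euclidean norm; all-zero rows (used for
#' isolated network nodes and empty descriptions) are left as zeros.
#'
#' @param m An `embedding_matrix` or plain numeric matrix.
#' @return Same type as the input, normalized.
#' @export
l2_normalize <- function(m) {
  if (inherits(m, "embedding_matrix")) {
    v <- l2_normalize(m$vectors)
    return(embedding_matrix(v, m$row_ids, m$source, l2_normalized = TRUE))
  }
  nrm <- sqrt(rowSums(m^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  m * scale
}

#' Subset an embedding matrix by id
#' @param m An `embedding_matrix`.
#' @param ids Ids to keep, in the requested order.
#' @return An `embedding_matrix` over `ids`.
#' @export
subset_embedding <- function(m, ids) {
  stopifnot(inherits(m, "embedding_matrix"))
  missing <- setdiff(ids, m$row_ids)
  if (length(missing)) {
    stop("ids absent from embedding: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  embedding_matrix(m$vectors[ids, , drop = FALSE], ids, m$source, m$l2_normalized)
}

#' Write an embedding matrix as TSV (id + one column per dimension)
#' @param m An `embedding_matrix`.
#' @param path Output path.
#' @export
write_embedding_tsv <- function(m, path) {
  stopifnot(inherits(m, "embedding_matrix"))
  df <- data.frame(id = m$row_ids, m$vectors, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embedding_tsv()]
#' @param path TSV path.
#' @param source Provenance tag to attach.
#' @return An `embedding_matrix`.
#' @export
read_embedding_tsv <- function(path, source = "graph") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  embedding_matrix(v, df[[1]], source)
}

# mean pairwise cosine similarity between rows of two matrices (or within one)
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
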