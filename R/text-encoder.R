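#' Deterministic offline text encoder (hashed bag-of-words projection)
#'
#' Encodes each text as hashed token counts pushed through a fixed random
#' projection: every distinct token deterministically hashes to a signed
#' Gaussian direction in `dim` dimensions, and a text's vector is the
#' count-weighted sum of its tokens' directions. Texts sharing vocabulary
#' therefore correlate; disjoint vocabularies are nearly orthogonal. The
#' encoder needs no model files or network access and is fully
#' deterministic, which makes it the reference encoder for all quantitative
#' tests. Remote sentence encoders can be swapped in through the same port
#' (any function mapping a character vector to a numeric matrix).
#'
#' Tokenization: lowercase, split on non-alphanumeric characters.
#'
#' @param dim Output dimension (default 512, matching the usual
#'   semantic-embedding size that is then PCA-aligned to the graph
#'   dimension).
#' @return An encoder function: `character vector -> numeric matrix`.
#' @export
hash_text_encoder <- function(dim = 512) {
  force(dim)
  function(texts) {
    out <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      toks <- tokenize_text(texts[[i]])
      if (!length(toks)) next
      tab <- table(toks)
      v <- numeric(dim)
      for (j in seq_along(tab)) {
        v <- v + as.numeric(tab[[j]]) * token_direction(names(tab)[j], dim)
      }
      out[i, ] <- v
    }
    out
  }
}

tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# FNV-style 31-bit hash of a token (xor byte, multiply by the FNV prime,
# reduce mod 2^31; the product stays below 2^53 so double arithmetic is exact)
token_hash <- function(token) {
  h <- 2166136261 %% 2147483648
  for (ch in utf8ToInt(token)) {
    h <- bitwXor(as.integer(h), as.integer(ch %% 2147483648))
    h <- (as.numeric(h) * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483629) + 1L
}

# fixed pseudo-random unit direction for a token, seeded by its hash
token_direction <- function(token, dim) {
  with_seed(token_hash(token), {
    d <- stats::rnorm(dim)
    d / sqrt(sum(d^2))
  })
}

#' Encode PAG descriptions into a semantic embedding matrix
#'
#' Applies a text encoder to an id -> text mapping. Empty texts yield
#' all-zero rows. The returned matrix is raw encoder output (not yet
#' normalized or dimension-aligned); follow with [pca_align()].
#'
#' @param texts Named character vector (id -> description).
#' @param encoder Encoder port: a function `character -> matrix`. Default is
#'   the deterministic offline encoder [hash_text_encoder()].
#' @return An `embedding_matrix` with `source = "semantic"`.
#' @export
encode_descriptions <- function(texts, encoder = hash_text_encoder()) {
  if (is.null(names(texts)) || any(!nzchar(names(texts)))) {
    stop("texts must be a named (id -> text) vector", call. = FALSE)
  }
  mat <- tryCatch(encoder(as.character(texts)), error = function(e) {
    stop("text encoder failed on ids [", paste(utils::head(names(texts), 3),
         collapse = ", "), " ...]: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.matrix(mat) || nrow(mat) != length(texts)) {
    stop("encoder must return one row per input text", call. = FALSE)
  }
  embedding_matrix(mat, names(texts), source = "semantic")
}

#' Project semantic embeddings to the graph dimension with PCA
#'
#' Principal component analysis on the row-centered matrix, keeping exactly
#' `target_dim` components so the semantic space can be blended with the
#' graph space. The retained-variance ratio (top `target_dim` eigenvalues
#' over the total) is reported in `attr(, "retained_variance")`; a warning
#' is emitted when it falls below `variance_goal` (the dimension match wins
#' over the variance goal, since blending requires equal dimensions).
#' Projected rows are L2-normalized.
#'
#' @param sem A semantic `embedding_matrix`.
#' @param target_dim Output dimension; must satisfy
#'   `target_dim <= min(nrow - 1, dim)`.
#' @param variance_goal Warn when retained variance drops below this
#'   (default 0.95).
#' @return An L2-normalized `embedding_matrix` of width `target_dim` with
#'   attribute `retained_variance`.
#' @export
pca_align <- function(sem, target_dim, variance_goal = 0.95) {
  stopifnot(inherits(sem, "embedding_matrix"))
  n <- nrow(sem$vectors)
  if (target_dim > min(n - 1, sem$dim)) {
    stop(sprintf("target_dim %d too large (max %d for %d rows of width %d)",
                 target_dim, min(n - 1, sem$dim), n, sem$dim), call. = FALSE)
  }
  pc <- stats::prcomp(sem$vectors, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  retained <- sum(ev[seq_len(target_dim)]) / sum(ev)
  if (retained < variance_goal) {
    warning(sprintf("PCA to %d dims retains %.1f%% of variance (< %.0f%%)",
                    target_dim, 100 * retained, 100 * variance_goal),
            call. = FALSE)
  }
  proj <- pc$x[, seq_len(target_dim), drop = FALSE]
  out <- l2_normalize(embedding_matrix(proj, sem$row_ids, source = "semantic"))
  attr(out, "retained_variance") <- retained
  out
}
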