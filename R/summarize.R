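#' Concatenate member descriptions under a character budget
#'
#' Joins the descriptions of a cluster's member PAGs into one text block
#' for summarization. If the verbatim join exceeds `budget` characters,
#' members are condensed rather than truncated: first every description is
#' reduced to its leading sentence, then the longest contributions are
#' halved word-wise until the join fits. Every member keeps at least one
#' word of its leading sentence.
#'
#' @param members List of [pag()] objects (or a character vector of
#'   descriptions).
#' @param budget Maximum output length in characters (default 8000, a
#'   stand-in for summarizer input limits).
#' @param separator Join separator (default a single space).
#' @return A single string of length at most `budget` (empty for no
#'   members).
#' @export
concatenate_descriptions <- function(members, budget = 8000, separator = " ") {
  texts <- if (is.character(members)) members else
    vapply(members, function(p) p$description, character(1))
  texts <- texts[nzchar(trimws(texts))]
  if (!length(texts)) return("")
  joined <- paste(texts, collapse = separator)
  if (nchar(joined) <= budget) return(joined)
  # condense: leading sentence per member
  texts <- vapply(texts, first_sentence, character(1), USE.NAMES = FALSE)
  joined <- paste(texts, collapse = separator)
  while (nchar(joined) > budget) {
    longest <- which.max(nchar(texts))
    words <- strsplit(texts[longest], " ", fixed = TRUE)[[1]]
    if (length(words) <= 1) break  # cannot condense further
    texts[longest] <- paste(words[seq_len(ceiling(length(words) / 2))],
                            collapse = " ")
    joined <- paste(texts, collapse = separator)
  }
  substr(joined, 1, budget)
}

split_sentences <- function(text) {
  s <- trimws(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]])
  s[nzchar(s)]
}

first_sentence <- function(text) {
  s <- split_sentences(text)
  if (length(s)) s[1] else trimws(text)
}

#' Offline extractive summarizer
#'
#' Returns the single most central sentence: each sentence is scored by the
#' mean document-level frequency of its tokens, and the highest-scoring
#' sentence wins (first on ties). Deterministic; needs no model files.
#'
#' @param text Input text.
#' @return One sentence.
#' @export
extractive_summarizer <- function(text) {
  sentences <- split_sentences(text)
  if (length(sentences) <= 1) return(if (length(sentences)) sentences else trimws(text))
  freq <- table(tokenize_text(text))
  score <- vapply(sentences, function(s) {
    toks <- tokenize_text(s)
    if (!length(toks)) return(0)
    mean(as.numeric(freq[toks]))
  }, numeric(1))
  sentences[which.max(score)]
}

#' Summarize a cluster description block
#'
#' Applies a summarizer port (a function `text -> text`) to the
#' concatenated descriptions. The default is the offline
#' [extractive_summarizer()]; remote abstractive models plug in through
#' the same port and are never required.
#'
#' @param text Source text (typically from [concatenate_descriptions()]).
#' @param summarizer Summarizer port.
#' @param cluster_id Optional id used to contextualize failures.
#' @return Summary text.
#' @export
summarize_text <- function(text, summarizer = extractive_summarizer,
                           cluster_id = NULL) {
  tryCatch(summarizer(text), error = function(e) {
    stop("summarizer failed", if (!is.null(cluster_id))
      paste0(" for cluster ", cluster_id), ": ", conditionMessage(e),
      call. = FALSE)
  })
}

# shared tokenization: lowercase, split on non-alphanumerics
rouge_tokens <- function(text) tokenize_text(text)

rouge_n_f <- function(summary, reference) {
  s <- rouge_tokens(summary); r <- rouge_tokens(reference)
  if (!length(s) || !length(r)) return(0)
  ts <- table(s); tr <- table(r)
  shared <- intersect(names(ts), names(tr))
  match <- sum(pmin(as.numeric(ts[shared]), as.numeric(tr[shared])))
  prec <- match / length(s); rec <- match / length(r)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

lcs_length <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  prev <- integer(length(b) + 1)
  for (i in seq_along(a)) {
    cur <- integer(length(b) + 1)
    for (j in seq_along(b)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

rouge_l_f <- function(summary, reference) {
  s <- rouge_tokens(summary); r <- rouge_tokens(reference)
  if (!length(s) || !length(r)) return(0)
  l <- lcs_length(s, r)
  prec <- l / length(s); rec <- l / length(r)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Score a summary against a reference text
#'
#' Three standard summary-quality metrics: cosine similarity between the
#' encoder embeddings of summary and reference; ROUGE-1 F (unigram-overlap
#' F1 with clipped counts); and ROUGE-L F (longest-common-subsequence F1).
#' Tokenization for the ROUGE scores is fixed: lowercase, split on
#' non-alphanumeric characters. An empty reference scores 0 on all three
#' metrics, with a warning.
#'
#' @param summary Summary text.
#' @param reference Reference text (by default the concatenated source
#'   descriptions serve as the reference).
#' @param encoder Text encoder for the cosine metric (default offline hash
#'   encoder).
#' @return Named numeric vector `c(cosine, rouge1_f, rougeL_f)`, each in
#'   `[0, 1]`.
#' @export
eval_summary <- function(summary, reference, encoder = hash_text_encoder()) {
  if (!nzchar(trimws(reference))) {
    warning("empty reference text; metrics set to 0", call. = FALSE)
    return(c(cosine = 0, rouge1_f = 0, rougeL_f = 0))
  }
  vecs <- encoder(c(summary, reference))
  cs <- cosine_similarity(vecs[1, ], vecs[2, ])
  c(cosine = min(max(cs, 0), 1),
    rouge1_f = rouge_n_f(summary, reference),
    rougeL_f = rouge_l_f(summary, reference))
}

#' Summarize every cluster of a PAG partition
#'
#' Convenience wrapper producing one summary record per non-noise cluster:
#' concatenated member descriptions, the summary, and its quality metrics
#' against the concatenation.
#'
#' @param clustering A `pag_clustering` (or named label vector).
#' @param descriptions Named id -> text vector.
#' @param summarizer Summarizer port (default offline extractive).
#' @param encoder Encoder for the cosine metric.
#' @param budget Concatenation budget in characters.
#' @return Data frame with columns cluster_id, n_members, summary, cosine,
#'   rouge1_f, rougeL_f; the source texts are kept in
#'   `attr(, "source_text")`.
#' @export
summarize_clusters <- function(clustering, descriptions,
                               summarizer = extractive_summarizer,
                               encoder = hash_text_encoder(), budget = 8000) {
  labels <- if (inherits(clustering, "pag_clustering")) clustering$labels
            else clustering
  ids_by_cluster <- split(names(labels), labels)
  ids_by_cluster <- ids_by_cluster[names(ids_by_cluster) != "-1"]
  rows <- list(); src <- character(0)
  for (cl in names(ids_by_cluster)) {
    texts <- descriptions[ids_by_cluster[[cl]]]
    texts[is.na(texts)] <- ""
    source_text <- concatenate_descriptions(unname(texts), budget = budget)
    summary <- summarize_text(source_text, summarizer, cluster_id = cl)
    m <- if (nzchar(source_text)) eval_summary(summary, source_text, encoder)
         else c(cosine = 0, rouge1_f = 0, rougeL_f = 0)
    rows[[cl]] <- data.frame(cluster_id = cl,
                             n_members = length(ids_by_cluster[[cl]]),
                             summary = summary, t(m),
                             stringsAsFactors = FALSE)
    src[cl] <- source_text
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), n_members = integer(0),
               summary = character(0), cosine = numeric(0),
               rouge1_f = numeric(0), rougeL_f = numeric(0))
  rownames(out) <- NULL
  attr(out, "source_text") <- src
  out
}
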