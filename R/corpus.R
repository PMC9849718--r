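## Corpus operations: title-relevance filtering, top-k TF-IDF keyword
## extraction, and selection of scheme-specific (UEBMI) documents.

#' Filter documents by title relevance
#'
#' A document is retained iff its title shares at least one token with
#' `relevance_tokens` (the health-relevance rule: titles mentioning medical,
#' medicine, health, hospital, ... terms). Input order is preserved; an empty
#' result is valid.
#'
#' @param docs list of `policy_document`.
#' @param relevance_tokens non-empty character vector.
#' @return filtered list of `policy_document`.
#' @export
filter_relevant <- function(docs, relevance_tokens) {
  assert_that(length(relevance_tokens) > 0, "relevance token set must be non-empty")
  keep <- vapply(docs, function(d) any(d$title_tokens %in% relevance_tokens), logical(1))
  docs[keep]
}

#' Extract top-k TF-IDF keywords per document
#'
#' Scores each term t in document d as `tf(t, d) * ln(N / df(t))` with raw
#' term counts, corpus size N and document frequency df, pooling title and
#' body tokens. The top `k` terms by score are returned per document, ties
#' broken by ascending token string. Terms occurring in every document have
#' idf 0 and are excluded, unless fewer than `k` positive-score terms exist,
#' in which case zero-score terms fill the remaining slots ranked by raw tf
#' (descending) then token; a single-document corpus therefore falls back to
#' top-k by raw term frequency.
#'
#' @param docs non-empty list of `policy_document`; document frequencies are
#'   computed over exactly this input corpus.
#' @param k number of keywords per document (default 5).
#' @param smooth_idf use `ln(1 + N/df)` instead of `ln(N/df)` (default FALSE).
#' @param sublinear_tf use `1 + ln(tf)` instead of raw tf (default FALSE).
#' @return a list, one element per document, each
#'   `list(doc_id, keywords = data.frame(token, score, tf))` with scores
#'   non-increasing.
#' @export
tfidf_keywords <- function(docs, k = 5L, smooth_idf = FALSE, sublinear_tf = FALSE) {
  assert_that(length(docs) > 0, "tfidf_keywords: empty corpus")
  assert_that(is_count(k) && k >= 1, "k must be a positive integer")
  n_docs <- length(docs)

  counts <- lapply(docs, function(d) table(c(d$title_tokens, d$body_tokens)))
  df <- table(unlist(lapply(counts, names), use.names = FALSE))

  lapply(seq_along(docs), function(i) {
    ct <- counts[[i]]
    toks <- names(ct)
    tf <- as.numeric(ct)
    if (sublinear_tf) tf_w <- 1 + log(tf) else tf_w <- tf
    dfi <- as.numeric(df[toks])
    idf <- if (smooth_idf) log(1 + n_docs / dfi) else log(n_docs / dfi)
    score <- tf_w * idf

    pos <- score > 0
    ord_pos <- order(-score[pos], toks[pos])
    sel <- which(pos)[ord_pos]
    if (length(sel) < k) {
      zero <- which(!pos)
      ord_zero <- zero[order(-tf[zero], toks[zero])]
      sel <- c(sel, ord_zero)
    }
    sel <- sel[seq_len(min(k, length(sel)))]
    list(doc_id = docs[[i]]$doc_id,
         keywords = data.frame(token = toks[sel], score = score[sel], tf = tf[sel],
                               stringsAsFactors = FALSE, row.names = NULL))
  })
}

#' Select scheme-specific documents
#'
#' A document is retained iff the scheme marker token (e.g. the token standing
#' for "UEBMI") appears in its title or among its extracted keywords. A
#' body-only mention that did not make the keyword list is insufficient.
#'
#' @param docs list of `policy_document`.
#' @param keyword_sets keyword sets aligned to `docs` (same doc_ids, any
#'   order); missing entries raise an alignment error.
#' @param uebmi_token the scheme marker token.
#' @return the retained subset of `docs`, order preserved.
#' @export
identify_uebmi_docs <- function(docs, keyword_sets, uebmi_token) {
  ks_ids <- vapply(keyword_sets, `[[`, character(1), "doc_id")
  idx <- match(vapply(docs, `[[`, character(1), "doc_id"), ks_ids)
  if (anyNA(idx)) {
    missing <- vapply(docs[is.na(idx)], `[[`, character(1), "doc_id")
    stop2(paste0("keyword sets missing for documents: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  keep <- vapply(seq_along(docs), function(i) {
    uebmi_token %in% docs[[i]]$title_tokens ||
      uebmi_token %in% keyword_sets[[idx[i]]]$keywords$token
  }, logical(1))
  docs[keep]
}
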