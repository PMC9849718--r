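## Policy documents and their JSONL serialisation. One record per document:
## {doc_id, prefecture_id, year, title_tokens[], body_tokens[]}. Token
## sequences are pre-tokenized opaque strings; tokenization itself is the
## caller's concern (an injected step), not this package's.

#' Construct a policy document
#'
#' @param doc_id document identifier.
#' @param prefecture_id issuing prefecture identifier.
#' @param year issue year.
#' @param title_tokens character vector of title tokens.
#' @param body_tokens character vector of body tokens (non-empty).
#' @return an object of class `policy_document`.
#' @export
policy_document <- function(doc_id, prefecture_id, year, title_tokens, body_tokens) {
  assert_that(length(body_tokens) > 0, paste0("document ", doc_id, " has empty body"))
  structure(list(doc_id = as.character(doc_id),
                 prefecture_id = as.character(prefecture_id),
                 year = as.integer(year),
                 title_tokens = as.character(title_tokens),
                 body_tokens = as.character(body_tokens)),
            class = "policy_document")
}

#' @export
print.policy_document <- function(x, ...) {
  cat(sprintf("<policy_document %s> prefecture %s, %d; title: %s; body: %d tokens\n",
              x$doc_id, x$prefecture_id, x$year,
              paste(x$title_tokens, collapse = " "), length(x$body_tokens)))
  invisible(x)
}

#' Write documents as JSONL
#'
#' One JSON object per line, keys in fixed order, so identical inputs yield
#' byte-identical files.
#'
#' @param docs list of `policy_document`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(doc_id = jsonlite::unbox(d$doc_id),
                          prefecture_id = jsonlite::unbox(d$prefecture_id),
                          year = jsonlite::unbox(d$year),
                          title_tokens = d$title_tokens,
                          body_tokens = d$body_tokens))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read documents from JSONL
#'
#' @param path JSONL file as written by [write_corpus_jsonl()].
#' @return list of `policy_document`.
#' @export
read_corpus_jsonl <- function(path) {
  assert_that(file.exists(path), paste0("corpus file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    policy_document(rec$doc_id, rec$prefecture_id, rec$year,
                    as.character(rec$title_tokens %||% character()),
                    as.character(rec$body_tokens))
  })
}

#' Write per-document keyword sets as JSONL
#'
#' @param keyword_sets list as returned by [tfidf_keywords()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_keywords_jsonl <- function(keyword_sets, path) {
  lines <- vapply(keyword_sets, function(ks) {
    pairs <- Map(function(tok, sc) list(jsonlite::unbox(tok), jsonlite::unbox(sc)),
                 ks$keywords$token, ks$keywords$score)
    jsonlite::toJSON(list(doc_id = jsonlite::unbox(ks$doc_id),
                          keywords = unname(pairs)), digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
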