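## Exposure scoring: count categorised keyword occurrences per document (with
## collocation qualification of neutral keywords), aggregate to prefecture-year,
## and cumulate from each prefecture's scheme launch year.

## start positions of a (possibly multi-token) keyword in a token stream
ngram_positions <- function(tokens, kw_tokens) {
  L <- length(kw_tokens)
  n <- length(tokens)
  if (n < L) return(integer())
  hits <- which(tokens == kw_tokens[1])
  if (L == 1) return(hits)
  hits <- hits[hits <= n - L + 1]
  hits[vapply(hits, function(p) all(tokens[p:(p + L - 1)] == kw_tokens), logical(1))]
}

## occurrences of one keyword in one token stream; if neutral, only
## occurrences with a collocation word within `window` tokens on either side
count_occurrences <- function(tokens, keyword, neutral, colloc, window) {
  kw_tokens <- strsplit(keyword, " ", fixed = TRUE)[[1]]
  pos <- ngram_positions(tokens, kw_tokens)
  if (length(pos) == 0) return(0L)
  if (!neutral) return(length(pos))
  L <- length(kw_tokens)
  n <- length(tokens)
  qualified <- vapply(pos, function(p) {
    lo <- max(1L, p - window)
    hi <- min(n, p + L - 1L + window)
    nb <- tokens[setdiff(lo:hi, p:(p + L - 1L))]
    any(nb %in% colloc)
  }, logical(1))
  sum(qualified)
}

#' Count categorised keyword occurrences in one document
#'
#' For each of the document's extracted keywords that the lexicon maps to a
#' category, adds the keyword's total occurrence count over the document's
#' title and body token streams to that category. A neutral keyword's
#' occurrence counts only when a collocation word appears within the lexicon's
#' window on either side of the occurrence (within the same field). Tokens
#' that were not extracted as keywords never contribute, unless
#' `all_lexicon = TRUE` (sensitivity mode), in which case every lexicon
#' keyword is scanned regardless of extraction.
#'
#' @param doc a `policy_document`.
#' @param keyword_set the document's extracted keyword set (from
#'   [tfidf_keywords()]); must carry the same `doc_id`.
#' @param lexicon a `category_lexicon`.
#' @param all_lexicon scan all lexicon keywords instead of only extracted ones.
#' @return named integer vector over the four categories.
#' @export
count_document_categories <- function(doc, keyword_set, lexicon, all_lexicon = FALSE) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  assert_that(identical(doc$doc_id, keyword_set$doc_id),
              paste0("keyword set for ", keyword_set$doc_id,
                     " does not belong to document ", doc$doc_id))
  counts <- stats::setNames(integer(length(EXPOSURE_CATEGORIES)), EXPOSURE_CATEGORIES)
  k2c <- lexicon$keyword_to_category
  if (all_lexicon) {
    candidates <- names(k2c)
  } else {
    extracted <- keyword_set$keywords$token
    pooled <- c(doc$title_tokens, doc$body_tokens)
    absent <- setdiff(extracted, pooled)
    assert_that(length(absent) == 0,
                paste0("corrupt keyword set for ", doc$doc_id,
                       ": keyword(s) not in document: ", paste(absent, collapse = ", ")))
    candidates <- intersect(unique(extracted), names(k2c))
  }
  for (kw in candidates) {
    neutral <- kw %in% lexicon$neutral_keywords
    occ <- count_occurrences(doc$title_tokens, kw, neutral,
                             lexicon$collocation_words, lexicon$collocation_window) +
           count_occurrences(doc$body_tokens, kw, neutral,
                             lexicon$collocation_words, lexicon$collocation_window)
    cat_ <- k2c[[kw]]
    counts[cat_] <- counts[cat_] + occ
  }
  counts
}

#' Count categories for a whole corpus
#'
#' @param docs list of `policy_document`.
#' @param keyword_sets aligned keyword sets (any order, matched by doc_id).
#' @param lexicon a `category_lexicon`.
#' @param all_lexicon see [count_document_categories()].
#' @return data.frame with doc_id, prefecture_id, year and the four category
#'   count columns, one row per document.
#' @export
count_corpus_categories <- function(docs, keyword_sets, lexicon, all_lexicon = FALSE) {
  ks_ids <- vapply(keyword_sets, `[[`, character(1), "doc_id")
  idx <- match(vapply(docs, `[[`, character(1), "doc_id"), ks_ids)
  assert_that(!anyNA(idx), "keyword sets not aligned to documents")
  rows <- lapply(seq_along(docs), function(i) {
    cc <- count_document_categories(docs[[i]], keyword_sets[[idx[i]]], lexicon, all_lexicon)
    cbind(data.frame(doc_id = docs[[i]]$doc_id,
                     prefecture_id = docs[[i]]$prefecture_id,
                     year = docs[[i]]$year, stringsAsFactors = FALSE),
          as.data.frame(as.list(cc)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), prefecture_id = character(),
                      year = integer(),
                      benefit_expansion = integer(), cost_containment = integer(),
                      service_delivery = integer(), pharmaceutical = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Aggregate per-document category counts to prefecture-year
#'
#' @param doc_counts output of [count_corpus_categories()] (or the generator's
#'   per-document ground truth with the same columns).
#' @return data.frame prefecture_id, year, four category yearly totals;
#'   sorted by prefecture then year. Row order of the input is irrelevant.
#' @export
aggregate_prefecture_year <- function(doc_counts) {
  if (nrow(doc_counts) == 0)
    return(data.frame(prefecture_id = character(), year = integer(),
                      benefit_expansion = integer(), cost_containment = integer(),
                      service_delivery = integer(), pharmaceutical = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(doc_counts[EXPOSURE_CATEGORIES],
                          by = list(prefecture_id = doc_counts$prefecture_id,
                                    year = doc_counts$year),
                          FUN = sum)
  agg <- agg[order(agg$prefecture_id, agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Cumulate yearly counts into exposure measures
#'
#' For each prefecture and category, exposure at year t is the sum of yearly
#' counts from the prefecture's scheme launch year through t, and 0 for years
#' before launch (prefectures not yet running the scheme have zero exposure).
#' With `supply_from_start = TRUE` the two supply-side categories
#' (service_delivery, pharmaceutical) are instead cumulated from the first
#' year of `years`, regardless of launch.
#'
#' @param yearly output of [aggregate_prefecture_year()].
#' @param launch_years named vector (names = prefecture ids) of launch years;
#'   required for every prefecture present in `yearly`.
#' @param years integer vector of years the table must cover; defaults to the
#'   range of years present in `yearly`.
#' @param supply_from_start cumulate supply-side categories from the first
#'   year instead of the launch year.
#' @return an `exposure_table`: data.frame prefecture_id, year, launch_year,
#'   four cumulative category columns, with a `divisor` attribute (1).
#' @export
cumulate <- function(yearly, launch_years, years = NULL, supply_from_start = FALSE) {
  prefs <- sort(unique(c(as.character(yearly$prefecture_id), names(launch_years))))
  missing_launch <- setdiff(unique(as.character(yearly$prefecture_id)), names(launch_years))
  assert_that(length(missing_launch) == 0,
              paste0("missing launch year for prefecture(s): ",
                     paste(missing_launch, collapse = ", ")))
  if (is.null(years)) {
    assert_that(nrow(yearly) > 0, "cumulate: no yearly counts and no `years` given")
    years <- seq(min(yearly$year), max(yearly$year))
  }
  years <- sort(unique(as.integer(years)))
  key <- py_key(yearly$prefecture_id, yearly$year)

  grid <- expand.grid(year = years, prefecture_id = prefs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("prefecture_id", "year")]
  grid$launch_year <- as.integer(launch_years[grid$prefecture_id])

  for (cc in EXPOSURE_CATEGORIES) {
    vals <- yearly[[cc]][match(py_key(grid$prefecture_id, grid$year), key)]
    vals[is.na(vals)] <- 0
    start <- if (supply_from_start && cc %in% c("service_delivery", "pharmaceutical"))
      min(years) else grid$launch_year
    vals[grid$year < start] <- 0
    cum <- stats::ave(vals, grid$prefecture_id, FUN = cumsum)
    cum[grid$year < start] <- 0
    grid[[cc]] <- cum
  }
  rownames(grid) <- NULL
  structure(grid, divisor = 1, class = c("exposure_table", "data.frame"))
}

#' Rescale exposure columns by a divisor
#'
#' Pure units choice for regression readability; the cumulative counts are
#' divided by `divisor` and the total divisor applied so far is recorded in
#' the table's `divisor` attribute (and in its CSV header on write).
#'
#' @param table an `exposure_table`.
#' @param divisor positive number.
#' @return the rescaled `exposure_table`.
#' @export
rescale <- function(table, divisor) {
  assert_that(is.numeric(divisor) && length(divisor) == 1 && divisor > 0,
              "divisor must be a positive number")
  for (cc in EXPOSURE_CATEGORIES) table[[cc]] <- table[[cc]] / divisor
  attr(table, "divisor") <- (attr(table, "divisor") %||% 1) * divisor
  table
}

#' Write an exposure table as CSV
#'
#' The divisor is recorded in a `# divisor:` comment header line.
#' @param table an `exposure_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# divisor: %.15g", attr(table, "divisor") %||% 1), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an exposure table from CSV
#'
#' @param path CSV as written by [write_exposure_csv()] (the `# divisor:`
#'   header is optional; plain CSVs are accepted with divisor 1).
#' @return an `exposure_table`.
#' @export
read_exposure_csv <- function(path) {
  assert_that(file.exists(path), paste0("exposure file not found: ", path))
  first <- readLines(path, n = 1)
  divisor <- 1
  skip <- 0
  if (startsWith(first, "# divisor:")) {
    divisor <- as.numeric(sub("# divisor:", "", first, fixed = TRUE))
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  df$prefecture_id <- as.character(df$prefecture_id)
  structure(df, divisor = divisor, class = c("exposure_table", "data.frame"))
}
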