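## Synthetic policy-document corpus with fully known ground truth. The
## generator emulates a prefectural policy database: per prefecture, a scheme
## launch year, a Poisson number of documents per year, a title-relevance mix,
## and - in scheme documents issued after launch - planted category keywords
## whose occurrence counts are the ground-truth exposure signal.
##
## Construction guarantees used by the tests:
## * background tokens come from a moderate closed vocabulary (high df, hence
##   low idf) and never collide with lexicon keywords, relevance tokens or the
##   scheme marker, so planted keywords (tf >= 4, low df) dominate the top-5
##   TF-IDF ranking;
## * at most one keyword per category is planted per document (<= 4 distinct),
##   so all planted keywords fit in the top-5;
## * collocation words occur ONLY adjacent to planted neutral-keyword
##   occurrences, and occurrence groups are separated by more than the
##   collocation window, so the countable (qualified) occurrences are exact by
##   construction;
## * documents dated before the prefecture's launch year contain no category
##   keywords at all.

RELEVANCE_TOKENS <- c("medical", "medicine", "health", "disease",
                      "hospital", "clinic", "outpatient", "hospitalization")
UEBMI_TOKEN <- "uebmi"

#' Specification of a synthetic document corpus
#'
#' @param n_prefectures number of prefectures.
#' @param years inclusive vector of calendar years covered.
#' @param launch_year_range 2-vector; each prefecture's scheme launch year is
#'   drawn uniformly from this inclusive range (within `years`).
#' @param docs_per_year_rate Poisson mean of documents per prefecture-year.
#' @param expansion_propensity,containment_propensity probability that a
#'   scheme document plants a benefit-expansion / cost-containment keyword;
#'   scalar or per-prefecture vector.
#' @param service_propensity,pharma_propensity same for the two supply-side
#'   categories.
#' @param neutral_keyword_rate probability a planted category mention uses a
#'   semantically neutral keyword (which then needs a collocation word to
#'   count); the generator collocates each neutral occurrence with
#'   probability `collocation_prob`.
#' @param collocation_prob probability a planted neutral-keyword occurrence is
#'   accompanied by a collocation word (others are planted bare and do not
#'   count toward ground truth).
#' @param relevant_fraction fraction of documents whose title passes the
#'   health-relevance filter.
#' @param uebmi_fraction fraction of relevant post-launch documents that are
#'   scheme (UEBMI) documents.
#' @param vocab_size background vocabulary size.
#' @param seed RNG seed; identical specs give byte-identical corpora.
#' @return a `corpus_spec`.
#' @export
corpus_spec <- function(n_prefectures = 50L,
                        years = 1997:2015,
                        launch_year_range = c(1998L, 2008L),
                        docs_per_year_rate = 3,
                        expansion_propensity = 0.55,
                        containment_propensity = 0.35,
                        service_propensity = 0.5,
                        pharma_propensity = 0.4,
                        neutral_keyword_rate = 0.3,
                        collocation_prob = 0.8,
                        relevant_fraction = 0.7,
                        uebmi_fraction = 0.6,
                        vocab_size = 300L,
                        seed = 1L) {
  assert_that(is_count(n_prefectures) && n_prefectures >= 1, "n_prefectures must be >= 1")
  assert_that(length(years) >= 1, "empty year range")
  years <- sort(unique(as.integer(years)))
  assert_that(length(launch_year_range) == 2 &&
                all(launch_year_range %in% years) &&
                launch_year_range[1] <= launch_year_range[2],
              "launch_year_range must be an inclusive range within years")
  rates <- list(expansion_propensity = expansion_propensity,
                containment_propensity = containment_propensity,
                service_propensity = service_propensity,
                pharma_propensity = pharma_propensity,
                neutral_keyword_rate = neutral_keyword_rate,
                collocation_prob = collocation_prob,
                relevant_fraction = relevant_fraction,
                uebmi_fraction = uebmi_fraction)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    assert_that(is.numeric(v) && all(v >= 0 & v <= 1),
                paste0(nm, " must lie in [0, 1]"))
    assert_that(length(v) %in% c(1L, n_prefectures),
                paste0(nm, " must be scalar or length n_prefectures"))
  }
  assert_that(is.numeric(docs_per_year_rate) && docs_per_year_rate >= 0,
              "docs_per_year_rate must be >= 0")
  assert_that(is_count(vocab_size) && vocab_size >= 10, "vocab_size must be >= 10")
  structure(list(n_prefectures = as.integer(n_prefectures), years = years,
                 launch_year_range = as.integer(launch_year_range),
                 docs_per_year_rate = docs_per_year_rate,
                 expansion_propensity = expansion_propensity,
                 containment_propensity = containment_propensity,
                 service_propensity = service_propensity,
                 pharma_propensity = pharma_propensity,
                 neutral_keyword_rate = neutral_keyword_rate,
                 collocation_prob = collocation_prob,
                 relevant_fraction = relevant_fraction,
                 uebmi_fraction = uebmi_fraction,
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

pref_rate <- function(spec, field, p_idx) {
  v <- spec[[field]]
  if (length(v) == 1) v else v[p_idx]
}

## pick a planted keyword for one category; neutral keywords only where the
## lexicon has one for the category
pick_keyword <- function(lexicon, category, neutral_rate) {
  kws <- names(lexicon$keyword_to_category)[lexicon$keyword_to_category == category]
  neut <- intersect(kws, lexicon$neutral_keywords)
  plain <- setdiff(kws, neut)
  use_neutral <- length(neut) > 0 && stats::runif(1) < neutral_rate
  pool <- if (use_neutral) neut else if (length(plain) > 0) plain else neut
  pool[sample.int(length(pool), 1)]
}

#' Generate a synthetic policy-document corpus
#'
#' @param spec a [corpus_spec()].
#' @param lexicon the `category_lexicon` whose keywords are planted (default
#'   [demo_lexicon()]).
#' @return list with `docs` (list of `policy_document`), `truth` (data.frame:
#'   doc_id, prefecture_id, year, is_relevant, is_uebmi and the four
#'   ground-truth countable category counts), `launch_years` (named vector),
#'   and `exposure` (the ground-truth `exposure_table`, i.e.
#'   [aggregate_prefecture_year()] + [cumulate()] applied to the planted
#'   counts).
#' @export
generate_corpus <- function(spec, lexicon = demo_lexicon()) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(lexicon, "category_lexicon"))
  bg_vocab <- sprintf("w%04d", seq_len(spec$vocab_size))
  title_vocab <- c("notice", "circular", "plan", "provision", "opinion",
                   "bureau", "administration", "municipal", "interim", "measures")
  window <- lexicon$collocation_window
  colloc <- lexicon$collocation_words

  docs <- list()
  truth_rows <- list()
  launch_years <- stats::setNames(integer(spec$n_prefectures),
                                  sprintf("P%03d", seq_len(spec$n_prefectures)))

  for (p in seq_len(spec$n_prefectures)) {
    pref_id <- sprintf("P%03d", p)
    set.seed(derive_seed(spec$seed, p))  # per-prefecture sub-stream
    launch <- sample(seq(spec$launch_year_range[1], spec$launch_year_range[2]), 1)
    launch_years[pref_id] <- launch
    doc_n <- 0L
    for (yr in spec$years) {
      n_docs <- stats::rpois(1, spec$docs_per_year_rate)
      if (n_docs == 0) next
      for (d in seq_len(n_docs)) {
        doc_n <- doc_n + 1L
        doc_id <- sprintf("%s-%04d", pref_id, doc_n)
        relevant <- stats::runif(1) < pref_rate(spec, "relevant_fraction", p)
        uebmi <- relevant && yr >= launch &&
          stats::runif(1) < pref_rate(spec, "uebmi_fraction", p)

        title <- sample(title_vocab, 3, replace = TRUE)
        if (relevant) title <- c(title, sample(RELEVANCE_TOKENS, 1))
        if (uebmi) title <- c(title, UEBMI_TOKEN)

        counts <- stats::setNames(integer(4), EXPOSURE_CATEGORIES)
        groups <- list()
        if (uebmi) {
          props <- c(benefit_expansion = pref_rate(spec, "expansion_propensity", p),
                     cost_containment = pref_rate(spec, "containment_propensity", p),
                     service_delivery = pref_rate(spec, "service_propensity", p),
                     pharmaceutical = pref_rate(spec, "pharma_propensity", p))
          for (cc in EXPOSURE_CATEGORIES) {
            if (stats::runif(1) >= props[[cc]]) next
            kw <- pick_keyword(lexicon, cc,
                               pref_rate(spec, "neutral_keyword_rate", p))
            is_neutral <- kw %in% lexicon$neutral_keywords
            m <- 4L + stats::rpois(1, 3)
            if (is_neutral) {
              collocated <- stats::runif(m) < pref_rate(spec, "collocation_prob", p)
              counts[cc] <- counts[cc] + sum(collocated)
              for (ok in collocated)
                groups[[length(groups) + 1L]] <-
                  if (ok) c(sample(colloc, 1), kw) else kw
            } else {
              counts[cc] <- counts[cc] + m
              for (i in seq_len(m)) groups[[length(groups) + 1L]] <- kw
            }
          }
        }

        ## assemble body: spacer > window between groups so collocation
        ## qualification is exact by construction
        n_bg <- 30L + stats::rpois(1, 20)
        body <- sample(bg_vocab, n_bg, replace = TRUE)
        if (length(groups) > 0) {
          groups <- groups[sample.int(length(groups))]
          segs <- list(sample(bg_vocab, window + 1, replace = TRUE))
          for (gtok in groups) {
            segs[[length(segs) + 1L]] <- gtok
            segs[[length(segs) + 1L]] <- sample(bg_vocab, window + 1, replace = TRUE)
          }
          segs[[length(segs) + 1L]] <- body
          body <- unlist(segs, use.names = FALSE)
        }

        docs[[length(docs) + 1L]] <- policy_document(doc_id, pref_id, yr, title, body)
        truth_rows[[length(truth_rows) + 1L]] <- cbind(
          data.frame(doc_id = doc_id, prefecture_id = pref_id, year = yr,
                     is_relevant = relevant, is_uebmi = uebmi,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)))
      }
    }
  }

  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
    data.frame(doc_id = character(), prefecture_id = character(), year = integer(),
               is_relevant = logical(), is_uebmi = logical(),
               benefit_expansion = integer(), cost_containment = integer(),
               service_delivery = integer(), pharmaceutical = integer(),
               stringsAsFactors = FALSE)
  exposure <- cumulate(aggregate_prefecture_year(truth), launch_years,
                       years = spec$years)
  list(docs = docs, truth = truth, launch_years = launch_years,
       exposure = exposure)
}
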