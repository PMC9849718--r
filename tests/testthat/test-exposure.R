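test_that("lexicon round-trips through its text config format", {
  lex <- demo_lexicon()
  path <- withr::local_tempfile(fileext = ".txt")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_identical(back$keyword_to_category, lex$keyword_to_category)
  expect_setequal(back$neutral_keywords, lex$neutral_keywords)
  expect_setequal(back$collocation_words, lex$collocation_words)
  expect_identical(back$collocation_window, lex$collocation_window)
  expect_error(category_lexicon(c(kw = "not_a_category")), "unknown categories")
})

test_that("worked three-document example: per-doc counts and aggregate (14, 8)", {
  fx <- guangzhou_fixture()
  ks <- tfidf_keywords(fx$docs, k = 5)
  c1 <- count_document_categories(fx$docs[[1]], ks[[1]], fx$lexicon)
  expect_identical(unname(c1["benefit_expansion"]), 14L)  # 10 collocated + 4
  expect_identical(unname(c1["cost_containment"]), 2L)
  counts <- count_corpus_categories(fx$docs, ks, fx$lexicon)
  agg <- aggregate_prefecture_year(counts)
  expect_identical(unname(agg$benefit_expansion), 14L)
  expect_identical(unname(agg$cost_containment), 8L)      # 2 + 3 + 3
  ## permuting document order leaves the table unchanged
  agg2 <- aggregate_prefecture_year(counts[c(3, 1, 2), ])
  expect_equal(agg2, agg)
})

test_that("a neutral keyword without a nearby collocation word never counts", {
  lex <- demo_lexicon()
  w <- lex$collocation_window
  ## occurrence with the direction word just OUTSIDE the window
  body <- c("increase", rep("filler", w), "reimb_rate", rep("filler", w + 1))
  d <- doc("n1", "p", 2005, c("uebmi"), body)
  ks <- tfidf_keywords(list(d), k = 5)
  expect_true("reimb_rate" %in% ks[[1]]$keywords$token)
  cc <- count_document_categories(d, ks[[1]], lex)
  expect_identical(sum(cc), 0L)
  ## same occurrence with the word just INSIDE the window counts once
  body2 <- c("increase", rep("filler", w - 1), "reimb_rate", rep("filler", w + 1))
  d2 <- doc("n1", "p", 2005, c("uebmi"), body2)
  cc2 <- count_document_categories(d2, tfidf_keywords(list(d2), k = 5)[[1]], lex)
  expect_identical(unname(cc2["benefit_expansion"]), 1L)
})

test_that("multi-token keywords match as contiguous n-grams", {
  lex <- category_lexicon(c("drug price negotiation" = "cost_containment",
                            solo = "benefit_expansion"))
  body <- c("a", "drug", "price", "negotiation", "b", "price", "negotiation",
            "drug", "c", "drug", "price", "negotiation")
  d <- doc("m1", "p", 2005, "t", body)
  fake_ks <- list(doc_id = "m1",
                  keywords = data.frame(token = "drug", score = 1, tf = 3))
  cc <- count_document_categories(d, fake_ks, lex, all_lexicon = TRUE)
  expect_identical(unname(cc["cost_containment"]), 2L)  # scrambled order does not match
})

test_that("document category counts equal the brute-force re-scan oracle", {
  gen <- generate_corpus(corpus_spec(n_prefectures = 5, seed = 17))
  lex <- demo_lexicon()
  rel <- filter_relevant(gen$docs, policytextpanel:::RELEVANCE_TOKENS)
  ks <- tfidf_keywords(rel, k = 5)
  sel <- identify_uebmi_docs(rel, ks, "uebmi")
  ks_ids <- vapply(ks, `[[`, character(1), "doc_id")
  for (d in sel[seq_len(min(40, length(sel)))]) {
    kset <- ks[[match(d$doc_id, ks_ids)]]
    got <- count_document_categories(d, kset, lex)
    want <- count_oracle(d, kset$keywords$token, lex)
    expect_identical(got, want)
    ## total counted occurrences can never exceed the document's token count
    expect_lte(sum(got), length(d$title_tokens) + length(d$body_tokens))
  }
  ## corrupt keyword set -> consistency error
  bad <- list(doc_id = sel[[1]]$doc_id,
              keywords = data.frame(token = "not_in_doc", score = 1, tf = 1))
  expect_error(count_document_categories(sel[[1]], bad, lex), "corrupt")
})

test_that("cumulate runs the sum from launch year and zeroes earlier years", {
  yearly <- data.frame(prefecture_id = "p1", year = c(2000, 2002),
                       benefit_expansion = c(3L, 5L), cost_containment = c(1L, 0L),
                       service_delivery = 0L, pharmaceutical = 0L)
  tab <- cumulate(yearly, c(p1 = 2000), years = 1998:2003)
  get <- function(yr) tab$benefit_expansion[tab$year == yr]
  expect_identical(get(2002), 8)          # 3 + 0 + 5
  expect_identical(get(2003), 8)          # carries forward
  expect_true(all(tab$benefit_expansion[tab$year < 2000] == 0))
  ## counts observed before launch are excluded from the running sum
  tab2 <- cumulate(yearly, c(p1 = 2001), years = 1998:2003)
  expect_identical(tab2$benefit_expansion[tab2$year == 2003], 5)
  expect_error(cumulate(yearly, c(px = 2000), years = 1998:2003), "launch year")
})

test_that("cumulative exposures are non-decreasing within prefecture", {
  gen <- generate_corpus(corpus_spec(n_prefectures = 8, seed = 23))
  tab <- gen$exposure
  for (p in unique(tab$prefecture_id)) {
    sub <- tab[tab$prefecture_id == p, ]
    sub <- sub[order(sub$year), ]
    for (cc in c("benefit_expansion", "cost_containment",
                 "service_delivery", "pharmaceutical"))
      expect_true(all(diff(sub[[cc]]) >= 0))
    expect_true(all(sub[sub$year < sub$launch_year[1],
                        c("benefit_expansion", "cost_containment")] == 0))
  }
})

test_that("rescale divides, composes multiplicatively, and records the divisor", {
  gen <- generate_corpus(corpus_spec(n_prefectures = 3, seed = 2))
  tab <- gen$exposure
  expect_equal(rescale(tab, 1), tab)
  r100 <- rescale(tab, 100)
  expect_equal(r100$benefit_expansion, tab$benefit_expansion / 100)
  expect_equal(attr(r100, "divisor"), 100)
  ## rescale(a) then rescale(b) == rescale(a*b)
  expect_equal(rescale(rescale(tab, 4), 25), r100)
  expect_error(rescale(tab, 0), "positive")
  ## CSV round trip preserves the divisor
  path <- withr::local_tempfile(fileext = ".csv")
  write_exposure_csv(r100, path)
  back <- read_exposure_csv(path)
  expect_equal(attr(back, "divisor"), 100)
  expect_equal(back$benefit_expansion, r100$benefit_expansion)
})

test_that("pipeline exposure equals generator ground truth exactly", {
  gen <- generate_corpus(corpus_spec(n_prefectures = 10, seed = 29))
  rel <- filter_relevant(gen$docs, policytextpanel:::RELEVANCE_TOKENS)
  ks <- tfidf_keywords(rel, k = 5)
  sel <- identify_uebmi_docs(rel, ks, "uebmi")
  ks_sel <- ks[match(vapply(sel, `[[`, character(1), "doc_id"),
                     vapply(ks, `[[`, character(1), "doc_id"))]
  counts <- count_corpus_categories(sel, ks_sel, demo_lexicon())
  tab <- cumulate(aggregate_prefecture_year(counts), gen$launch_years,
                  years = 1997:2015)
  expect_equal(as.data.frame(tab), as.data.frame(gen$exposure))
})
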