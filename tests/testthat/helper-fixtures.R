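## Fixtures and independent oracles shared across the test files. Oracles are
## deliberately naive (brute force / explicit dummy variables) and never call
## the code paths they check.

## ---- document fixtures ----

doc <- function(id, pref, year, title, body) {
  policy_document(id, pref, year, title, body)
}

## repeats each element of `pairs` (list of token vectors) with filler between
## occurrences, far enough apart that collocation windows never overlap
spaced_body <- function(groups, window = 5, filler = "filler") {
  segs <- list(rep(filler, window + 1))
  for (g in groups) {
    segs[[length(segs) + 1]] <- g
    segs[[length(segs) + 1]] <- rep(filler, window + 1)
  }
  unlist(segs, use.names = FALSE)
}

## the three-document worked example: one document with a collocated neutral
## expansion keyword (10 occurrences), a plain expansion keyword (4) and a
## containment keyword (2); two further documents with a containment keyword
## (3 occurrences each). Expected prefecture-year totals: expansion 14,
## containment 8.
guangzhou_fixture <- function() {
  lex <- demo_lexicon()
  d1 <- doc("GZ-1", "guangzhou", 2012, c("notice", "medical", "uebmi"),
            spaced_body(c(
              replicate(10, c("increase", "reimb_rate"), simplify = FALSE),
              replicate(4, "suppl_program", simplify = FALSE),
              replicate(2, "per_diem", simplify = FALSE))))
  d2 <- doc("GZ-2", "guangzhou", 2012, c("circular", "health", "uebmi"),
            spaced_body(replicate(3, "designated_facility_mgmt", simplify = FALSE)))
  d3 <- doc("GZ-3", "guangzhou", 2012, c("plan", "hospital", "uebmi"),
            spaced_body(replicate(3, "designated_facility_mgmt", simplify = FALSE)))
  list(docs = list(d1, d2, d3), lexicon = lex)
}

## ---- TF-IDF oracle: brute-force score-and-sort over the full vocabulary ----

tfidf_oracle <- function(docs, k = 5) {
  n <- length(docs)
  pooled <- lapply(docs, function(d) c(d$title_tokens, d$body_tokens))
  vocab <- unique(unlist(pooled))
  df <- vapply(vocab, function(t) sum(vapply(pooled, function(p) t %in% p, logical(1))),
               numeric(1))
  lapply(seq_len(n), function(i) {
    tf <- vapply(vocab, function(t) sum(pooled[[i]] == t), numeric(1))
    score <- tf * log(n / df)
    present <- tf > 0
    cand <- data.frame(token = vocab[present], score = score[present],
                       tf = tf[present], stringsAsFactors = FALSE)
    pos <- cand[cand$score > 0, ]
    pos <- pos[order(-pos$score, pos$token), ]
    if (nrow(pos) < k) {
      zero <- cand[cand$score <= 0, ]
      zero <- zero[order(-zero$tf, zero$token), ]
      pos <- rbind(pos, zero)
    }
    utils::head(pos, k)
  })
}

## ---- category-count oracle: independent re-scan of the token streams ----

count_oracle <- function(d, extracted, lexicon) {
  out <- setNames(integer(4), c("benefit_expansion", "cost_containment",
                                "service_delivery", "pharmaceutical"))
  w <- lexicon$collocation_window
  for (kw in intersect(unique(extracted), names(lexicon$keyword_to_category))) {
    kt <- strsplit(kw, " ")[[1]]
    total <- 0L
    for (stream in list(d$title_tokens, d$body_tokens)) {
      n <- length(stream)
      L <- length(kt)
      if (n < L) next
      for (p in seq_len(n - L + 1)) {
        if (!all(stream[p:(p + L - 1)] == kt)) next
        if (kw %in% lexicon$neutral_keywords) {
          nb <- stream[setdiff(max(1, p - w):min(n, p + L - 1 + w), p:(p + L - 1))]
          if (any(nb %in% lexicon$collocation_words)) total <- total + 1L
        } else total <- total + 1L
      }
    }
    out[lexicon$keyword_to_category[[kw]]] <- out[lexicon$keyword_to_category[[kw]]] + total
  }
  out
}

## ---- LSDV oracle: explicit dummy-variable lm() fit ----

lsdv_oracle <- function(panel, outcome, regressors, id_col = "person_id",
                        year_col = "year") {
  X <- as.data.frame(lapply(regressors, function(r) {
    parts <- strsplit(r, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) as.numeric(panel[[p]])))
  }))
  names(X) <- paste0("x", seq_along(regressors))
  dat <- cbind(data.frame(y = as.numeric(panel[[outcome]]),
                          id = factor(panel[[id_col]]),
                          yr = factor(panel[[year_col]])), X)
  fit <- stats::lm(y ~ . - id - yr + id + yr, data = dat)
  cf <- stats::coef(fit)[names(X)]
  se <- sqrt(diag(stats::vcov(fit)))[names(X)]
  list(coefficients = setNames(cf, regressors), se = setNames(se, regressors),
       sigma = summary(fit)$sigma)
}

## ---- just-identified IV ratio oracle on demeaned data ----

iv_ratio_oracle <- function(panel, outcome, endogenous, instrument,
                            id_col = "person_id") {
  dm <- function(v) {
    v <- as.numeric(v)
    stats::ave(v, panel[[id_col]], FUN = mean) * -1 + v
  }
  yt <- dm(panel[[outcome]]); xt <- dm(panel[[endogenous]])
  zt <- dm(panel[[instrument]])
  stats::cov(zt, yt) / stats::cov(zt, xt)
}

## ---- small panel fixture for estimator tests ----

make_small_panel <- function(n_id = 12, waves = c(2000, 2005, 2010), seed = 42,
                             b = c(x1 = 0.7, x2 = -0.4)) {
  set.seed(seed)
  grid <- expand.grid(person_id = sprintf("i%02d", seq_len(n_id)), year = waves,
                      stringsAsFactors = FALSE)
  grid$prefecture_id <- rep(sprintf("p%d", 1:4), length.out = n_id)[
    match(grid$person_id, sprintf("i%02d", seq_len(n_id)))]
  fe <- stats::rnorm(n_id)
  names(fe) <- sprintf("i%02d", seq_len(n_id))
  grid$x1 <- stats::rnorm(nrow(grid))
  grid$x2 <- stats::rnorm(nrow(grid))
  grid$y <- 1 + b["x1"] * grid$x1 + b["x2"] * grid$x2 +
    fe[grid$person_id] + 0.2 * (grid$year == waves[2]) -
    0.1 * (grid$year == waves[3]) + stats::rnorm(nrow(grid), 0, 0.5)
  grid
}

## default small exposure table + panel from the generators, shared by tests
make_synth_bundle <- function(n_pref = 12, seed = 21, panel_args = list()) {
  cs <- corpus_spec(n_prefectures = n_pref, seed = seed)
  gen <- generate_corpus(cs)
  expo <- rescale(gen$exposure, 100)
  pargs <- utils::modifyList(list(seed = seed + 1), panel_args)
  pg <- do.call(panel_spec, pargs)
  out <- generate_panel(pg, expo)
  panel <- merge_exposures(out$panel, expo)
  list(corpus = gen, exposure = expo, panel = panel, truth = out$truth,
       instruments = out$instruments)
}

MODEL_REGRESSORS <- c(
  "uebmi_enrolled", "benefit_expansion", "cost_containment",
  "uebmi_enrolled:benefit_expansion", "uebmi_enrolled:cost_containment",
  "benefit_expansion:cost_containment",
  "uebmi_enrolled:benefit_expansion:cost_containment",
  "service_delivery", "pharmaceutical", "days_unable", "severity", "chronic",
  "utilization", "age", "schooling_years", "household_size", "log_income")

EXOG_REGRESSORS <- c(
  "benefit_expansion", "cost_containment", "service_delivery", "pharmaceutical",
  "days_unable", "severity", "chronic", "utilization", "age",
  "schooling_years", "household_size", "log_income")
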