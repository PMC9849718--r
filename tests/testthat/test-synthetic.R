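test_that("corpus generation is byte-deterministic and validates its spec", {
  spec <- corpus_spec(n_prefectures = 4, seed = 7)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(corpus_spec(n_prefectures = 4, seed = 7))
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(g1$docs, p1)
  write_corpus_jsonl(g2$docs, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  ## JSONL round trip preserves documents
  back <- read_corpus_jsonl(p1)
  expect_equal(back, g1$docs)
  expect_error(corpus_spec(expansion_propensity = 1.2), "\\[0, 1\\]")
  expect_error(corpus_spec(launch_year_range = c(1990, 2008)), "within years")
})

test_that("zero document rate yields an empty corpus with all-zero exposure truth", {
  g <- generate_corpus(corpus_spec(n_prefectures = 3, docs_per_year_rate = 0, seed = 1))
  expect_length(g$docs, 0)
  expect_true(all(g$exposure$benefit_expansion == 0))
  expect_true(all(g$exposure$cost_containment == 0))
  expect_identical(nrow(g$exposure), 3L * length(1997:2015))
})

test_that("degenerate propensities plant expansion-only keyword counts", {
  g <- generate_corpus(corpus_spec(n_prefectures = 4, expansion_propensity = 1,
                                   containment_propensity = 0,
                                   service_propensity = 0, pharma_propensity = 0,
                                   neutral_keyword_rate = 0, seed = 19))
  ue <- g$truth[g$truth$is_uebmi, ]
  expect_gt(nrow(ue), 0)
  expect_true(all(ue$benefit_expansion > 0))
  expect_true(all(ue$cost_containment == 0))
  expect_true(all(ue$service_delivery == 0))
  expect_true(all(ue$pharmaceutical == 0))
})

test_that("pre-launch documents contain no category keywords at all", {
  g <- generate_corpus(corpus_spec(n_prefectures = 6, seed = 37))
  lex <- demo_lexicon()
  kw <- names(lex$keyword_to_category)
  for (d in g$docs) {
    if (d$year >= g$launch_years[[d$prefecture_id]]) next
    expect_length(intersect(c(d$title_tokens, d$body_tokens), kw), 0)
  }
})

test_that("planted ground-truth counts equal a brute-force recount of the corpus", {
  g <- generate_corpus(corpus_spec(n_prefectures = 5, seed = 59))
  lex <- demo_lexicon()
  kws <- names(lex$keyword_to_category)
  truth_ids <- g$truth$doc_id
  for (d in g$docs[sample.int(length(g$docs), min(60, length(g$docs)))]) {
    want <- count_oracle(d, kws, lex)   # scan for ALL lexicon keywords
    got <- unlist(g$truth[match(d$doc_id, truth_ids),
                          c("benefit_expansion", "cost_containment",
                            "service_delivery", "pharmaceutical")])
    expect_identical(unname(got), unname(want))
  }
})

test_that("panel generation is deterministic and respects the null model", {
  b <- make_synth_bundle(n_pref = 3, seed = 61)
  pg1 <- generate_panel(panel_spec(seed = 5), b$exposure)
  pg2 <- generate_panel(panel_spec(seed = 5), b$exposure)
  expect_identical(pg1$panel, pg2$panel)
  ## null model: all coefficients, year effects and variances zero ->
  ## identical positive log spending everywhere
  zb <- list(b0 = 0, b1_enroll = 0, b2_expansion = 0, b3_containment = 0,
             b4_enroll_exp = 0, b5_enroll_cont = 0, b6_exp_cont = 0,
             b7_threeway = 0,
             lambda_supply = c(service_delivery = 0, pharmaceutical = 0),
             delta_covariates = c(days_unable = 0, severity = 0, chronic = 0,
                                  utilization = 0, age = 0, schooling_years = 0,
                                  household_size = 0, log_income = 0))
  null_spec <- panel_spec(beta = zb, sigma_individual_fe = 0, sigma_noise = 0,
                          year_effects = rep(0, 7), seed = 5)
  pg0 <- generate_panel(null_spec, b$exposure)
  pos <- pg0$panel$oop_raw[pg0$panel$oop_raw > 0]
  expect_gt(length(pos), 0)
  expect_equal(stats::sd(log(pos)), 0)
  ## missing exposure coverage names the offending prefecture-year
  short <- b$exposure[b$exposure$year != 2009, ]
  expect_error(generate_panel(panel_spec(seed = 5), short), "2009")
})

test_that("zero instrument loadings give near-zero instrument-enrolment correlation", {
  b <- make_synth_bundle(n_pref = 25, seed = 67, panel_args = list(
    n_individuals_per_prefecture_wave = 35,
    alpha = utils::modifyList(default_alpha(),
                              list(a_uebmi_pen = 0, a_gmi_pen = 0)),
    seed = 68))
  pan <- b$panel
  expect_gt(nrow(pan), 9000)
  expect_lt(abs(stats::cor(pan$uebmi_penetration, pan$uebmi_enrolled)), 0.05)
  expect_lt(abs(stats::cor(pan$gmi_penetration, pan$uebmi_enrolled)), 0.05)
})

test_that("zero-spending share matches the probit-implied probability", {
  for (p in c(0.3, 0.6, 0.85)) {
    b <- make_synth_bundle(n_pref = 20, seed = 73,
                           panel_args = list(p_spend_intercept = p, seed = 74))
    share_pos <- mean(b$panel$oop_raw > 0)
    se <- sqrt(p * (1 - p) / nrow(b$panel))
    expect_lt(abs(share_pos - p), 3 * se + 1e-12)
  }
})

test_that("doubling the entry cohort leaves covariate moments stable", {
  b1 <- make_synth_bundle(n_pref = 15, seed = 79,
                          panel_args = list(n_individuals_per_prefecture_wave = 10,
                                            seed = 80))
  b2 <- make_synth_bundle(n_pref = 15, seed = 79,
                          panel_args = list(n_individuals_per_prefecture_wave = 20,
                                            seed = 80))
  for (v in c("age", "schooling_years", "log_income", "household_size")) {
    m1 <- mean(b1$panel[[v]]); m2 <- mean(b2$panel[[v]])
    pooled_se <- sqrt(stats::var(b1$panel[[v]]) / nrow(b1$panel) +
                        stats::var(b2$panel[[v]]) / nrow(b2$panel))
    expect_lt(abs(m1 - m2), 4 * pooled_se)
  }
})

test_that("instrument tables correlate negatively as configured", {
  b <- make_synth_bundle(n_pref = 40, seed = 83)
  inst <- b$instruments
  r <- stats::cor(inst$uebmi_penetration, inst$gmi_penetration)
  expect_lt(r, 0)
})

test_that("uninsured observations are present in every wave", {
  b <- make_synth_bundle(n_pref = 10, seed = 89)
  by_wave <- tapply(b$panel$uebmi_enrolled, b$panel$year, function(x) sum(x == 0))
  expect_true(all(by_wave > 0))
})
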