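# policytextpanel

Measure locally heterogeneous health-insurance reform effort from
policy-document corpora, and estimate its effect on individual out-of-pocket
(OOP) health spending.

Chinese social health insurance (the urban employee scheme, UEBMI) is run by
prefectures, and prefectures differ in whether they push *benefit expansion*
(reimbursement rates, coverage catalogues, supplementary programs) or *cost
containment* (per-diem payment, global budgets, management of designated
facilities). This package turns the stream of prefectural policy documents
into prefecture-year exposure measures and fits the panel models that relate
them to spending:

* **Corpus**: title-relevance filtering; per-document top-5 keywords by
  TF-IDF (`tf × ln(N/df)`, deterministic tie-breaks); scheme-document
  selection by marker token in title or keywords.
* **Exposure**: extracted keywords are mapped to four reform categories
  through a lexicon; *neutral* keywords (e.g. `reimb_rate`) count only when
  a direction word (`increase`, `expand`, ...) falls within a token window;
  counts are aggregated per prefecture-year and cumulated from each
  prefecture's scheme launch year (zero before launch).
* **Panel**: deflate-and-log the outcome (`ln(deflated OOP + 1)`), merge
  exposures by prefecture-year, summarise.
* **Estimators**: two-way (individual + year) fixed effects equal to LSDV;
  fixed-effects 2SLS with first-stage F, Sargan overidentification and
  Wu–Hausman endogeneity diagnostics; delta-method linear combinations and
  interaction marginal-effect grids; two-part (probit + log-linear) model.
* **Synthetic data**: generators for a document corpus and an unbalanced
  individual panel with fully known ground truth, so the entire pipeline is
  testable without any restricted data.

The estimated macro model is

```
ln(OOPS_ijt) = b1·expansion_jt + b2·containment_jt
             + b3·expansion_jt × containment_jt
             + λ'Z_jt + δ'X_ijt + Y_t + I_i + e_ijt
```

with supply-side exposures `Z`, individual covariates `X`, year effects `Y_t`
and individual effects `I_i`; the micro model adds an (optionally
instrumented) enrolment dummy and its interactions up to the three-way term.

## Worked example

```r
library(policytextpanel)

gen <- generate_corpus(corpus_spec(n_prefectures = 20, seed = 42))
rel <- filter_relevant(gen$docs, c("medical", "medicine", "health", "disease",
                                   "hospital", "clinic", "outpatient",
                                   "hospitalization"))
ks  <- tfidf_keywords(rel, k = 5)
sel <- identify_uebmi_docs(rel, ks, "uebmi")
# 1178 docs -> 827 relevant -> 286 scheme docs

ks_sel <- ks[match(vapply(sel, `[[`, character(1), "doc_id"),
                   vapply(ks, `[[`, character(1), "doc_id"))]
counts <- count_corpus_categories(sel, ks_sel, demo_lexicon())
expo <- rescale(cumulate(aggregate_prefecture_year(counts), gen$launch_years,
                         years = 1997:2015), 100)
identical(as.data.frame(expo), as.data.frame(rescale(gen$exposure, 100)))
# TRUE — the pipeline recovers the planted ground truth exactly

pg  <- generate_panel(panel_spec(seed = 42), expo)
pan <- merge_exposures(pg$panel, expo)
pan$log_oop <- deflate_and_log(pan$oop_raw, pan$year,
                               setNames(rep(1, 7), sort(unique(pan$year))), 2015)
fit <- fit_twoway_fe(pan[pan$oop_raw > 0, ], "log_oop",
  c("benefit_expansion", "cost_containment",
    "benefit_expansion:cost_containment", "service_delivery", "pharmaceutical",
    "days_unable", "severity", "chronic", "utilization", "age",
    "schooling_years", "household_size", "log_income"))
fit
```

```
<fit_result: twoway_fe>  n = 1351, persons = 1011, within R2 = 0.669
  SEs: cluster = prefecture
                                   estimate     se      p
benefit_expansion                    0.4684 0.8874 0.5976
cost_containment                     0.5786 1.3074 0.6581
benefit_expansion:cost_containment  -0.4612 1.5960 0.7726
...
severity                             1.0302 0.1197 0.0000 ***
utilization                          1.8971 0.1455 0.0000 ***
...
  unidentified (no within variation): chronic, schooling_years
```

At this small demonstration scale the exposure coefficients are noisy but
centred near their planted values (expansion 0.4, interaction −0.55, severity
1.1, utilization 2.5); person-constant covariates are correctly flagged as
unidentified under individual fixed effects. Marginal effects of benefit
expansion across cost-containment levels:

```r
marginal_effects(fit, "benefit_expansion", "cost_containment",
                 grid = c(0, 0.2, 0.4, 0.6))
#   moderator effect    se  lower upper
# 1       0.0  0.468 0.887 -1.271 2.208
# 2       0.2  0.376 0.793 -1.178 1.931
# 3       0.4  0.284 0.821 -1.326 1.893
# 4       0.6  0.192 0.961 -1.692 2.075
```

The effect declines as cost-containment effort rises — the interaction the
synthetic world plants. `fit_fe_2sls()` instruments enrolment with the two
penetration rates, `fit_two_part()` gives the probit + log-linear robustness
model, and `run_pipeline(config)` drives the whole chain from a config list
or JSON file, writing hashed artifacts and a manifest (see
`inst/cli/policytextpanel.R` for the command-line wrapper).

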