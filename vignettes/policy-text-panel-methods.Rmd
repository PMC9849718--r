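---
title: "Measuring local insurance-reform effort from policy text and estimating its effect on out-of-pocket spending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: policy text exposures and panel estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(policytextpanel)
```

## The problem

Social health insurance in China is administered at the prefecture level, and
prefectures differ sharply in how they run the urban employee scheme (UEBMI):
some emphasise *benefit expansion* (higher reimbursement rates, wider coverage
catalogues, supplementary programs), others *cost containment* (prospective
payment such as per-diem and global budgets, management of designated
facilities, fee control). Administrative intensity of this kind is not
recorded in any statistical yearbook, but it is visible in the stream of
policy documents each prefecture issues. This package implements a
text-as-data measurement of that effort and the panel econometrics used to
relate it to individual out-of-pocket (OOP) health spending.

The pipeline is:

1. **Filter** documents whose titles mention health-related terms.
2. **Extract** each document's top five TF-IDF keywords.
3. **Select** scheme documents: the scheme marker token appears in the title
   or among the extracted keywords (a body-only mention that did not rank as
   a keyword is not enough).
4. **Score**: map extracted keywords to four reform categories via a lexicon,
   counting occurrences; *semantically neutral* keywords (e.g. a
   "reimbursement rate" can be raised or cut) count only when a direction
   word ("increase", "expand", ...) occurs within a token window around the
   occurrence.
5. **Cumulate** yearly category counts per prefecture from the prefecture's
   scheme launch year (zero before launch) into exposure measures
   $expansion_{jt}$ and $containment_{jt}$, plus two supply-side controls
   (service-delivery and pharmaceutical reforms).
6. **Estimate** the spending models below on an individual panel.

## Models

With $i$ indexing individuals, $j$ prefectures and $t$ survey years, the
macro model is the two-way fixed-effects regression

$$\ln(OOPS_{ijt}) = \beta_1\,expansion_{jt} + \beta_2\,containment_{jt}
  + \beta_3\,expansion_{jt} \times containment_{jt}
  + \lambda' Z_{jt} + \delta' X_{ijt} + Y_t + I_i + \varepsilon_{ijt},$$

where $Z_{jt}$ are the supply-side exposures, $X_{ijt}$ individual
covariates, and $Y_t$, $I_i$ year and individual fixed effects. The outcome
is $\ln(\text{deflated OOP} + 1)$, the $+1$ keeping zero spending in sample.
The micro model adds an enrolment dummy and its interactions with both
exposures up to the three-way term; because enrolment is a choice variable,
it is alternatively instrumented with two prefecture-level penetration rates
(the scheme's own penetration, and the penetration of the older
government-employee scheme it displaces) in a fixed-effects 2SLS.

`fit_twoway_fe()` computes the within-individual demeaned regression with
year dummies, which is numerically identical to least-squares dummy
variables; the test suite asserts that equality to 1e-8 on fixtures.
Interaction columns are products of *raw* columns built before demeaning
(demeaning a product of demeaned columns is not the LSDV estimand).
`fit_fe_2sls()` within-transforms everything and runs a linear first stage;
it reports the first-stage partial $F$ on the excluded instruments, the
Sargan overidentification statistic (when $\ge 2$ instruments), and a
regression-based Wu–Hausman endogeneity test. `lincom()` and
`marginal_effects()` provide delta-method inference on coefficient
combinations, e.g. the effect of benefit expansion at a grid of
cost-containment levels. `fit_two_part()` is the robustness specification:
a probit for any spending and a linear model for log positive spending.

## Design choices in open territory

* **TF-IDF variant.** Raw term frequency times $\ln(N/df)$, computed over
  the filtered input corpus, no smoothing or normalisation; smoothed idf and
  sublinear tf are available as switches. Ties break by ascending token so
  extraction is reproducible. Terms appearing in every document score zero
  and are excluded unless fewer than $k$ positive-score terms exist (a
  single-document corpus then falls back to ranking by raw frequency).
* **Only extracted keywords count.** Category counts come from the top-5
  keywords per document; `all_lexicon = TRUE` offers a sensitivity mode that
  scans every lexicon keyword.
* **Collocation window.** The source methodology does not state the window;
  the default is 5 tokens on either side, within the same field (title or
  body), configurable per lexicon.
* **Exposure scaling.** Raw cumulative counts reach the hundreds; a units
  divisor (default 100) is applied before regression so coefficients are
  readable, and the divisor is recorded in the table metadata and CSV
  header. It is never applied silently.
* **Standard errors.** Clustering level is configurable; the default is the
  prefecture, where the treatment varies. The CR1 small-sample factor counts
  absorbed individual effects only when individuals are not nested within
  clusters, so singleton clusters reproduce HC1 exactly.
* **Two-part binary part.** A probit with individual fixed effects is
  inconsistent on short panels (incidental parameters), so part 1 uses
  prefecture + year dummies; part 2 keeps individual fixed effects.
* **Forbidden regression.** The 2SLS first stage is linear; plugging fitted
  probit probabilities into the second stage is not offered.
* **First-stage covariates.** All exogenous regressors of the structural
  equation enter the first stage.
* **Severity.** Enters as a single ordinal score (0-3) by default, matching
  how the estimators' reference results report one severity row.
* **Listwise deletion.** Rows missing any model column are dropped with the
  count recorded on the fit, never silently.

## The synthetic world

Real inputs of this design (a national policy-document corpus; restricted
longitudinal survey microdata) cannot be shipped. The `synthetic_data`
module generates both with known ground truth; its defaults are the stated
world of the test suite, chosen once:

* 50 prefectures, years 1997-2015, launch years uniform on 1998-2008,
  Poisson(3) documents per prefecture-year, 70% title-relevant, 60% of
  relevant post-launch documents scheme-specific;
* scheme documents plant at most one keyword per category (expansion with
  probability 0.55, containment 0.35, supply categories 0.5/0.4) with 4+
  occurrences each; 30% of category mentions use a neutral keyword, each
  occurrence collocated with probability 0.8;
* panels with 10 entrants per prefecture-wave over the 7 survey waves and a
  55% per-wave dropout give roughly 6,000 observations, about 1.7 per
  person, mimicking the unbalanced structure of the reference survey;
* enrolment is Bernoulli-logit in the two penetration instruments (their
  loadings chosen a priori to give a strong first stage, as published
  first-stage F statistics for this design are in the hundreds; at synthetic
  scale the realised F is ~30-40); log positive spending follows the full
  structural equation with an exposure interaction of -0.55 and year effects
  trending upward by 0.05 per wave; spending is positive with probability
  0.6 (probit link), independent of the error, so the positive-spending
  subsample identifies the structural coefficients without selection bias.

Two deliberate departures from a literal world:

* **Age jitter.** Exact age = cohort + period is perfectly collinear with
  individual and year fixed effects, so measured age carries a ±1-year
  interview-timing jitter; without it no fixed-effects fit of age is
  possible at all.
* **Exogenous enrolment by default.** The confounder that motivates the IV
  enters the enrolment equation always, but loads on the outcome only in the
  documented endogenous variant (`gamma_confounder > 0`). The IV recovery
  tests additionally switch off the enrolment interactions, because the
  estimator instruments a single endogenous column; with interactions on,
  that IV regression would be misspecified by construction.

What a green test establishes: the extraction/scoring pipeline recovers
planted counts *exactly*; the estimators are unbiased for the planted
coefficients with confidence-interval coverage inside [0.90, 0.99] over 200
replicates. What it does not establish: anything about tokenizer quality,
lexicon completeness, or the published point estimates, which require the
restricted data.

## Numerical and degenerate-input behaviour

Regressors with no within-individual variation are reported as `NA` and
flagged rather than silently dropped; remaining collinearity is an error
naming the aliased columns. Just-identified IV models report the
overidentification test as not applicable rather than erroring. Degenerate
two-part splits (all or no spending positive) flag part 1; detected probit
separation withholds coefficients. Deterministic generation uses one RNG
sub-stream per prefecture, so enlarging the corpus never perturbs existing
prefectures, and fixed-seed pipeline runs are byte-identical (hashed in the
run manifest).

## Limitations

Tokenization is injected, not provided: the package consumes pre-tokenized
token sequences and ships only a transliterated demonstration lexicon. The
exposure measure counts keywords, not policy stringency; documents are
weighted by verbosity. Standard-error options do not include two-way
clustering. The two-part model's binary part conditions on prefecture, not
individual, heterogeneity.
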