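## Category lexicon: keyword -> reform category, plus the collocation rule for
## semantically neutral keywords (a neutral keyword such as "reimb_rate" names
## a quantity, not a direction; it only counts toward its category when a
## direction word such as "increase" occurs within `collocation_window` tokens).

EXPOSURE_CATEGORIES <- c("benefit_expansion", "cost_containment",
                         "service_delivery", "pharmaceutical")

#' Construct a category lexicon
#'
#' A lexicon maps keywords (single tokens, or multi-token phrases written as
#' space-separated tokens) to one of the four reform categories:
#' `benefit_expansion`, `cost_containment`, `service_delivery`,
#' `pharmaceutical`. Keywords listed in `neutral_keywords` are semantically
#' neutral: an occurrence contributes to its category only when one of the
#' `collocation_words` appears within `collocation_window` tokens on either
#' side of the occurrence, in the same field (title or body) of the document.
#'
#' @param keyword_to_category named character vector; names are keywords,
#'   values are categories.
#' @param neutral_keywords character vector, a subset of the lexicon keywords.
#' @param collocation_words character vector of direction words that qualify
#'   a neutral keyword occurrence.
#' @param collocation_window integer >= 1, number of tokens on either side of
#'   a neutral-keyword occurrence searched for a collocation word.
#' @return an object of class `category_lexicon`.
#' @export
category_lexicon <- function(keyword_to_category,
                             neutral_keywords = character(),
                             collocation_words = character(),
                             collocation_window = 5L) {
  assert_that(length(keyword_to_category) > 0 && !is.null(names(keyword_to_category)),
              "keyword_to_category must be a named character vector")
  bad <- setdiff(unique(unname(keyword_to_category)), EXPOSURE_CATEGORIES)
  assert_that(length(bad) == 0,
              paste0("unknown categories: ", paste(bad, collapse = ", ")))
  assert_that(is_count(collocation_window) && collocation_window >= 1,
              "collocation_window must be an integer >= 1")
  unknown <- setdiff(neutral_keywords, names(keyword_to_category))
  assert_that(length(unknown) == 0,
              paste0("neutral keywords not in lexicon: ", paste(unknown, collapse = ", ")))
  if (length(neutral_keywords) > 0)
    assert_that(length(collocation_words) > 0,
                "neutral keywords declared but no collocation words given")
  structure(list(keyword_to_category = keyword_to_category,
                 neutral_keywords = unique(neutral_keywords),
                 collocation_words = unique(collocation_words),
                 collocation_window = as.integer(collocation_window)),
            class = "category_lexicon")
}

#' @export
print.category_lexicon <- function(x, ...) {
  tab <- table(factor(x$keyword_to_category, levels = EXPOSURE_CATEGORIES))
  cat("<category_lexicon>\n")
  for (cc in EXPOSURE_CATEGORIES) cat(sprintf("  %-18s %d keywords\n", cc, tab[[cc]]))
  cat(sprintf("  neutral: %d, collocation words: %d, window: %d\n",
              length(x$neutral_keywords), length(x$collocation_words),
              x$collocation_window))
  invisible(x)
}

#' Built-in demonstration lexicon
#'
#' A small transliterated lexicon mirroring the kind of inventory used to
#' categorise employee-insurance policy keywords: benefit-expansion terms
#' (reimbursement rates, supplementary programs, coverage catalogue),
#' cost-containment terms (per-diem payment, global budgets, management of
#' designated facilities), supply-side service-delivery and pharmaceutical
#' terms. `reimb_rate` and `fee_control` are neutral and require a collocated
#' direction word. Tokens are opaque ASCII strings so no particular language
#' or tokenizer is assumed.
#'
#' @param collocation_window window passed to [category_lexicon()].
#' @return a `category_lexicon`.
#' @export
demo_lexicon <- function(collocation_window = 5L) {
  k2c <- c(
    reimb_rate        = "benefit_expansion",
    suppl_program     = "benefit_expansion",
    catalogue_scope   = "benefit_expansion",
    ceiling_raise     = "benefit_expansion",
    per_diem          = "cost_containment",
    global_budget     = "cost_containment",
    designated_facility_mgmt = "cost_containment",
    fee_control       = "cost_containment",
    referral_system   = "service_delivery",
    tiered_delivery   = "service_delivery",
    clinical_pathway  = "service_delivery",
    essential_medicines = "pharmaceutical",
    drug_procurement  = "pharmaceutical",
    drug_price_reg    = "pharmaceutical"
  )
  category_lexicon(
    keyword_to_category = k2c,
    neutral_keywords = c("reimb_rate", "fee_control"),
    collocation_words = c("increase", "enhance", "improve", "expand", "strengthen"),
    collocation_window = collocation_window
  )
}

#' Read a category lexicon from a structured text config
#'
#' Format: an optional `window: <int>` line, then bracketed sections. Each of
#' the four category sections lists one keyword per line (multi-token phrases
#' as space-separated tokens); `[neutral]` lists the neutral keywords and
#' `[collocations]` the direction words. Lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path file path.
#' @return a `category_lexicon`.
#' @export
read_lexicon <- function(path) {
  assert_that(file.exists(path), paste0("lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  window <- 5L
  k2c <- character()
  neutral <- character()
  colloc <- character()
  section <- NA_character_
  for (ln in lines) {
    if (grepl("^window\\s*:", ln)) {
      window <- as.integer(sub("^window\\s*:\\s*", "", ln))
      next
    }
    m <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(m) == 2) {
      section <- m[2]
      next
    }
    assert_that(!is.na(section), paste0("lexicon line outside any section: ", ln))
    if (section %in% EXPOSURE_CATEGORIES) {
      k2c[ln] <- section
    } else if (section == "neutral") {
      neutral <- c(neutral, ln)
    } else if (section == "collocations") {
      colloc <- c(colloc, ln)
    } else {
      stop2(paste0("unknown lexicon section: [", section, "]"))
    }
  }
  category_lexicon(k2c, neutral, colloc, window)
}

#' Write a category lexicon to its structured text format
#'
#' @param lexicon a `category_lexicon`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  out <- c(sprintf("window: %d", lexicon$collocation_window))
  for (cc in EXPOSURE_CATEGORIES) {
    kws <- names(lexicon$keyword_to_category)[lexicon$keyword_to_category == cc]
    out <- c(out, paste0("[", cc, "]"), kws)
  }
  out <- c(out, "[neutral]", lexicon$neutral_keywords,
           "[collocations]", lexicon$collocation_words)
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
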