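## End-to-end orchestration: simulate (or read) -> filter -> extract keywords
## -> select scheme documents -> score exposures -> merge panel -> fit models
## -> write artifacts + manifest. Single process, deterministic under a fixed
## seed; every artifact is hashed into the manifest.

#' Run the full pipeline
#'
#' In simulation mode (`config$simulate = TRUE`, the default) a corpus and a
#' panel are generated from `corpus_spec`/`panel_spec` blocks; otherwise
#' `corpus_file` (JSONL) and `panel_file` (CSV) are read. The corpus is
#' filtered for title relevance, top-k keywords are extracted, scheme
#' documents are selected, category counts are aggregated and cumulated into
#' an exposure table (rescaled by `config$divisor`, default 100), the outcome
#' is deflated and logged, exposures are merged, and each model spec in
#' `config$models` is fitted. All artifacts are written under
#' `config$out_dir` and hashed into the returned manifest.
#'
#' Config validation happens before any computation; identical config + seed
#' yields identical artifact hashes.
#'
#' @param config named list (or path to a JSON file): fields `out_dir`,
#'   `seed`, `simulate`, optional `corpus_spec` / `panel_spec` argument lists,
#'   `lexicon_file` (default: built-in demo lexicon), `corpus_file` /
#'   `panel_file` / `deflator` in non-simulation mode, `k` (keywords per
#'   document, default 5), `divisor` (default 100), `base_year`, and `models`
#'   (named list of model specs: `type` = "fe" | "iv" | "twopart", `outcome`,
#'   `regressors`, optional `endogenous`, `instruments`, `cluster`,
#'   `sample_filter`).
#' @return the run manifest (also written as `manifest.json`): per-artifact
#'   md5 hashes, per-stage counts, seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), paste0("config file not found: ", config))
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  ## ---- validation, before any compute ----
  assert_that(!is.null(config$out_dir), "config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  simulate <- isTRUE(config$simulate %||% TRUE)
  if (!is.null(config$lexicon_file)) {
    assert_that(file.exists(config$lexicon_file),
                paste0("lexicon file not found: ", config$lexicon_file))
    lexicon <- read_lexicon(config$lexicon_file)
  } else lexicon <- demo_lexicon()
  if (!simulate) {
    assert_that(!is.null(config$corpus_file) && file.exists(config$corpus_file),
                "non-simulation mode requires an existing corpus_file")
    assert_that(!is.null(config$panel_file) && file.exists(config$panel_file),
                "non-simulation mode requires an existing panel_file")
  }
  k <- as.integer(config$k %||% 5L)
  divisor <- as.numeric(config$divisor %||% 100)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- list()
  paths <- character()
  log_stage <- function(name, value) {
    counts[[name]] <<- value
    message(sprintf("[pipeline] %s: %s", name, paste(value, collapse = ", ")))
  }

  ## ---- corpus stage ----
  if (simulate) {
    cargs <- as.list(config$corpus_spec %||% list())
    cargs$seed <- cargs$seed %||% seed
    cspec <- do.call(corpus_spec, cargs)
    gen <- generate_corpus(cspec, lexicon)
    docs <- gen$docs
    launch_years <- gen$launch_years
    years <- cspec$years
    paths["corpus"] <- file.path(out_dir, "corpus.jsonl")
    write_corpus_jsonl(docs, paths["corpus"])
    paths["exposure_truth"] <- file.path(out_dir, "exposure_truth.csv")
    write_exposure_csv(rescale(gen$exposure, divisor), paths["exposure_truth"])
  } else {
    docs <- read_corpus_jsonl(config$corpus_file)
    launch_years <- unlist(config$launch_years)
    years <- sort(unique(vapply(docs, `[[`, integer(1), "year")))
  }
  log_stage("documents_in", length(docs))

  relevant <- filter_relevant(docs, config$relevance_tokens %||% RELEVANCE_TOKENS)
  log_stage("documents_relevant", length(relevant))

  keyword_sets <- if (length(relevant) > 0) tfidf_keywords(relevant, k = k) else list()
  paths["keywords"] <- file.path(out_dir, "keywords.jsonl")
  write_keywords_jsonl(keyword_sets, paths["keywords"])

  uebmi_docs <- identify_uebmi_docs(relevant, keyword_sets,
                                    config$uebmi_token %||% UEBMI_TOKEN)
  log_stage("documents_uebmi", length(uebmi_docs))

  ## ---- exposure stage ----
  ks_ids <- vapply(keyword_sets, `[[`, character(1), "doc_id")
  uebmi_ks <- keyword_sets[match(vapply(uebmi_docs, `[[`, character(1), "doc_id"), ks_ids)]
  doc_counts <- count_corpus_categories(uebmi_docs, uebmi_ks, lexicon)
  yearly <- aggregate_prefecture_year(doc_counts)
  exposure <- cumulate(yearly, launch_years, years = years)
  exposure <- rescale(exposure, divisor)
  paths["exposure"] <- file.path(out_dir, "exposure.csv")
  write_exposure_csv(exposure, paths["exposure"])
  log_stage("exposure_rows", nrow(exposure))

  ## ---- panel stage ----
  if (simulate) {
    pargs <- as.list(config$panel_spec %||% list())
    pargs$seed <- pargs$seed %||% seed
    pspec <- do.call(panel_spec, pargs)
    pgen <- generate_panel(pspec, exposure)
    panel <- pgen$panel
    paths["panel"] <- file.path(out_dir, "panel.csv")
    write_panel_csv(panel, paths["panel"])
  } else {
    panel <- read_panel_csv(config$panel_file)
  }
  log_stage("panel_rows_in", nrow(panel))

  deflator <- unlist(config$deflator %||%
                       stats::setNames(rep(1, length(unique(panel$year))),
                                       sort(unique(panel$year))))
  base_year <- config$base_year %||% max(panel$year)
  panel$log_oop <- deflate_and_log(panel$oop_raw, panel$year, deflator, base_year)
  analysis <- merge_exposures(panel, exposure, strict = isTRUE(config$strict %||% TRUE))
  log_stage("panel_rows_merged", nrow(analysis))
  log_stage("panel_rows_dropped", attr(analysis, "n_dropped"))
  paths["analysis"] <- file.path(out_dir, "analysis.csv")
  utils::write.csv(analysis, paths["analysis"], row.names = FALSE, quote = FALSE)

  summ <- panel_summary(analysis)
  paths["summary"] <- file.path(out_dir, "summary.tsv")
  write_summary_tsv(summ, paths["summary"])
  log_stage("persons", summ$n_persons)

  ## ---- model stage ----
  fits <- list()
  for (mname in names(config$models %||% list())) {
    m <- config$models[[mname]]
    fit <- switch(m$type %||% "fe",
      fe = fit_twoway_fe(analysis, m$outcome %||% "log_oop", m$regressors,
                         cluster = m$cluster %||% "prefecture",
                         sample_filter = m$sample_filter %||% "all"),
      iv = fit_fe_2sls(analysis, m$outcome %||% "log_oop", m$regressors,
                       endogenous = m$endogenous, instruments = m$instruments,
                       cluster = m$cluster %||% "prefecture",
                       sample_filter = m$sample_filter %||% "all"),
      twopart = fit_two_part(analysis, m$outcome %||% "oop_raw", m$regressors,
                             cluster = m$cluster %||% "prefecture",
                             sample_filter = m$sample_filter %||% "all"),
      stop2(paste0("unknown model type in spec ", mname, ": ", m$type)))
    fits[[mname]] <- fit
    paths[paste0("fit_", mname)] <- file.path(out_dir, paste0("fit_", mname, ".json"))
    write_fit_json(fit, paths[paste0("fit_", mname)])
  }
  if (length(fits) > 0) {
    paths["results"] <- file.path(out_dir, "results.tsv")
    write_results_tsv(fits, paths["results"])
  }

  manifest <- list(seed = seed,
                   hashes = as.list(tools::md5sum(unname(paths))),
                   stage_counts = counts)
  names(manifest$hashes) <- names(paths)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$fits <- fits
  invisible(manifest)
}

## machine-readable fit serialisation
write_fit_json <- function(fit, path) {
  obj <- if (inherits(fit, "fit_result")) fit_to_list(fit) else
    list(part1 = list(degenerate = fit$part1$degenerate,
                      separated = fit$part1$separated,
                      share_positive = fit$part1$share_positive,
                      coefficients = as.list(fit$part1$coefficients)),
         part2 = fit_to_list(fit$part2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

fit_to_list <- function(fit) {
  list(method = fit$method,
       coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       n_obs = fit$n_obs, n_persons = fit$n_persons,
       r2_within = fit$r2_within, cluster = fit$cluster,
       unidentified = fit$unidentified,
       diagnostics = fit$diagnostics)
}

## human-readable table: coefficient (SE) with significance stars at
## 0.10 / 0.05 / 0.01
write_results_tsv <- function(fits, path) {
  fits <- lapply(fits, function(f) if (inherits(f, "fit_result")) f else f$part2)
  all_terms <- unique(unlist(lapply(fits, function(f) f$regressors)))
  lines <- paste(c("term", names(fits)), collapse = "\t")
  for (tm in all_terms) {
    cells <- vapply(fits, function(f) {
      est <- f$coefficients[tm]
      if (is.null(est) || is.na(est)) return("")
      p <- fit_pvalue(f, est / f$se[tm])
      stars <- if (is.na(p)) "" else if (p < .01) "***" else if (p < .05) "**"
               else if (p < .10) "*" else ""
      sprintf("%.3f%s (%.3f)", est, stars, f$se[tm])
    }, character(1))
    lines <- c(lines, paste(c(tm, cells), collapse = "\t"))
  }
  nobs <- vapply(fits, function(f) as.character(f$n_obs), character(1))
  lines <- c(lines, paste(c("n_obs", nobs), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
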