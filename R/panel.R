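## Panel construction: deflate and log the out-of-pocket outcome, merge
## prefecture-year exposures into the individual panel, and summarise.

#' Deflate spending to a base year and take ln(x + 1)
#'
#' Spending is first deflated to base-year price levels using a user-supplied
#' index table (`deflated = raw * index(base_year) / index(year)`), then 1 is
#' added before taking the natural log so that zero spending maps to zero
#' rather than missing.
#'
#' @param oop_raw numeric vector of raw spending amounts (>= 0).
#' @param year survey year of each observation (recycled if length 1).
#' @param deflator named numeric vector, year -> price index (> 0), covering
#'   every survey year and the base year.
#' @param base_year the reference year spending is adjusted to.
#' @return numeric vector `ln(deflated + 1)`.
#' @export
deflate_and_log <- function(oop_raw, year, deflator, base_year) {
  year <- rep_len(as.character(year), length(oop_raw))
  need <- unique(c(year, as.character(base_year)))
  missing <- setdiff(need, names(deflator))
  assert_that(length(missing) == 0,
              paste0("deflator missing year(s): ", paste(missing, collapse = ", ")))
  assert_that(all(deflator[need] > 0), "deflator indices must be positive")
  deflated <- oop_raw * deflator[[as.character(base_year)]] / as.numeric(deflator[year])
  log1p(deflated)
}

#' Merge prefecture-year exposures into the individual panel
#'
#' Left join on (prefecture_id, year). Outcome and covariate columns are never
#' modified; only exposure columns (and launch_year) are appended. With
#' `strict = TRUE` (default) unmatched panel rows are an error listing the
#' offending keys; with `strict = FALSE` they are dropped with a warning
#' carrying the dropped count.
#'
#' @param panel data.frame with prefecture_id and year columns.
#' @param exposure an `exposure_table`.
#' @param strict error (TRUE) or drop-and-warn (FALSE) on unmatched rows.
#' @return the merged analysis panel; attribute `n_dropped` records drops.
#' @export
merge_exposures <- function(panel, exposure, strict = TRUE) {
  idx <- match(py_key(panel$prefecture_id, panel$year),
               py_key(exposure$prefecture_id, exposure$year))
  if (anyNA(idx)) {
    bad <- unique(paste0("(", panel$prefecture_id[is.na(idx)], ", ",
                         panel$year[is.na(idx)], ")"))
    if (strict)
      stop2(paste0("panel rows without exposure coverage: ",
                   paste(utils::head(bad, 10), collapse = ", ")))
    warning(sprintf("dropping %d panel rows without exposure coverage",
                    sum(is.na(idx))), call. = FALSE)
  }
  keep <- !is.na(idx)
  out <- panel[keep, , drop = FALSE]
  add <- c(EXPOSURE_CATEGORIES, "launch_year")
  for (cc in add) out[[cc]] <- exposure[[cc]][idx[keep]]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "divisor") <- attr(exposure, "divisor") %||% 1
  out
}

#' Summarise an analysis panel
#'
#' Per-variable n (non-missing), mean and SD (n-1 denominator; reported as NA
#' when fewer than two non-missing values), plus panel structure: number of
#' observations, distinct persons, and mean observations per person.
#'
#' @param panel non-empty data.frame; numeric/logical columns are summarised.
#' @param person_col name of the person identifier column.
#' @return list with `variables` (data.frame variable, n, mean, sd),
#'   `n_obs`, `n_persons`, `obs_per_person`.
#' @export
panel_summary <- function(panel, person_col = "person_id") {
  assert_that(is.data.frame(panel) && nrow(panel) > 0, "panel_summary: empty panel")
  num_cols <- names(panel)[vapply(panel, function(x) is.numeric(x) || is.logical(x), logical(1))]
  vars <- do.call(rbind, lapply(num_cols, function(v) {
    x <- as.numeric(panel[[v]])
    x <- x[!is.na(x)]
    data.frame(variable = v, n = length(x),
               mean = if (length(x) > 0) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  n_obs <- nrow(panel)
  n_persons <- if (person_col %in% names(panel))
    length(unique(panel[[person_col]])) else NA_integer_
  list(variables = vars, n_obs = n_obs, n_persons = n_persons,
       obs_per_person = if (!is.na(n_persons)) n_obs / n_persons else NA_real_)
}

#' Write a panel summary as TSV
#'
#' @param summary output of [panel_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# observations\t%d", summary$n_obs), con)
  writeLines(sprintf("# persons\t%d", summary$n_persons), con)
  writeLines(sprintf("# obs_per_person\t%.3f", summary$obs_per_person), con)
  utils::write.table(summary$variables, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop rows with missing values in model columns
#'
#' Listwise deletion restricted to the columns a model actually uses, with the
#' dropped count recorded (survey panels routinely lose rows to item
#' nonresponse; the drop is explicit here, never silent).
#'
#' @param panel data.frame.
#' @param cols columns that must be non-missing.
#' @return panel subset; attribute `n_dropped` records the number removed.
#' @export
drop_incomplete <- function(panel, cols) {
  missing_cols <- setdiff(cols, names(panel))
  assert_that(length(missing_cols) == 0,
              paste0("panel lacks column(s): ", paste(missing_cols, collapse = ", ")))
  ok <- stats::complete.cases(panel[cols])
  out <- panel[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}
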