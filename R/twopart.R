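## Two-part expenditure model: a probit for whether any spending occurs, and a
## two-way fixed-effects linear model for the log of positive spending.
## A probit with individual fixed effects is inconsistent on short panels
## (incidental parameters), so part 1 uses prefecture + year dummies instead;
## part 2 keeps the individual/year fixed-effects treatment.

#' Two-part model for spending outcomes
#'
#' Part 1 is a probit regression of `1{spending > 0}` on the regressors plus
#' year and prefecture dummies. Part 2 is [fit_twoway_fe()] of `ln(spending)`
#' on the positive-spending subsample. Degenerate splits (all observations
#' positive, or none) flag part 1 rather than fitting it; (quasi-)complete
#' separation in the probit is detected and flagged, with coefficients
#' withheld.
#'
#' @inheritParams fit_twoway_fe
#' @param outcome column holding raw (deflated) spending, not logged.
#' @return list with elements `part1` (list: model or NULL, `degenerate`,
#'   `separated`, `share_positive`) and `part2` (a `fit_result`, on the full
#'   sample when every observation is positive).
#' @export
fit_two_part <- function(panel, outcome, regressors,
                         id_col = "person_id", year_col = "year",
                         prefecture_col = "prefecture_id",
                         cluster = "prefecture", sample_filter = "all") {
  panel <- apply_sample_filter(panel, sample_filter)
  used_cols <- unique(c(outcome, unlist(strsplit(regressors, ":", fixed = TRUE)),
                        id_col, year_col, prefecture_col))
  panel <- drop_incomplete(panel, used_cols)
  spend <- as.numeric(panel[[outcome]])
  assert_that(all(spend >= 0), "spending outcome must be non-negative")
  pos <- spend > 0
  share_positive <- mean(pos)

  part1 <- list(model = NULL, coefficients = NULL,
                degenerate = FALSE, separated = FALSE,
                share_positive = share_positive)
  if (all(pos) || !any(pos)) {
    part1$degenerate <- TRUE
  } else {
    X <- build_design(panel, regressors)
    dat <- as.data.frame(X)
    names(dat) <- make.names(colnames(X))
    dat$.pos <- as.integer(pos)
    dat$.year <- factor(panel[[year_col]])
    dat$.pref <- factor(panel[[prefecture_col]])
    rhs <- paste(c(names(dat)[seq_len(ncol(X))], ".year", ".pref"), collapse = " + ")
    sep_warn <- FALSE
    gfit <- withCallingHandlers(
      stats::glm(stats::as.formula(paste(".pos ~", rhs)), data = dat,
                 family = stats::binomial(link = "probit")),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    ## a probit slope beyond ~8 on these scales only arises under
    ## (quasi-)complete separation
    huge <- any(abs(stats::coef(gfit)[seq_len(ncol(X)) + 1]) > 8, na.rm = TRUE)
    if (huge || (sep_warn && !gfit$converged)) {
      part1$separated <- TRUE               # coefficients withheld
    } else {
      cf <- stats::coef(gfit)
      names(cf)[seq_len(ncol(X)) + 1] <- colnames(X) # restore original names
      part1$model <- gfit
      part1$coefficients <- cf
    }
  }

  sub <- if (all(pos)) panel else panel[pos, , drop = FALSE]
  sub$.log_pos_spend <- log(as.numeric(sub[[outcome]]))
  part2 <- fit_twoway_fe(sub, ".log_pos_spend", regressors,
                         id_col = id_col, year_col = year_col,
                         prefecture_col = prefecture_col, cluster = cluster)
  list(part1 = part1, part2 = part2)
}
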