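## Two-way fixed-effects estimation by within-individual demeaning plus year
## dummies (numerically identical to least-squares dummy variables, LSDV).
## Interactions are written in regressor names with ":" and are constructed
## on the raw columns BEFORE demeaning, matching LSDV semantics.

## build the regressor matrix; names may contain ":" products of raw columns
build_design <- function(panel, regressors) {
  if (length(regressors) == 0)
    return(matrix(numeric(0), nrow = nrow(panel), ncol = 0,
                  dimnames = list(NULL, character(0))))
  cols <- lapply(regressors, function(r) {
    parts <- strsplit(r, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(panel))
    assert_that(length(missing) == 0,
                paste0("regressor ", r, " references unknown column(s): ",
                       paste(missing, collapse = ", ")))
    Reduce(`*`, lapply(parts, function(p) as.numeric(panel[[p]])))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- regressors
  X
}

## year dummies, first (reference) level dropped
year_dummies <- function(year) {
  lev <- sort(unique(year))
  if (length(lev) < 2) return(NULL)
  D <- vapply(lev[-1], function(t) as.numeric(year == t), numeric(length(year)))
  colnames(D) <- paste0("year_", lev[-1])
  D
}

## demean columns of M within groups g
within_demean <- function(M, g) {
  M <- as.matrix(M)
  sums <- rowsum(M, g, reorder = FALSE)
  n <- as.vector(rowsum(rep(1, nrow(M)), g, reorder = FALSE))
  means <- sums / n
  M - means[match(g, rownames(means)), , drop = FALSE]
}

apply_sample_filter <- function(panel, sample_filter, enroll_col = "uebmi_enrolled") {
  if (is.null(sample_filter) || identical(sample_filter, "all")) return(panel)
  assert_that(enroll_col %in% names(panel),
              paste0("sample filter needs column ", enroll_col))
  keep <- switch(sample_filter,
                 enrolled = panel[[enroll_col]] == 1,
                 uninsured = panel[[enroll_col]] == 0,
                 stop2(paste0("unknown sample_filter: ", sample_filter)))
  panel[keep, , drop = FALSE]
}

## sandwich or classical covariance on demeaned data.
## In the CR1 small-sample factor G/(G-1)*(N-1)/(N-K), absorbed individual
## effects are counted in K only when individuals are NOT nested within
## clusters (the usual absorbed-FE convention); with singleton clusters
## (never nested) the factor collapses to HC1's N/(N-K) with full K.
fe_vcov <- function(Xd, u, XtXinv, cluster_id, group_id, n_absorbed) {
  N <- nrow(Xd)
  df <- N - n_absorbed - ncol(Xd)
  if (is.null(cluster_id)) { # classical
    assert_that(df > 0, "no residual degrees of freedom")
    return(list(vcov = sum(u^2) / df * XtXinv, df = df, n_clusters = NA_integer_))
  }
  Xu <- Xd * u
  S <- crossprod(rowsum(Xu, cluster_id, reorder = FALSE))
  G <- length(unique(cluster_id))
  nested <- all(tapply(cluster_id, group_id,
                       function(cl) length(unique(cl)) == 1))
  K <- ncol(Xd) + if (nested) 0 else n_absorbed
  adj <- G / (G - 1) * (N - 1) / (N - K)
  list(vcov = adj * XtXinv %*% S %*% XtXinv, df = df, n_clusters = G)
}

resolve_cluster <- function(panel, cluster, id_col, prefecture_col) {
  if (is.null(cluster) || identical(cluster, "none")) return(NULL)
  col <- switch(cluster,
                prefecture = prefecture_col,
                individual = id_col,
                robust = NULL,
                stop2(paste0("unknown cluster option: ", cluster)))
  if (identical(cluster, "robust")) return(seq_len(nrow(panel))) # singletons = HC1
  as.character(panel[[col]])
}

#' Two-way fixed-effects regression
#'
#' Estimates a linear model with individual and year fixed effects by
#' within-individual demeaning of the outcome, regressors and year dummies;
#' coefficients equal the LSDV estimates with individual and year dummies.
#' Regressors whose within-individual variation is (numerically) zero are
#' unidentified under the within transform: they are flagged, reported as NA,
#' and excluded from the fit. Remaining collinearity is an error naming the
#' aliased columns.
#'
#' @param panel analysis data.frame.
#' @param outcome outcome column name.
#' @param regressors character vector of regressor names; interactions are
#'   spelled with `:` (e.g. `"benefit_expansion:cost_containment"`) and are
#'   built from the raw columns before demeaning.
#' @param id_col,year_col,prefecture_col identifier columns.
#' @param cluster `"prefecture"` (default), `"individual"`, `"robust"` (HC1),
#'   or `"none"` (classical).
#' @param sample_filter `"all"`, `"enrolled"` or `"uninsured"` (on
#'   `uebmi_enrolled`).
#' @param p_reference `"normal"` (default) or `"t"` (clusters-1 df when
#'   clustered, residual df otherwise).
#' @return a `fit_result`: coefficients (NA where unidentified), vcov, SEs,
#'   n_obs, n_persons, within R-squared, diagnostics slot (NULL here).
#' @export
fit_twoway_fe <- function(panel, outcome, regressors,
                          id_col = "person_id", year_col = "year",
                          prefecture_col = "prefecture_id",
                          cluster = "prefecture", sample_filter = "all",
                          p_reference = "normal") {
  panel <- apply_sample_filter(panel, sample_filter)
  used_cols <- unique(c(outcome, unlist(strsplit(regressors, ":", fixed = TRUE)),
                        id_col, year_col, prefecture_col))
  panel <- drop_incomplete(panel, used_cols)
  assert_that(nrow(panel) > 1, "too few observations after filtering")

  y <- as.numeric(panel[[outcome]])
  X <- build_design(panel, regressors)
  D <- year_dummies(panel[[year_col]])
  if (!is.null(D)) X <- cbind(X, D)
  g <- as.character(panel[[id_col]])

  yd <- within_demean(matrix(y, ncol = 1), g)[, 1]
  Xd <- within_demean(X, g)

  ## regressors annihilated by the within transform are unidentified
  scale_ <- pmax(apply(abs(X), 2, max), 1)
  dead <- apply(abs(Xd), 2, max) < 1e-10 * scale_
  unidentified <- colnames(X)[dead]
  Xd_fit <- Xd[, !dead, drop = FALSE]
  assert_that(ncol(Xd_fit) > 0, "no identified regressors after demeaning")

  qrX <- qr(Xd_fit)
  if (qrX$rank < ncol(Xd_fit)) {
    aliased <- colnames(Xd_fit)[qrX$pivot[(qrX$rank + 1):ncol(Xd_fit)]]
    stop2(paste0("collinear regressors after demeaning: ",
                 paste(aliased, collapse = ", ")))
  }
  beta <- qr.coef(qrX, yd)
  u <- yd - Xd_fit %*% beta
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(Xd_fit), colnames(Xd_fit))

  cl <- resolve_cluster(panel, cluster, id_col, prefecture_col)
  n_persons <- length(unique(g))
  vc <- fe_vcov(Xd_fit, as.vector(u), XtXinv, cl, g, n_absorbed = n_persons)

  coefs <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  coefs[names(beta)] <- beta
  tss <- sum(yd^2)
  r2_within <- if (tss > 0) 1 - sum(u^2) / tss else NA_real_

  new_fit_result(
    method = "twoway_fe",
    coefficients = coefs, vcov = vc$vcov,
    n_obs = nrow(panel), n_persons = n_persons,
    r2_within = r2_within, df_resid = vc$df,
    n_clusters = vc$n_clusters, cluster = cluster,
    p_reference = p_reference, unidentified = unidentified,
    regressors = regressors,
    ranges = apply(X[, regressors, drop = FALSE], 2, range),
    n_dropped = attr(panel, "n_dropped") %||% 0L
  )
}

## ---- fit_result container ----

new_fit_result <- function(method, coefficients, vcov, n_obs, n_persons,
                           r2_within, df_resid, n_clusters, cluster,
                           p_reference, unidentified, regressors, ranges,
                           n_dropped = 0L, diagnostics = NULL) {
  se <- stats::setNames(rep(NA_real_, length(coefficients)), names(coefficients))
  se[colnames(vcov)] <- sqrt(pmax(diag(vcov), 0))
  structure(list(method = method, coefficients = coefficients, vcov = vcov,
                 se = se, n_obs = n_obs, n_persons = n_persons,
                 r2_within = r2_within, df_resid = df_resid,
                 n_clusters = n_clusters, cluster = cluster,
                 p_reference = p_reference, unidentified = unidentified,
                 regressors = regressors, ranges = ranges,
                 n_dropped = n_dropped, diagnostics = diagnostics,
                 lincom_results = list()),
            class = "fit_result")
}

## inference reference distribution for a z-like statistic
fit_pvalue <- function(fit, z) {
  if (identical(fit$p_reference, "t")) {
    df <- if (!is.na(fit$n_clusters)) fit$n_clusters - 1 else fit$df_resid
    2 * stats::pt(-abs(z), df = df)
  } else {
    2 * stats::pnorm(-abs(z))
  }
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat(sprintf("<fit_result: %s>  n = %d, persons = %d, within R2 = %.3f\n",
              x$method, x$n_obs, x$n_persons, x$r2_within))
  if (!is.null(x$cluster)) cat(sprintf("  SEs: cluster = %s\n", x$cluster))
  est <- x$coefficients
  z <- est / x$se
  p <- fit_pvalue(x, z)
  stars <- ifelse(is.na(p), "", ifelse(p < .01, "***", ifelse(p < .05, "**",
                  ifelse(p < .10, "*", ""))))
  tab <- data.frame(estimate = round(est, digits), se = round(x$se, digits),
                    p = round(p, digits), ` ` = stars, check.names = FALSE)
  print(tab)
  if (length(x$unidentified) > 0)
    cat("  unidentified (no within variation):",
        paste(x$unidentified, collapse = ", "), "\n")
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  first-stage F = %.3f; overid p = %s; endogeneity p = %.3f\n",
                d$first_stage_F,
                if (is.na(d$overid_p)) "n/a (just identified)" else sprintf("%.3f", d$overid_p),
                d$endogeneity_p))
  }
  invisible(x)
}

#' Coefficients of a fit
#' @param object a `fit_result`.
#' @param ... unused.
#' @export
coef.fit_result <- function(object, ...) object$coefficients

#' Covariance matrix of a fit
#' @param object a `fit_result`.
#' @param ... unused.
#' @export
vcov.fit_result <- function(object, ...) object$vcov
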