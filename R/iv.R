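## Fixed-effects 2SLS: within-transform everything, then two-stage least
## squares with one endogenous regressor and excluded prefecture-level
## instruments, plus the standard diagnostic trio (first-stage F on the
## excluded instruments, Sargan/Hansen overidentification, regression-based
## Wu-Hausman endogeneity test).

#' Fixed-effects two-stage least squares
#'
#' Estimates the two-way fixed-effects model with one endogenous regressor
#' instrumented by excluded instruments. All variables (outcome, exogenous
#' regressors, year dummies, endogenous regressor, instruments) are
#' within-individual demeaned first; 2SLS is then applied with a linear first
#' stage. A fitted-probability plug-in first stage (the "forbidden
#' regression") is deliberately not offered.
#'
#' Diagnostics reported in `$diagnostics`:
#' * `first_stage_F`: partial F-statistic of the excluded instruments in the
#'   first stage;
#' * `overid_stat`, `overid_p`: Sargan statistic (n R-squared of the 2SLS
#'   residual on the full instrument set), chi-squared with
#'   (instruments - 1) df; `NA` with a note when just identified;
#' * `endogeneity_stat`, `endogeneity_p`: regression-based Wu-Hausman test
#'   (structural equation augmented with the first-stage residual; t-test on
#'   its coefficient).
#'
#' @inheritParams fit_twoway_fe
#' @param endogenous name of the endogenous regressor column.
#' @param instruments character vector (>= 1) of excluded instrument columns;
#'   must not appear among `regressors`.
#' @return a `fit_result` with the endogenous coefficient first and the
#'   diagnostics slot populated.
#' @export
fit_fe_2sls <- function(panel, outcome, regressors, endogenous, instruments,
                        id_col = "person_id", year_col = "year",
                        prefecture_col = "prefecture_id",
                        cluster = "prefecture", sample_filter = "all",
                        p_reference = "normal") {
  assert_that(length(instruments) >= 1, "at least one instrument required")
  assert_that(!endogenous %in% regressors,
              "endogenous regressor must not be listed among exogenous regressors")
  overlap <- intersect(instruments, regressors)
  assert_that(length(overlap) == 0,
              paste0("instruments also listed as regressors: ",
                     paste(overlap, collapse = ", ")))

  panel <- apply_sample_filter(panel, sample_filter)
  used_cols <- unique(c(outcome, endogenous, instruments,
                        unlist(strsplit(regressors, ":", fixed = TRUE)),
                        id_col, year_col, prefecture_col))
  panel <- drop_incomplete(panel, used_cols)

  y <- as.numeric(panel[[outcome]])
  Xex <- build_design(panel, regressors)
  D <- year_dummies(panel[[year_col]])
  if (!is.null(D)) Xex <- cbind(Xex, D)
  endo <- build_design(panel, endogenous)
  Zx <- build_design(panel, instruments)
  g <- as.character(panel[[id_col]])

  yd <- within_demean(matrix(y, ncol = 1), g)[, 1]
  Xex_d <- within_demean(Xex, g)
  endo_d <- within_demean(endo, g)[, 1]
  Zx_d <- within_demean(Zx, g)

  scale_ <- pmax(apply(abs(Xex), 2, max), 1)
  dead <- apply(abs(Xex_d), 2, max) < 1e-10 * scale_
  unidentified <- colnames(Xex)[dead]
  Xex_d <- Xex_d[, !dead, drop = FALSE]
  assert_that(max(abs(endo_d)) > 1e-10,
              "endogenous regressor has no within-individual variation")
  assert_that(all(apply(abs(Zx_d), 2, max) > 1e-10),
              "an instrument has no within-individual variation")

  Z <- cbind(Zx_d, Xex_d)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop2("first-stage design is rank deficient")

  ## first stage and 2SLS second stage
  fs_coef <- qr.coef(qrZ, endo_d)
  endo_hat <- as.vector(Z %*% fs_coef)
  fs_resid <- endo_d - endo_hat

  X <- cbind(endo_d, Xex_d)
  colnames(X)[1] <- endogenous
  Xhat <- cbind(endo_hat, Xex_d)
  colnames(Xhat)[1] <- endogenous
  qrXh <- qr(Xhat)
  if (qrXh$rank < ncol(Xhat)) stop2("2SLS projected design is rank deficient")
  beta <- qr.coef(qrXh, yd)
  u <- as.vector(yd - X %*% beta)  # residuals at actual (not projected) X

  XtXinv <- chol2inv(qr.R(qrXh))
  dimnames(XtXinv) <- list(colnames(Xhat), colnames(Xhat))
  cl <- resolve_cluster(panel, cluster, id_col, prefecture_col)
  n_persons <- length(unique(g))
  vc <- fe_vcov(Xhat, u, XtXinv, cl, g, n_absorbed = n_persons)

  ## --- diagnostics ---
  N <- length(yd)
  df_fs <- N - n_persons - ncol(Z)
  rss_u <- sum(fs_resid^2)
  if (ncol(Xex_d) > 0) {
    fs_r <- qr.resid(qr(Xex_d), endo_d)
  } else fs_r <- endo_d
  rss_r <- sum(fs_r^2)
  q <- ncol(Zx_d)
  first_stage_F <- ((rss_r - rss_u) / q) / (rss_u / df_fs)
  first_stage_F_p <- stats::pf(first_stage_F, q, df_fs, lower.tail = FALSE)

  if (q >= 2) {
    e_on_z <- qr.resid(qrZ, u)
    overid_stat <- N * (1 - sum(e_on_z^2) / sum(u^2))
    overid_p <- stats::pchisq(overid_stat, df = q - 1, lower.tail = FALSE)
  } else {
    overid_stat <- NA_real_
    overid_p <- NA_real_
  }

  ## Wu-Hausman: augment structural equation with the first-stage residual
  Xa <- cbind(X, wu_resid = fs_resid)
  qrA <- qr(Xa)
  ba <- qr.coef(qrA, yd)
  ua <- yd - Xa %*% ba
  dfa <- N - n_persons - ncol(Xa)
  s2a <- sum(ua^2) / dfa
  Va <- s2a * chol2inv(qr.R(qrA))
  t_wu <- ba[["wu_resid"]] / sqrt(Va[ncol(Xa), ncol(Xa)])
  endogeneity_p <- 2 * stats::pt(-abs(t_wu), df = dfa)

  coefs <- stats::setNames(rep(NA_real_, 1 + ncol(Xex)),
                           c(endogenous, colnames(Xex)))
  coefs[names(beta)] <- beta
  tss <- sum(yd^2)

  fit <- new_fit_result(
    method = "fe_2sls",
    coefficients = coefs, vcov = vc$vcov,
    n_obs = N, n_persons = n_persons,
    r2_within = if (tss > 0) 1 - sum(u^2) / tss else NA_real_,
    df_resid = vc$df, n_clusters = vc$n_clusters, cluster = cluster,
    p_reference = p_reference, unidentified = unidentified,
    regressors = c(endogenous, regressors),
    ranges = apply(cbind(endo, Xex[, regressors, drop = FALSE]), 2, range),
    n_dropped = attr(panel, "n_dropped") %||% 0L,
    diagnostics = list(first_stage_F = first_stage_F,
                       first_stage_F_p = first_stage_F_p,
                       n_instruments = q,
                       overid_stat = overid_stat, overid_p = overid_p,
                       overid_note = if (q < 2) "not applicable (just identified)" else NULL,
                       endogeneity_stat = unname(t_wu),
                       endogeneity_p = unname(endogeneity_p))
  )
  fit
}
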