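## Post-estimation inference: linear combinations of coefficients (delta
## method) and interaction marginal-effects grids.

## parse "b1 + 0.5*b2 - b3" into a named weight vector
parse_contrast <- function(expr) {
  s <- gsub("\\s+", "", expr)
  s <- gsub("-", "+-", s, fixed = TRUE)
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  terms <- terms[nzchar(terms)]
  w <- numeric()
  for (tm in terms) {
    sign <- 1
    if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
    parts <- strsplit(tm, "*", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    is_num <- !is.na(num)
    assert_that(sum(!is_num) == 1,
                paste0("cannot parse contrast term: ", tm))
    coefname <- parts[!is_num]
    weight <- sign * prod(num[is_num], 1)
    w[coefname] <- (if (coefname %in% names(w)) w[[coefname]] else 0) + weight
  }
  w
}

#' Linear combination of fitted coefficients
#'
#' Computes a contrast c'beta with delta-method standard error sqrt(c'Vc) and
#' a two-sided p-value (normal reference by default, following the fit's
#' `p_reference`).
#'
#' @param fit a `fit_result`.
#' @param contrast either a named numeric vector of weights over coefficient
#'   names, or a character expression such as
#'   `"uebmi_enrolled + 0.5*uebmi_enrolled:cost_containment"`.
#' @return list with `estimate`, `se`, `z`, `p`, and the `contrast` weights.
#' @export
lincom <- function(fit, contrast) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  assert_that(is.numeric(contrast) && !is.null(names(contrast)),
              "contrast must be a named numeric vector or an expression string")
  unknown <- setdiff(names(contrast), names(fit$coefficients))
  assert_that(length(unknown) == 0,
              paste0("unknown coefficient(s) in contrast: ",
                     paste(unknown, collapse = ", ")))
  dead <- intersect(names(contrast)[contrast != 0], fit$unidentified)
  assert_that(length(dead) == 0,
              paste0("contrast uses unidentified coefficient(s): ",
                     paste(dead, collapse = ", ")))
  cvec <- stats::setNames(numeric(ncol(fit$vcov)), colnames(fit$vcov))
  cvec[names(contrast)] <- contrast
  est <- sum(cvec * fit$coefficients[names(cvec)])
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  z <- est / se
  list(estimate = est, se = se, z = z, p = fit_pvalue(fit, z),
       contrast = contrast)
}

## map each coefficient involving `focal` to its moderator weight builder
margin_weights <- function(fit, focal, moderator, fixed) {
  coef_names <- colnames(fit$vcov)
  out <- list()
  found_interaction <- FALSE
  for (nm in coef_names) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!(focal %in% parts)) next
    others <- parts[parts != focal]
    if (length(parts) - length(others) != 1) next # focal^2 terms unsupported
    known <- others %in% c(moderator, names(fixed))
    assert_that(all(known),
                paste0("coefficient ", nm, " involves ", paste(others[!known],
                       collapse = ", "), "; fix its value via `fixed`"))
    if (moderator %in% others) found_interaction <- TRUE
    const <- prod(vapply(others[others != moderator],
                         function(f) as.numeric(fixed[[f]]), numeric(1)), 1)
    out[[nm]] <- list(const = const, with_m = moderator %in% others)
  }
  assert_that(length(out) > 0, paste0("fit contains no coefficient on ", focal))
  assert_that(found_interaction,
              paste0("fit contains no ", focal, ":", moderator, " interaction"))
  out
}

#' Marginal effect of a focal regressor across moderator values
#'
#' For a fit containing `focal`, `focal:moderator` (and optionally higher
#' interactions whose remaining variables are pinned via `fixed`), computes
#' `effect(m) = beta_focal + beta_interaction * m + ...` over a grid of
#' moderator values with delta-method confidence intervals.
#'
#' @param fit a `fit_result`.
#' @param focal focal regressor name.
#' @param moderator moderator regressor name.
#' @param grid numeric vector of moderator values; defaults to 21 points over
#'   the moderator's observed range. Values outside the observed range trigger
#'   a warning, not an error.
#' @param fixed named list pinning any further interacted variables (e.g. the
#'   second moderator of a three-way term).
#' @param level confidence level (default 0.95).
#' @return data.frame (moderator value, effect, se, lower, upper), sorted by
#'   moderator value.
#' @export
marginal_effects <- function(fit, focal, moderator, grid = NULL,
                             fixed = list(), level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  rng <- if (moderator %in% colnames(fit$ranges)) fit$ranges[, moderator] else NULL
  if (is.null(grid)) {
    assert_that(!is.null(rng), paste0("no observed range stored for ", moderator,
                                      "; supply `grid`"))
    grid <- seq(rng[1], rng[2], length.out = 21)
  }
  grid <- sort(as.numeric(grid))
  if (!is.null(rng) && (min(grid) < rng[1] - 1e-12 || max(grid) > rng[2] + 1e-12))
    warning("marginal-effects grid extends outside the observed moderator range",
            call. = FALSE)

  wts <- margin_weights(fit, focal, moderator, fixed)
  coef_names <- colnames(fit$vcov)
  C <- matrix(0, nrow = length(grid), ncol = length(coef_names),
              dimnames = list(NULL, coef_names))
  for (nm in names(wts)) {
    w <- wts[[nm]]
    C[, nm] <- if (w$with_m) w$const * grid else w$const
  }
  beta <- fit$coefficients[coef_names]
  effect <- drop(C %*% beta)
  se <- sqrt(pmax(rowSums((C %*% fit$vcov) * C), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(moderator = grid, effect = effect, se = se,
             lower = effect - zq * se, upper = effect + zq * se)
}
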