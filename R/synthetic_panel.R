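## Synthetic unbalanced individual panel with known ground truth. The data
## generating process mirrors the estimated models: enrolment is Bernoulli
## with a logit linear in two prefecture-level instruments (scheme penetration
## and a negatively correlated substitute-program penetration), covariates and
## a time-varying confounder; spending is two-part - positive with a
## probit-link probability, and log positive spending equal to the structural
## linear predictor (enrolment, the two exposures, all their interactions,
## supply-side and individual covariates, year effects, an individual fixed
## effect) plus noise. The confounder enters the outcome only when
## `gamma_confounder != 0`, which is the documented endogenous-enrolment
## variant used to exercise the IV estimator.

#' Default structural coefficients of the synthetic panel
#'
#' Magnitudes are anchored to the scale of published two-way fixed-effects
#' estimates for this outcome (e.g. severity ~ 1.1, utilization ~ 2.5, an
#' exposure interaction near -0.55 on exposures rescaled to ~unit magnitude).
#' @return named list of coefficients.
#' @export
default_beta <- function() {
  list(b0 = 0.5, b1_enroll = 0.1, b2_expansion = 0.4, b3_containment = 0.3,
       b4_enroll_exp = 0.2, b5_enroll_cont = -0.3, b6_exp_cont = -0.55,
       b7_threeway = -0.25,
       lambda_supply = c(service_delivery = 0.08, pharmaceutical = -0.15),
       delta_covariates = c(days_unable = 0.05, severity = 1.1, chronic = 0.1,
                            utilization = 2.5, age = 0.01,
                            schooling_years = -0.01, household_size = 0,
                            log_income = 0.02))
}

#' Default enrolment-equation coefficients
#'
#' Instrument loadings are strong by design (published first-stage F
#' statistics for this design are in the hundreds).
#' @return named list.
#' @export
default_alpha <- function() {
  list(a0 = -1.6, a_uebmi_pen = 6, a_gmi_pen = -3.5, a_confounder = 1,
       a_age = 0.01, a_income = 0.2)
}

#' Specification of a synthetic individual panel
#'
#' @param n_individuals_per_prefecture_wave number of NEW individuals entering
#'   the panel per prefecture per wave.
#' @param waves survey years (ascending).
#' @param beta structural coefficients, see [default_beta()].
#' @param alpha enrolment-equation coefficients, see [default_alpha()].
#' @param gamma_confounder loading of the time-varying confounder in the
#'   outcome; 0 (default) makes enrolment exogenous, > 0 gives the
#'   endogenous-enrolment variant for IV testing.
#' @param year_effects named numeric vector of year effects (one per wave);
#'   default a mild upward trend.
#' @param sigma_individual_fe,sigma_noise standard deviations (> 0 unless the
#'   degenerate null model is wanted; 0 is allowed).
#' @param p_spend_intercept baseline probability of any spending.
#' @param p_spend_severity probit-index loading on illness severity
#'   (default 0: the zero-spending share then converges to
#'   `1 - p_spend_intercept` exactly).
#' @param attrition_rate per-wave probability an individual is not
#'   re-observed (monotone dropout).
#' @param instrument_cor target correlation between the two penetration
#'   instruments (negative: the substitute program is being displaced).
#' @param seed RNG seed.
#' @return a `panel_spec`.
#' @export
panel_spec <- function(n_individuals_per_prefecture_wave = 10L,
                       waves = c(1997L, 2000L, 2004L, 2006L, 2009L, 2011L, 2015L),
                       beta = default_beta(),
                       alpha = default_alpha(),
                       gamma_confounder = 0,
                       year_effects = NULL,
                       sigma_individual_fe = 0.8,
                       sigma_noise = 1,
                       p_spend_intercept = 0.6,
                       p_spend_severity = 0,
                       attrition_rate = 0.55,
                       instrument_cor = -0.3,
                       seed = 1L) {
  assert_that(is_count(n_individuals_per_prefecture_wave) &&
                n_individuals_per_prefecture_wave >= 1,
              "n_individuals_per_prefecture_wave must be >= 1")
  waves <- as.integer(waves)
  assert_that(!is.unsorted(waves, strictly = TRUE), "waves must be sorted ascending")
  assert_that(sigma_individual_fe >= 0 && sigma_noise >= 0,
              "sigma values must be non-negative")
  assert_that(p_spend_intercept > 0 && p_spend_intercept <= 1,
              "p_spend_intercept must be in (0, 1]")
  assert_that(attrition_rate >= 0 && attrition_rate <= 1,
              "attrition_rate must be in [0, 1]")
  if (is.null(year_effects))
    year_effects <- stats::setNames(0.05 * (seq_along(waves) - 1), waves)
  assert_that(length(year_effects) == length(waves),
              "year_effects must have one value per wave")
  names(year_effects) <- waves
  structure(list(n_individuals_per_prefecture_wave =
                   as.integer(n_individuals_per_prefecture_wave),
                 waves = waves, beta = beta, alpha = alpha,
                 gamma_confounder = gamma_confounder,
                 year_effects = year_effects,
                 sigma_individual_fe = sigma_individual_fe,
                 sigma_noise = sigma_noise,
                 p_spend_intercept = p_spend_intercept,
                 p_spend_severity = p_spend_severity,
                 attrition_rate = attrition_rate,
                 instrument_cor = instrument_cor,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

## prefecture-wave instrument tables: scheme penetration rises over time with
## prefecture-specific level and trend; substitute-program penetration is
## built from a latent negatively correlated with the scheme latent
generate_instruments <- function(prefectures, waves, instrument_cor, seed) {
  set.seed(derive_seed(seed, 999983L))
  rows <- list()
  r <- instrument_cor
  for (p in seq_along(prefectures)) {
    ## strong prefecture-specific rollout trends: scheme penetration climbs
    ## from near zero at markedly different speeds (common trends are absorbed
    ## by year fixed effects; identification rides on the heterogeneity)
    base_u <- stats::rnorm(1)
    trend_u <- stats::rnorm(1, 0.55, 0.35)
    z_g <- stats::rnorm(1)
    base_g <- r * base_u + sqrt(max(0, 1 - r^2)) * z_g
    trend_g <- stats::rnorm(1, -0.3, 0.2)
    ti <- seq_along(waves) - 1
    lat_u <- -2.2 + base_u + trend_u * ti + stats::rnorm(length(ti), 0, 0.5)
    lat_g <- -0.5 + base_g + trend_g * ti + stats::rnorm(length(ti), 0, 0.5)
    rows[[p]] <- data.frame(prefecture_id = prefectures[p], year = waves,
                            uebmi_penetration = stats::plogis(lat_u),
                            gmi_penetration = stats::plogis(lat_g),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic individual panel
#'
#' @param spec a [panel_spec()].
#' @param exposure an `exposure_table` covering every prefecture-wave; the
#'   exposure columns are used AS GIVEN (rescale before calling if desired).
#' @return list with `panel` (data.frame of observations; exposure columns are
#'   NOT included - they are merged downstream), `truth` (list: beta, alpha,
#'   gamma_confounder, year_effects, individual_fe, confounder per
#'   observation, linpred per observation, positive-spending probability) and
#'   `instruments` (prefecture-wave table).
#' @export
generate_panel <- function(spec, exposure) {
  stopifnot(inherits(spec, "panel_spec"))
  prefectures <- sort(unique(exposure$prefecture_id))
  need <- expand.grid(prefecture_id = prefectures, year = spec$waves,
                      stringsAsFactors = FALSE)
  miss <- !(py_key(need$prefecture_id, need$year) %in%
              py_key(exposure$prefecture_id, exposure$year))
  if (any(miss)) {
    bad <- paste0("(", need$prefecture_id[miss], ", ", need$year[miss], ")")
    stop2(paste0("exposure table does not cover prefecture-wave(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  inst <- generate_instruments(prefectures, spec$waves, spec$instrument_cor, spec$seed)
  ekey <- py_key(exposure$prefecture_id, exposure$year)
  ikey <- py_key(inst$prefecture_id, inst$year)
  b <- spec$beta; a <- spec$alpha
  n_new <- spec$n_individuals_per_prefecture_wave
  waves <- spec$waves

  W <- length(waves)
  pref_frames <- vector("list", length(prefectures))
  fe_frames <- vector("list", length(prefectures))
  for (p in seq_along(prefectures)) {
    pref <- prefectures[p]
    set.seed(derive_seed(spec$seed, p))

    ## person-level draws (one cohort of n_new entrants per wave)
    n_persons <- n_new * W
    entry <- rep(seq_len(W), each = n_new)
    pid <- sprintf("%s-%02d-%04d", pref, entry, rep(seq_len(n_new), W))
    fe_i <- stats::rnorm(n_persons, 0, spec$sigma_individual_fe)
    age0 <- pmin(pmax(stats::rnorm(n_persons, 40, 12), 18), 60)
    school <- pmin(pmax(round(stats::rnorm(n_persons, 9.5, 3.5)), 0), 18)
    chronic <- as.integer(stats::runif(n_persons) < 0.042)
    inc_i <- stats::rnorm(n_persons, 0, 0.8)

    ## monotone dropout: observed in entry wave, survives each later wave
    ## with probability 1 - attrition_rate
    n_obs_p <- vapply(seq_len(n_persons), function(j) {
      avail <- W - entry[j]
      if (avail == 0) return(1L)
      u <- stats::runif(avail)
      fail <- which(u < spec$attrition_rate)
      1L + if (length(fail) == 0) avail else fail[1] - 1L
    }, integer(1))

    idx <- rep(seq_len(n_persons), n_obs_p)
    wave_idx <- unlist(lapply(seq_len(n_persons),
                              function(j) entry[j] + seq_len(n_obs_p[j]) - 1L),
                       use.names = FALSE)
    n_obs <- length(idx)
    sev <- sample(0:3, n_obs, replace = TRUE, prob = c(0.856, 0.059, 0.071, 0.014))
    pref_frames[[p]] <- data.frame(
      person_id = pid[idx], prefecture_id = pref, year = waves[wave_idx],
      days_unable = ifelse(sev == 0, 0L, stats::rpois(n_obs, 2)),
      severity = sev, chronic = chronic[idx],
      utilization = as.integer(stats::runif(n_obs) < stats::plogis(-2.5 + 1.2 * sev)),
      ## +/- 1-year interview-timing jitter: without it, age would be exactly
      ## collinear with individual + year fixed effects (age = cohort + period)
      age = age0[idx] + waves[wave_idx] - waves[entry[idx]] +
        sample(c(-1L, 0L, 0L, 1L), n_obs, replace = TRUE),
      schooling_years = school[idx],
      household_size = 1L + stats::rpois(n_obs, 2.7),
      log_income = stats::rnorm(n_obs, 9, 1) + inc_i[idx] + 0.03 * (wave_idx - 1),
      confounder = stats::rnorm(n_obs),
      u_enroll = stats::runif(n_obs), u_pos = stats::runif(n_obs),
      eps = stats::rnorm(n_obs, 0, spec$sigma_noise),
      individual_fe = fe_i[idx], stringsAsFactors = FALSE)
    fe_frames[[p]] <- data.frame(person_id = pid, individual_fe = fe_i,
                                 stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, pref_frames)
  fe_rows <- fe_frames

  m_inst <- match(py_key(panel$prefecture_id, panel$year), ikey)
  panel$uebmi_penetration <- inst$uebmi_penetration[m_inst]
  panel$gmi_penetration <- inst$gmi_penetration[m_inst]
  m_exp <- match(py_key(panel$prefecture_id, panel$year), ekey)
  expn <- exposure$benefit_expansion[m_exp]
  cont <- exposure$cost_containment[m_exp]
  serv <- exposure$service_delivery[m_exp]
  pharm <- exposure$pharmaceutical[m_exp]

  ## enrolment: Bernoulli with logit linear in instruments, covariates,
  ## confounder
  lin_enroll <- a$a0 + a$a_uebmi_pen * panel$uebmi_penetration +
    a$a_gmi_pen * panel$gmi_penetration +
    a$a_confounder * panel$confounder +
    a$a_age * (panel$age - 40) + a$a_income * (panel$log_income - 9)
  panel$uebmi_enrolled <- as.integer(panel$u_enroll < stats::plogis(lin_enroll))

  dcov <- b$delta_covariates
  linpred <- b$b0 +
    b$b1_enroll * panel$uebmi_enrolled +
    b$b2_expansion * expn + b$b3_containment * cont +
    b$b4_enroll_exp * panel$uebmi_enrolled * expn +
    b$b5_enroll_cont * panel$uebmi_enrolled * cont +
    b$b6_exp_cont * expn * cont +
    b$b7_threeway * panel$uebmi_enrolled * expn * cont +
    b$lambda_supply[["service_delivery"]] * serv +
    b$lambda_supply[["pharmaceutical"]] * pharm +
    dcov[["days_unable"]] * panel$days_unable + dcov[["severity"]] * panel$severity +
    dcov[["chronic"]] * panel$chronic + dcov[["utilization"]] * panel$utilization +
    dcov[["age"]] * panel$age + dcov[["schooling_years"]] * panel$schooling_years +
    dcov[["household_size"]] * panel$household_size +
    dcov[["log_income"]] * panel$log_income +
    spec$year_effects[as.character(panel$year)] +
    panel$individual_fe + spec$gamma_confounder * panel$confounder

  p_pos <- stats::pnorm(stats::qnorm(spec$p_spend_intercept) +
                          spec$p_spend_severity * panel$severity)
  positive <- panel$u_pos < p_pos
  panel$oop_raw <- ifelse(positive, exp(linpred + panel$eps), 0)

  truth <- list(beta = b, alpha = a, gamma_confounder = spec$gamma_confounder,
                year_effects = spec$year_effects,
                individual_fe = do.call(rbind, fe_rows),
                confounder = panel$confounder,
                linpred = linpred, p_positive = p_pos)
  keep <- c("person_id", "prefecture_id", "year", "uebmi_enrolled", "oop_raw",
            "days_unable", "severity", "chronic", "utilization", "age",
            "schooling_years", "household_size", "log_income",
            "uebmi_penetration", "gmi_penetration")
  out <- panel[keep]
  rownames(out) <- NULL
  list(panel = out, truth = truth, instruments = inst)
}

#' Write a synthetic panel as CSV
#' @param panel data.frame from [generate_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a panel CSV
#' @param path CSV path.
#' @return data.frame with prefecture_id/person_id as character.
#' @export
read_panel_csv <- function(path) {
  assert_that(file.exists(path), paste0("panel file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in intersect(c("person_id", "prefecture_id"), names(df)))
    df[[cc]] <- as.character(df[[cc]])
  df
}
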