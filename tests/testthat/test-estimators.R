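test_that("fit_twoway_fe equals the explicit LSDV oracle on a small fixture", {
  pan <- make_small_panel()
  fit <- fit_twoway_fe(pan, "y", c("x1", "x2"), cluster = "none")
  orc <- lsdv_oracle(pan, "y", c("x1", "x2"))
  expect_equal(fit$coefficients[c("x1", "x2")], orc$coefficients, tolerance = 1e-8)
  expect_equal(fit$se[c("x1", "x2")], orc$se, tolerance = 1e-8)
  ## interaction built before demeaning, as in LSDV
  pan$x1x2 <- NULL
  fit2 <- fit_twoway_fe(pan, "y", c("x1", "x2", "x1:x2"), cluster = "none")
  orc2 <- lsdv_oracle(pan, "y", c("x1", "x2", "x1:x2"))
  expect_equal(fit2$coefficients[c("x1", "x2", "x1:x2")], orc2$coefficients,
               tolerance = 1e-8)
  expect_equal(fit2$se[c("x1", "x2", "x1:x2")], orc2$se, tolerance = 1e-8)
})

test_that("LSDV equality holds on larger random fixtures too", {
  for (seed in c(7, 99)) {
    pan <- make_small_panel(n_id = 40, waves = c(1, 2, 3, 4), seed = seed)
    ## unbalance it
    pan <- pan[-sample.int(nrow(pan), 30), ]
    fit <- fit_twoway_fe(pan, "y", c("x1", "x2"), cluster = "none")
    orc <- lsdv_oracle(pan, "y", c("x1", "x2"))
    expect_equal(fit$coefficients[c("x1", "x2")], orc$coefficients, tolerance = 1e-8)
  }
})

test_that("regressors without within variation are flagged unidentified", {
  pan <- make_small_panel()
  pan$fixed_trait <- as.numeric(factor(pan$person_id)) # person-constant
  fit <- fit_twoway_fe(pan, "y", c("x1", "fixed_trait"))
  expect_true("fixed_trait" %in% fit$unidentified)
  expect_true(is.na(fit$coefficients["fixed_trait"]))
  expect_false(is.na(fit$coefficients["x1"]))
  ## genuinely collinear time-varying regressors raise a rank error by name
  pan$x1_copy <- pan$x1
  expect_error(fit_twoway_fe(pan, "y", c("x1", "x1_copy")), "x1_copy")
})

test_that("slopes are invariant to adding a constant to the outcome", {
  pan <- make_small_panel(seed = 8)
  f1 <- fit_twoway_fe(pan, "y", c("x1", "x2"))
  pan$y <- pan$y + 100
  f2 <- fit_twoway_fe(pan, "y", c("x1", "x2"))
  expect_equal(f1$coefficients[c("x1", "x2")], f2$coefficients[c("x1", "x2")],
               tolerance = 1e-10)
})

test_that("singleton clusters reproduce heteroskedasticity-robust SEs", {
  pan <- make_small_panel(n_id = 25, seed = 14)
  pan$rowid <- as.character(seq_len(nrow(pan)))
  f_rob <- fit_twoway_fe(pan, "y", c("x1", "x2"), cluster = "robust")
  ## cluster on a column where every cluster is a singleton
  f_single <- fit_twoway_fe(pan, "y", c("x1", "x2"),
                            cluster = "prefecture", prefecture_col = "rowid")
  expect_equal(f_single$se[c("x1", "x2")], f_rob$se[c("x1", "x2")],
               tolerance = 1e-10)
  ## clustered SEs are non-negative and finite
  f_cl <- fit_twoway_fe(pan, "y", c("x1", "x2"), cluster = "prefecture")
  expect_true(all(f_cl$se[c("x1", "x2")] > 0))
})

test_that("lincom reproduces single coefficients and parses expressions", {
  pan <- make_small_panel(seed = 10)
  fit <- fit_twoway_fe(pan, "y", c("x1", "x2", "x1:x2"), cluster = "none")
  lc <- lincom(fit, c(x1 = 1))
  expect_equal(lc$estimate, unname(fit$coefficients["x1"]))
  expect_equal(lc$se, unname(fit$se["x1"]))
  ## expression parsing with weights
  lc2 <- lincom(fit, "x1 + 0.5*x1:x2")
  expect_equal(lc2$estimate,
               unname(fit$coefficients["x1"] + 0.5 * fit$coefficients["x1:x2"]))
  ## m = 0 boundary of the marginal-effects grid equals the focal row
  me0 <- marginal_effects(fit, "x1", "x2", grid = 0)
  expect_equal(me0$effect, unname(fit$coefficients["x1"]))
  expect_equal(me0$se, unname(fit$se["x1"]))
  expect_error(lincom(fit, c(nope = 1)), "unknown coefficient")
})

test_that("delta-method lincom SE agrees with a bootstrap on a small fixture", {
  pan <- make_small_panel(n_id = 30, waves = c(1, 2, 3), seed = 77)
  fit <- fit_twoway_fe(pan, "y", c("x1", "x2"), cluster = "none")
  lc <- lincom(fit, "x1 + x2")
  ## block bootstrap over persons, 500 resamples
  set.seed(123)
  ids <- unique(pan$person_id)
  stat <- replicate(500, {
    take <- sample(ids, length(ids), replace = TRUE)
    bp <- do.call(rbind, lapply(seq_along(take), function(i) {
      rows <- pan[pan$person_id == take[i], ]
      rows$person_id <- sprintf("bs%03d", i)
      rows
    }))
    f <- fit_twoway_fe(bp, "y", c("x1", "x2"), cluster = "none")
    sum(f$coefficients[c("x1", "x2")])
  })
  expect_lt(abs(stats::sd(stat) - lc$se) / lc$se, 0.15)
})

test_that("marginal effects: sign change point, vectorized vs per-point equality", {
  b <- make_synth_bundle(n_pref = 10, seed = 41)
  pan <- b$panel[b$panel$oop_raw > 0, ]
  pan$log_pos <- log(pan$oop_raw)
  fit <- fit_twoway_fe(pan, "log_pos",
                       c("benefit_expansion", "cost_containment",
                         "benefit_expansion:cost_containment", "severity"))
  bf <- fit$coefficients["benefit_expansion"]
  bi <- fit$coefficients["benefit_expansion:cost_containment"]
  mstar <- -bf / bi
  me <- suppressWarnings(marginal_effects(fit, "benefit_expansion",
                                          "cost_containment",
                                          grid = c(mstar - 0.1, mstar, mstar + 0.1)))
  expect_equal(me$effect[2], 0, tolerance = 1e-10)
  expect_equal(sign(me$effect[1]), -sign(me$effect[3]))
  ## vectorized grid equals lincom per point to 1e-12
  grid <- seq(0, 0.5, length.out = 11)
  me2 <- marginal_effects(fit, "benefit_expansion", "cost_containment", grid = grid)
  for (i in seq_along(grid)) {
    lc <- lincom(fit, stats::setNames(c(1, grid[i]),
                                      c("benefit_expansion",
                                        "benefit_expansion:cost_containment")))
    expect_equal(me2$effect[i], lc$estimate, tolerance = 1e-12)
    expect_equal(me2$se[i], lc$se, tolerance = 1e-12)
  }
  ## grid outside the observed moderator range warns but still computes
  expect_warning(marginal_effects(fit, "benefit_expansion", "cost_containment",
                                  grid = c(0, 99)), "outside")
})

test_that("three-way marginal effects pin the second moderator via `fixed`", {
  b <- make_synth_bundle(n_pref = 10, seed = 43)
  pan <- b$panel[b$panel$oop_raw > 0, ]
  pan$log_pos <- log(pan$oop_raw)
  fit <- fit_twoway_fe(pan, "log_pos", MODEL_REGRESSORS)
  me <- marginal_effects(fit, "uebmi_enrolled", "cost_containment",
                         grid = c(0, 0.2), fixed = list(benefit_expansion = 0.1))
  cf <- fit$coefficients
  want0 <- cf[["uebmi_enrolled"]] + 0.1 * cf[["uebmi_enrolled:benefit_expansion"]]
  want2 <- want0 + 0.2 * cf[["uebmi_enrolled:cost_containment"]] +
    0.2 * 0.1 * cf[["uebmi_enrolled:benefit_expansion:cost_containment"]]
  expect_equal(me$effect, c(want0, want2), tolerance = 1e-12)
  ## refusing to guess: unpinned three-way variable is an error
  expect_error(marginal_effects(fit, "uebmi_enrolled", "cost_containment",
                                grid = c(0, 0.2)), "fix its value")
})

test_that("two-part model: degenerate split, separation flag, part-2 recovery path", {
  b <- make_synth_bundle(n_pref = 8, seed = 47,
                         panel_args = list(p_spend_intercept = 1))
  pan <- b$panel
  ## all observations positive: part 1 degenerate, part 2 equals a full-sample fit
  tp <- fit_two_part(pan, "oop_raw", c("uebmi_enrolled", "severity"))
  expect_true(tp$part1$degenerate)
  pan$logpos <- log(pan$oop_raw)
  ref <- fit_twoway_fe(pan, "logpos", c("uebmi_enrolled", "severity"))
  expect_equal(tp$part2$coefficients, ref$coefficients, tolerance = 1e-10)

  ## separable fixture: perfect predictor of any-spending
  set.seed(5)
  n <- 120
  sepdat <- data.frame(person_id = sprintf("i%02d", rep(1:40, each = 3)),
                       prefecture_id = rep(c("a", "b"), each = 60),
                       year = rep(1:3, 40), x = rep(c(0, 1), 60))
  sepdat$oop_raw <- ifelse(sepdat$x > 0, exp(stats::rnorm(n)), 0)
  tp2 <- fit_two_part(sepdat, "oop_raw", "x")
  expect_true(tp2$part1$separated)
  expect_null(tp2$part1$coefficients)

  ## ordinary two-part data: part 1 fits and reports the positive share
  b3 <- make_synth_bundle(n_pref = 8, seed = 53)
  tp3 <- fit_two_part(b3$panel, "oop_raw", c("uebmi_enrolled", "severity", "log_income"))
  expect_false(tp3$part1$degenerate)
  expect_false(tp3$part1$separated)
  expect_equal(tp3$part1$share_positive, mean(b3$panel$oop_raw > 0))
  expect_true("uebmi_enrolled" %in% names(tp3$part1$coefficients))
})
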