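test_that("a zero-variance outcome yields all-zero slopes", {
  tt <- simulate_trial_table(n_participants = 4, n_trials = 3, seed = 1)
  tt$hbdiff <- 7.5
  m <- fit_mlm(tt, mlm_spec())
  co <- m$coefficients
  expect_equal(unname(co["(Intercept)", "estimate"]), 7.5)
  expect_true(all(co[-1, "estimate"] == 0))
})

test_that("with no random variance the fit reduces to ordinary regression", {
  # balanced toy data generated with zero participant variance
  eff <- trial_effects(sd_participant = 0, sd_resid = 5)
  tt <- simulate_trial_table(n_participants = 8, n_trials = 4,
                             effects = eff, seed = 3)
  m <- suppressMessages(fit_mlm(tt, mlm_spec()))
  ols <- lm(hbdiff ~ condition + subregion + condition:subregion + handedness,
            data = transform(tt,
                             condition = factor(condition,
                                                c("standard", "dnn")),
                             subregion = factor(subregion,
                                                c("left_lateral",
                                                  "lower_medial",
                                                  "right_lateral")),
                             handedness = factor(handedness,
                                                 c("left", "right"))))
  expect_equal(unname(m$coefficients[, "estimate"]), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("the program effect is recovered across simulated datasets", {
  ests <- vapply(1:20, function(s) {
    tt <- simulate_trial_table(seed = s)
    m <- fit_mlm(tt, mlm_spec())
    unname(m$coefficients["conditiondnn", "estimate"])
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-19)) / 19, 0.15)
  # single-fit CI covers the truth for a typical seed
  tt <- simulate_trial_table(seed = 100)
  m <- fit_mlm(tt, mlm_spec())
  co <- m$coefficients["conditiondnn", ]
  ci <- co["estimate"] + c(-1, 1) * qt(0.975, co["df"]) * co["se"]
  expect_true(ci[1] <= -19 && -19 <= ci[2])
})

test_that("likelihood-ratio comparison satisfies its identities", {
  tt <- simulate_trial_table(seed = 5)
  m0 <- fit_mlm(tt, mlm_spec(fixed = character(0)))
  m1 <- fit_mlm(tt, mlm_spec(fixed = c("condition", "handedness")))
  m2 <- fit_mlm(tt, mlm_spec())
  cmp <- compare_nested(m1, m2)
  expect_equal(cmp$chi2, 2 * (m2$loglik - m1$loglik))
  expect_equal(cmp$df, 4)   # 2 region dummies + 2 interaction terms
  expect_gte(cmp$chi2, 0)
  expect_equal(cmp$delta_aic, m2$aic - m1$aic)
  cmp0 <- compare_nested(m0, m1)
  expect_equal(cmp0$df, 2)
  expect_gte(cmp0$chi2, 0)
  # identical models: chi2 = 0, p = 1
  same <- compare_nested(m1, m1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # AIC identity: 2k - 2 logLik
  expect_equal(m2$aic, 2 * m2$df_model - 2 * m2$loglik)
  # non-nested specs are refused
  ma <- fit_mlm(tt, mlm_spec(fixed = "handedness"))
  mb <- fit_mlm(tt, mlm_spec(fixed = "condition"))
  expect_error(compare_nested(ma, mb), "not nested")
})

test_that("simple slopes by refit equal the linear-combination slopes", {
  tt <- simulate_trial_table(seed = 12)
  m <- fit_mlm(tt, mlm_spec())
  s_refit <- simple_slopes(m, method = "refit")
  s_lc <- simple_slopes(m, method = "contrast")
  expect_equal(s_refit$estimate, s_lc$estimate, tolerance = 1e-6)
  expect_equal(s_refit$se, s_lc$se, tolerance = 1e-6)
  expect_equal(s_refit$p, s_lc$p, tolerance = 1e-6)
  expect_equal(s_refit$subregion,
               c("left_lateral", "lower_medial", "right_lateral"))
  # the left-lateral slope reproduces the interaction model's program term
  expect_equal(s_refit$estimate[1],
               unname(m$coefficients["conditiondnn", "estimate"]))
})

test_that("without an interaction in the data the slopes agree", {
  eff <- trial_effects(program_effect = c(left_lateral = -10,
                                          lower_medial = -10,
                                          right_lateral = -10))
  tt <- simulate_trial_table(seed = 8, effects = eff)
  m <- fit_mlm(tt, mlm_spec())
  s <- simple_slopes(m, method = "contrast")
  expect_lt(max(s$estimate) - min(s$estimate),
            6 * max(s$se))  # equal within noise
  expect_true(all(s$ci_lo < -10 & -10 < s$ci_hi))
})

test_that("dummy coding gives the paper's sign conventions", {
  tt <- simulate_trial_table(seed = 2)
  m <- fit_mlm(tt, mlm_spec())
  # DNN lower than standard in left lateral: negative program coefficient
  expect_lt(m$coefficients["conditiondnn", "estimate"], 0)
  # right-handers carry higher oxygenation: positive handedness coefficient
  expect_gt(m$coefficients["handednessright", "estimate"], 0)
})

test_that("the brain-behaviour model recovers a programmed effort slope", {
  # no program effect, so the effort-only model is correctly specified
  # (with both present, the effort slope absorbs part of the condition
  # contrast, as in any omitted-variable design)
  eff <- trial_effects(effort_slope_left = 8,
                       program_effect = c(left_lateral = 0,
                                          lower_medial = 0,
                                          right_lateral = 0))
  tt <- simulate_trial_table(seed = 31, effects = eff)
  bb <- brain_behaviour_model(tt, correct_only = TRUE)
  ci <- bb$slope + c(-1, 1) * qt(0.975, bb$df) * bb$se
  expect_true(ci[1] <= 8 && 8 <= ci[2])
  expect_equal(bb$lrt$df, 1)
  expect_equal(bb$lrt$chi2, 2 * (bb$fit$loglik -
                                   fit_mlm(bb$fit$data,
                                           mlm_spec(character(0)))$loglik),
               tolerance = 1e-8)
})

test_that("uncoupled effort gives a near-zero brain-behaviour slope", {
  tt <- simulate_trial_table(seed = 44)  # effort_slope_left = 0
  bb <- brain_behaviour_model(tt, correct_only = TRUE)
  expect_lt(abs(bb$slope), 3 * bb$se)
})

test_that("the correct-only filter selects a subset of all trials", {
  tt <- simulate_trial_table(seed = 13)
  all_tr <- brain_behaviour_model(tt, correct_only = FALSE)
  cor_tr <- brain_behaviour_model(tt, correct_only = TRUE)
  expect_lt(cor_tr$n_obs, all_tr$n_obs)
  expect_equal(all_tr$n_obs,
               sum(tt$subregion == "left_lateral" & !is.na(tt$hbdiff)))
  tt0 <- tt[tt$subregion == "left_lateral", ]
  tt0$correct <- 0
  expect_error(brain_behaviour_model(tt0, correct_only = TRUE),
               "no correct trials")
})

test_that("missing subregion rows are tolerated (FIML)", {
  tt <- simulate_trial_table(seed = 6)
  drop_idx <- seq(1, nrow(tt), by = 17)
  tt$hbdiff[drop_idx] <- NA
  m <- fit_mlm(tt, mlm_spec())
  expect_equal(m$n_obs, nrow(tt) - length(drop_idx))
  expect_lt(m$coefficients["conditiondnn", "estimate"], 0)
})
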