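test_that("pooled t from summaries reproduces the printed group tests", {
  # hinting: SZ 14.9 +/- 2.1 vs HC 17.9 +/- 1.5, n = 10 each
  tt <- t_test_from_summary(14.9, 2.1, 10, 17.9, 1.5, 10)
  expect_equal(tt$df, 18)
  expect_equal(tt$t, -3.68, tolerance = 0.01 / 3.68)
  expect_lt(tt$p_value, 0.01)
  # total time: HC 169.10 +/- 41.01 vs SZ 208.8 +/- 63.46
  tt2 <- t_test_from_summary(169.10, 41.01, 10, 208.8, 63.46, 10)
  expect_equal(tt2$t, -1.66, tolerance = 0.01 / 1.66)
  expect_equal(tt2$df, 18)
  # identical groups: t = 0
  expect_equal(t_test_from_summary(5, 1, 8, 5, 1, 8)$t, 0)
  expect_error(t_test_from_summary(5, 0, 8, 5, 0, 8), "undefined")
})

test_that("raw-data t-test equals the summary test and is antisymmetric", {
  tt <- t_test_raw(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -sqrt(3 / 2), tolerance = 1e-10)  # -1.2247
  expect_equal(tt$df, 4)
  expect_equal(t_test_raw(c(1, 2, 3), c(1, 2, 3))$t, 0)
  set.seed(5)
  for (k in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    a <- t_test_raw(x, y)
    b <- t_test_from_summary(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y))
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$df, b$df)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
    expect_equal(t_test_raw(y, x)$t, -a$t, tolerance = 1e-12)
  }
})

test_that("spearman matches hand examples and the naive oracle", {
  inc <- spearman(1:8, (1:8)^3)
  expect_equal(inc$rho, 1)
  expect_equal(spearman(1:8, rev(1:8))$rho, -1)
  # ranks (1, 2.5, 2.5, 4) vs (1, 2, 3, 4) -> 0.9487
  tied <- spearman(c(1, 2, 2, 4), c(10, 20, 30, 40))
  expect_equal(tied$rho, 0.9486833, tolerance = 1e-6)
  expect_error(spearman(rep(1, 5), 1:5), "constant")

  set.seed(31)
  for (k in 1:40) {
    n <- sample(4:25, 1)
    x <- sample(1:8, n, replace = TRUE) + runif(n, 0, 0.01 * (k %% 2))
    y <- rnorm(n) + 0.3 * x
    got <- spearman(x, y)
    expect_equal(got$rho, spearman_oracle_rho(x, y), tolerance = 1e-10)
    # agreement with the standard implementation's estimate
    expect_equal(got$rho,
                 unname(cor.test(x, y, method = "spearman",
                                 exact = FALSE)$estimate),
                 tolerance = 1e-10)
  }
})

test_that("spearman exact p is available for small tie-free samples", {
  x <- c(3, 1, 4, 5, 2); y <- c(2, 1, 5, 4, 3)
  ex <- spearman(x, y, exact = TRUE)
  expect_equal(ex$p_value,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  expect_warning(spearman(c(1, 1, 2, 3), c(4, 3, 2, 1), exact = TRUE),
                 "approximation")
})

test_that("AIC comparison prefers the lower-AIC fit and is antisymmetric", {
  a <- list(aic = 388.1, n_obs = 323)
  b <- list(aic = 404.7, n_obs = 323)
  cmp <- compare_aic(a, b, labels = c("retained", "maximal"))
  expect_identical(cmp$preferred, "retained")
  expect_equal(cmp$delta_aic, 16.6, tolerance = 1e-9)
  rev_cmp <- compare_aic(b, a, labels = c("maximal", "retained"))
  expect_identical(rev_cmp$preferred, "retained")
  expect_equal(rev_cmp$delta_aic, cmp$delta_aic)
  # ties go to the first argument by convention
  tie <- compare_aic(a, list(aic = 388.1, n_obs = 323))
  expect_true(tie$tie); expect_identical(tie$preferred, "a")
  expect_error(compare_aic(a, list(aic = 400, n_obs = 300)), "comparable")
  # -2 logLik + 2k: logLik -190.05 with 4 parameters gives 388.1
  expect_equal(-2 * -190.05 + 2 * 4, 388.1)
})

test_that("the mixed logit recovers generator truth and reports sane fits", {
  cfg <- generator_config(n_participants_per_group = 40L, seed = 301L)
  ds <- generate_dataset(cfg)
  flt <- filter_tokens(ds)
  mf <- model_frame(flt$dataset, classify_phrasing(flt$dataset))
  fit <- fit_mixed_logit(mf)
  expect_s3_class(fit, "pp_modelfit")
  expect_true(fit$converged)
  fe <- fit$fixed_effects
  cond <- fe[fe$name == "conditioncontrastive", ]
  expect_lt(abs(cond$estimate - 2.5982), 3 * cond$std_error)
  # Wald statistic is estimate / SE; variance components non-negative
  expect_equal(fe$statistic, fe$estimate / fe$std_error, tolerance = 1e-8)
  expect_true(all(fit$variance_components >= 0))
  expect_setequal(names(fit$variance_components),
                  c("participant_id", "item_id"))
  # AIC invariant against the reported log-likelihood
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$n_params)
  expect_equal(fit$n_obs, nrow(mf))
})

test_that("a constant outcome is a separation error, not a silent fit", {
  mf <- data.frame(outcome = 1, condition = rep(c("given", "contrastive"), 20),
                   group = "HC",
                   participant_id = rep(c("P1", "P2"), each = 20),
                   item_id = rep(sprintf("I%02d", 1:20), 2))
  expect_error(fit_mixed_logit(mf), "constant")
})

test_that("null effects give well-calibrated z statistics", {
  # all true effects 0, zero variance components
  null_cfg <- function(seed) generator_config(
    true_coefficients = c(intercept = 0, condition_effect = 0,
                          group_effect = 0, interaction = 0),
    var_participant = 0, var_item = 0, dropout_prob = 0, seed = seed)
  zs <- vapply(1:50, function(r) {
    ds <- generate_dataset(null_cfg(5000L + r))
    mf <- model_frame(ds, classify_phrasing(ds))
    fe <- fit_mixed_logit(mf)$fixed_effects
    fe$statistic[fe$name == "conditioncontrastive"]
  }, 0)
  expect_gte(mean(abs(zs) < 1.96), 0.9)
})

test_that("log-LMMs recover the derived condition contrast and shift-invariance", {
  # with zero variance components the marginal two-AP probabilities are
  # plogis(eta), so the HC log-duration contrast is
  # (p_c - p_g) * (E log U[1.12,1.40] - E log U[0.90,1.08])
  cfg <- generator_config(n_participants_per_group = 60L,
                          var_participant = 0, var_item = 0,
                          dropout_prob = 0, seed = 77L)
  e_log_unif <- function(a, b) (b * (log(b) - 1) - a * (log(a) - 1)) / (b - a)
  p_g <- plogis(cfg$true_coefficients[["intercept"]])
  p_c <- plogis(cfg$true_coefficients[["intercept"]] +
                  cfg$true_coefficients[["condition_effect"]])
  truth <- (p_c - p_g) * (e_log_unif(1.12, 1.40) - e_log_unif(0.90, 1.08))
  ds <- generate_dataset(cfg)
  mf <- model_frame(ds, classify_phrasing(ds))
  fit <- fit_lmm_log(mf[mf$group == "HC", ], "duration")
  cond <- fit$fixed_effects[fit$fixed_effects$name == "conditioncontrastive", ]
  expect_lt(abs(cond$estimate - truth), 3 * cond$std_error)

  # multiplying the response by a constant shifts only the intercept
  mf2 <- mf; mf2$dur_s2 <- mf2$dur_s2 * 1000   # seconds -> ms
  fit2 <- fit_lmm_log(mf2[mf2$group == "HC", ], "duration")
  fe1 <- fit$fixed_effects; fe2 <- fit2$fixed_effects
  ix <- fe1$name != "(Intercept)"
  expect_equal(fe2$estimate[ix], fe1$estimate[ix], tolerance = 1e-6)
  expect_equal(
    fe2$estimate[fe2$name == "(Intercept)"],
    fe1$estimate[fe1$name == "(Intercept)"] + log(1000), tolerance = 1e-6)
})

test_that("null-effect LMM t statistics stay near zero", {
  null_cfg <- function(seed) generator_config(
    true_coefficients = c(intercept = 0, condition_effect = 0,
                          group_effect = 0, interaction = 0),
    var_participant = 0, var_item = 0, dropout_prob = 0, seed = seed)
  ts <- vapply(1:50, function(r) {
    ds <- generate_dataset(null_cfg(9000L + r))
    mf <- model_frame(ds, classify_phrasing(ds))
    fe <- fit_lmm_log(mf, "duration", pvalues = "wald")$fixed_effects
    fe$statistic[fe$name == "conditioncontrastive"]
  }, 0)
  expect_gte(mean(abs(ts) < 2), 0.9)
})

test_that("satterthwaite p-values come with denominator df", {
  ds <- generate_dataset(generator_config(seed = 11L))
  mf <- model_frame(ds, classify_phrasing(ds))
  fit <- fit_lmm_log(mf, "f0", pvalues = "satterthwaite")
  expect_true("df" %in% names(fit$fixed_effects))
  expect_true(all(fit$fixed_effects$df > 0))
})

test_that("maximal random structure is available for AIC comparison", {
  ds <- generate_dataset(generator_config(seed = 21L))
  flt <- filter_tokens(ds)
  mf <- model_frame(flt$dataset, classify_phrasing(flt$dataset))
  retained <- fit_mixed_logit(mf)
  maximal <- fit_mixed_logit(mf, random = "maximal")
  expect_equal(retained$n_obs, maximal$n_obs)
  cmp <- compare_aic(retained, maximal, c("retained", "maximal"))
  expect_true(cmp$preferred %in% c("retained", "maximal"))
  expect_gte(cmp$delta_aic, 0)
})
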