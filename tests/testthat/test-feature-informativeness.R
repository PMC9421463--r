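sim_labelled_cohort <- function(n, beta, cutpoints = c(-1, 1), seed = 1,
                                p = length(beta)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("x%02d", seq_len(p))))
  y <- simulate_visual_labels(X, beta, cutpoints, seed = seed + 1)
  dplyr::bind_cols(tibble::as_tibble(X), visual_label = y)
}

test_that("the Bonferroni family size is features x covariates", {
  co <- simulate_qc_features(n_sites = 4, scans_per_site = 25,
                             n_features = 10, seed = 3)
  scr <- covariate_screen(co)
  expect_equal(attr(scr, "n_tests"), 10L * 6L)
  expect_equal(scr$p_adjusted, pmin(1, scr$p_value * 60))
  expect_equal(scr$significant, scr$p_adjusted < 0.05)
})

test_that("a 3-SD site shift is detected after Bonferroni in almost every run", {
  hits <- sapply(1:50, function(seed) {
    co <- simulate_qc_features(
      n_sites = 4, scans_per_site = 50, n_features = 3,
      site_offsets = cbind(c(0, 3, 0, 3), 0, 0),
      seed = seed)
    scr <- covariate_screen(co, features = c("f01", "f02", "f03"))
    scr$significant[scr$feature == "f01" & scr$covariate == "site"]
  })
  expect_gte(mean(hits), 0.99)
})

test_that("null features give uniform raw p-values across simulations", {
  ps <- sapply(1:500, function(seed) {
    co <- simulate_qc_features(n_sites = 2, scans_per_site = 25,
                               n_features = 1, site_shift_sd = 0, seed = seed)
    scr <- covariate_screen(co, features = "f01")
    scr$p_value[scr$covariate == "age"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("constant features are skipped and short tables rejected", {
  co <- simulate_qc_features(n_sites = 2, scans_per_site = 20, n_features = 2,
                             seed = 5)
  co$f02 <- 1
  expect_message(scr <- covariate_screen(co), "constant")
  expect_false("f02" %in% scr$feature)
  expect_error(covariate_screen(co[1:8, ]), "complete rows")
})

test_that("ordinal MLE is invariant to affine predictor rescaling", {
  dat <- sim_labelled_cohort(800, beta = c(0.8, -0.4), seed = 11)
  f1 <- fit_ordinal(dat)
  dat2 <- dplyr::mutate(dat, x01 = x01 * 100)
  f2 <- fit_ordinal(dat2)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
  expect_equal(f2$aic, f1$aic, tolerance = 1e-8)
  expect_equal(f2$coefficients$estimate[1] * 100,
               f1$coefficients$estimate[1], tolerance = 1e-6)
  expect_equal(f2$coefficients$p_value, f1$coefficients$p_value,
               tolerance = 1e-8)
})

test_that("two-level labels reproduce binary logistic estimates", {
  set.seed(21)
  X <- matrix(rnorm(1500 * 2), 1500, 2, dimnames = list(NULL, c("a", "b")))
  y <- simulate_visual_labels(X, c(0.8, -0.3), 0.2, seed = 22,
                              levels = c("poor", "good"))
  dat <- dplyr::bind_cols(tibble::as_tibble(X), visual_label = y)
  fit <- fit_ordinal(dat, level_order = c("poor", "good"))
  g <- stats::glm(I(y == "good") ~ a + b, data = dat, family = stats::binomial,
                  control = stats::glm.control(epsilon = 1e-12))
  expect_equal(fit$coefficients$estimate, unname(stats::coef(g)[2:3]),
               tolerance = 1e-6)
  expect_equal(fit$cutpoints, unname(-stats::coef(g)[1]), tolerance = 1e-6)
})

test_that("estimates, SEs and likelihood agree with an independent PO fitter", {
  skip_if_not_installed("MASS")
  dat <- sim_labelled_cohort(1000, beta = c(1, -0.5, 0.2), seed = 31)
  fit <- fit_ordinal(dat)
  m <- MASS::polr(
    factor(visual_label, levels = c("poor", "moderate", "good"),
           ordered = TRUE) ~ x01 + x02 + x03,
    data = dat, Hess = TRUE)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(m)),
               tolerance = 1e-4)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(stats::vcov(m))[1:3])),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(fit$aic, stats::AIC(m), tolerance = 1e-5)
})

test_that("odds ratios, CIs and AIC satisfy their defining identities", {
  dat <- sim_labelled_cohort(600, beta = c(0.5, 0), seed = 41)
  fit <- fit_ordinal(dat)
  co <- fit$coefficients
  expect_equal(co$odds_ratio, exp(co$estimate))
  expect_true(all(co$ci_low < co$ci_high))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * (2 + fit$K - 1))
  g <- glance(fit)
  expect_equal(g$AIC, fit$aic)
  expect_equal(tidy(fit)$estimate, co$estimate)
})

test_that("a pure-noise predictor is usually non-significant", {
  rejections <- sapply(1:60, function(seed) {
    dat <- sim_labelled_cohort(2000, beta = 0, seed = 100 + seed, p = 1)
    fit_ordinal(dat)$coefficients$p_value < 0.05
  })
  expect_lt(mean(rejections), 0.12)   # nominal 5% type-I error
})

test_that("backward elimination never increases AIC and stops correctly", {
  dat <- sim_labelled_cohort(1000, beta = c(1, 0.8, 0, 0), seed = 51)
  full <- fit_ordinal(dat)
  el <- backward_eliminate_aic(full)
  expect_lte(el$fit$aic, full$aic)
  expect_true(all(diff(el$log$aic) <= 0))
  # a single strong predictor is never removed
  one <- fit_ordinal(dat, features = "x01")
  el1 <- backward_eliminate_aic(one)
  expect_equal(el1$fit$features, "x01")
  expect_equal(nrow(el1$log), 1L)
})

test_that("model comparison satisfies the nesting identities", {
  dat <- sim_labelled_cohort(800, beta = c(1, 0.5, 0), seed = 61)
  full <- fit_ordinal(dat)
  self <- compare_models(full, full)
  expect_equal(self$lr_statistic, 0)
  expect_equal(self$p_value, 1)
  red <- fit_ordinal(dat, features = c("x01", "x02"))
  cmp <- compare_models(full, red)
  expect_gte(cmp$lr_statistic, 0)
  expect_equal(cmp$df, 1L)
  other <- fit_ordinal(dplyr::mutate(dat, z = rnorm(800)),
                       features = c("x01", "z"))
  expect_error(compare_models(full, other), "not nested")
})

test_that("complete-case filtering happens once, upstream of both models", {
  dat <- sim_labelled_cohort(500, beta = c(1, 0.4), seed = 71)
  dat$x02[1:40] <- NA
  full <- fit_ordinal(dat)
  expect_equal(full$n, 460L)
  expect_equal(full$n_dropped, 40L)
  el <- backward_eliminate_aic(full)
  expect_equal(el$fit$n, full$n)
  cmp <- compare_models(full, el$fit)
  expect_gte(cmp$lr_statistic, 0)
})
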