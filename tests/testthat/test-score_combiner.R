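test_that("feature building maps schemes onto the right columns and labels", {
  co <- toy_cohort()
  f <- build_features(co, scheme_spec("L858R", "qscore", "qscore"))
  expect_equal(dim(f$x), c(6, 2))
  expect_equal(f$x[, 1], quickscore(co$l858r_intensity, co$l858r_percent))
  expect_equal(f$x[, 2], quickscore(co$total_egfr_intensity,
                                    co$total_egfr_percent))
  # L858R labels include complex carriers; exact-deletion labels do not
  expect_equal(f$y, c(1, 1, 0, 0, 0, 0))
  f2 <- build_features(co, scheme_spec("delE746-A750", "intensity", "none"))
  expect_equal(ncol(f2$x), 1)
  expect_equal(drop(f2$x), co$del19_intensity)
  expect_equal(f2$y, c(0, 0, 1, 0, 0, 0))
  expect_error(build_features(co[, -which(names(co) == "l858r_percent")],
                              scheme_spec("L858R", "qscore", "none")),
               "missing stain column")
})

test_that("each target has six schemes: two single-feature, four combined", {
  for (tg in c("L858R", "delE746-A750")) {
    s <- all_schemes(tg)
    expect_length(s, 6)
    expect_equal(sum(vapply(s, function(x)
      x$total_egfr_feature == "none", logical(1))), 2)
  }
})

test_that("simulated cohorts carry the configured L858R prevalence into labels", {
  co <- enrolled_cohort(seed = 11, n_patients = 4000, n_low_content = 0)
  f <- build_features(co, scheme_spec("L858R", "qscore", "qscore"))
  expect_equal(mean(f$y), 43 / 142, tolerance = 0.1)
})

test_that("a feature unrelated to balanced labels gets slope ~0, intercept ~logit(prevalence)", {
  x <- rep(c(-1, 0, 1), each = 4)
  y <- rep(c(0, 1), 6)
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.5), tolerance = 1e-6)
})

test_that("logistic fitting recovers known coefficients from simulated quickscores", {
  set.seed(1)
  n <- 5000
  q <- runif(n, 0, 300)
  y <- rbinom(n, 1, plogis(-1 + 0.02 * q))
  fit <- fit_logistic(q, y)
  se <- sqrt(diag(fit$vcov))
  expect_true(abs(fit$coefficients[1] - (-1)) < 1.96 * se[1])
  expect_true(abs(fit$coefficients[2] - 0.02) < 1.96 * se[2])
  # agrees with the IRLS reference implementation in glm()
  ref <- glm(y ~ q, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
  # predictions at known covariates match the closed form
  expect_equal(predict_probability(fit, 50), plogis(-1 + 0.02 * 50),
               tolerance = 0.05)
})

test_that("complete separation raises an error; the Firth fit stays finite", {
  x <- c(3, 3, 3, 0, 0, 0)
  y <- c(1, 1, 1, 0, 0, 0)
  expect_error(fit_logistic(x, y), "separation")
  firth <- fit_logistic(x, y, firth = TRUE)
  expect_true(all(is.finite(firth$coefficients)))
  expect_true(firth$coefficients[2] > 0)
  expect_error(fit_logistic(x, rep(1, 6)), "single class")
})

test_that("coefficients are invariant to row permutation and nesting lowers deviance", {
  co <- enrolled_cohort(seed = 3)
  f <- build_features(co, scheme_spec("L858R", "qscore", "qscore"))
  fit <- fit_logistic(f$x, f$y)
  set.seed(42)
  perm <- sample(nrow(f$x))
  fit_p <- fit_logistic(f$x[perm, ], f$y[perm])
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-8)
  fit_1 <- fit_logistic(f$x[, 1], f$y)
  expect_lte(fit$deviance, fit_1$deviance)
})

test_that("prediction is monotone in the linear predictor and checks dimensions", {
  fit0 <- structure(list(coefficients = c(0, 0)), class = "logit_fit")
  expect_equal(predict_probability(fit0, c(-5, 0, 7)), rep(0.5, 3))
  fit1 <- structure(list(coefficients = c(0, 1)), class = "logit_fit")
  expect_equal(predict_probability(fit1, 0), 0.5)
  p <- predict_probability(fit1, seq(-3, 3, by = 0.5))
  expect_true(all(diff(p) > 0))
  expect_error(predict_probability(fit0, cbind(1:3, 1:3)), "dimension")
})

test_that("a single-feature logistic transform leaves the ROC unchanged", {
  co <- enrolled_cohort(seed = 5)
  f <- build_features(co, scheme_spec("L858R", "qscore", "none"))
  fit <- fit_logistic(f$x, f$y)
  auc_raw <- roc_curve(drop(f$x), f$y)$auc
  auc_prob <- roc_curve(predict_probability(fit, f$x), f$y)$auc
  expect_equal(auc_prob, auc_raw, tolerance = 1e-12)
})
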