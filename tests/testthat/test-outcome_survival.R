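test_that("Kaplan-Meier reduces to the empirical survival without censoring", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km_survival_at(km, c(0.5, 1, 2)), c(1, 0.5, 0))
  expect_equal(km$median, 1)
  set.seed(15)
  t <- round(rexp(60, 0.1), 1) + 0.1
  km2 <- km_estimate(t, rep(1, 60))
  grid <- c(2, 5, 10, 20)
  expect_equal(km_survival_at(km2, grid),
               vapply(grid, function(g) mean(t > g), numeric(1)))
  # curve is a non-increasing step function starting at 1
  expect_true(all(diff(km2$surv) <= 0))
  expect_equal(km_survival_at(km2, 0), 1)
})

test_that("KM median recovers the true exponential median under censoring", {
  set.seed(16)
  n <- 5000
  t_event <- rexp(n, log(2) / 12)
  m <- stainclass:::censor_bound(log(2) / 12, 0.2)
  t_cens <- runif(n, 0, m)
  km <- km_estimate(pmin(t_event, t_cens), as.integer(t_event <= t_cens))
  expect_equal(mean(t_event > t_cens), 0.2, tolerance = 0.02)
  expect_equal(km$median, 12, tolerance = 0.7 / 12)
  # a heavily censored small sample can leave the median undefined
  km_und <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_false(km_und$median_defined)
})

test_that("log-rank test is null on identical groups and invariant to relabeling", {
  t <- c(2, 4, 6, 8, 10, 2, 4, 6, 8, 10)
  e <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  set.seed(17)
  t2 <- rexp(40, 0.1)
  g2 <- rep(c("x", "y"), 20)
  a <- logrank_test(t2, rep(1, 40), g2)
  b <- logrank_test(t2, rep(1, 40), ifelse(g2 == "x", "y", "x"))
  expect_equal(a$chisq, b$chisq)
  expect_error(logrank_test(t2, rep(1, 40), rep("x", 40)), "two groups")
})

test_that("log-rank p agrees with a permutation oracle on a small fixture", {
  set.seed(18)
  n <- 40
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, ifelse(g == 1, log(2) / 6, log(2) / 10))
  e <- rbinom(n, 1, 0.85)
  obs <- logrank_test(t, e, g)
  perm <- replicate(4000, logrank_test(t, e, sample(g))$chisq)
  p_perm <- mean(perm >= obs$chisq - 1e-12)
  expect_equal(obs$p_value, p_perm, tolerance = 0.02)
})

test_that("Cox regression recovers a known hazard ratio and is scale/duplication invariant", {
  set.seed(19)
  n <- 600
  grp <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.08 * ifelse(grp == 1, 3, 1))
  d <- data.frame(pfs_months = t, pfs_event = 1, grp = grp)
  fit <- cox_fit(d, covariates = "grp")
  expect_equal(fit$table$hr, 3, tolerance = 0.15)
  expect_true(fit$table$lower < 3 & fit$table$upper > 3)
  # rescaling time (months -> days) leaves the hazard ratio unchanged
  d_days <- transform(d, pfs_months = pfs_months * 30.4)
  expect_equal(cox_fit(d_days, covariates = "grp")$table$hr, fit$table$hr,
               tolerance = 1e-6)
  # duplicating every sample leaves the point estimate unchanged; exact
  # under Breslow (Efron redistributes the induced ties slightly)
  fit_b <- cox_fit(d, covariates = "grp", ties = "breslow")
  dup_b <- cox_fit(rbind(d, d), covariates = "grp", ties = "breslow")
  expect_equal(dup_b$table$hr, fit_b$table$hr, tolerance = 1e-8)
  expect_equal(cox_fit(rbind(d, d), covariates = "grp")$table$hr,
               fit$table$hr, tolerance = 0.01)
})

test_that("Cox errors on constant covariates, no events and monotone likelihood", {
  d <- data.frame(pfs_months = rexp(20, 0.1), pfs_event = 1, z = 1)
  expect_error(cox_fit(d, covariates = "z"), "constant")
  d2 <- data.frame(pfs_months = rexp(20, 0.1), pfs_event = 0,
                   z = rep(0:1, 10))
  expect_error(cox_fit(d2, covariates = "z"), "no events")
  # perfectly separated event times give a monotone partial likelihood
  d3 <- data.frame(pfs_months = c(1:10, 101:110), pfs_event = 1,
                   z = rep(1:0, each = 10))
  expect_error(cox_fit(d3, covariates = "z"), "monotone|failed")
})

test_that("Cox Wald intervals cover the null at roughly nominal rate", {
  set.seed(20)
  covered <- 0
  n_rep <- 300
  for (i in 1:n_rep) {
    n <- 120
    z <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1)  # hazard independent of z
    d <- data.frame(pfs_months = t, pfs_event = 1, z = z)
    fit <- tryCatch(cox_fit(d, covariates = "z"), error = function(e) NULL)
    if (is.null(fit)) next
    covered <- covered + (fit$table$lower <= 1 && 1 <= fit$table$upper)
  }
  expect_gte(covered / n_rep, 0.93)
})

test_that("reverse-KM follow-up and responder classification behave as documented", {
  t <- c(5, 10, 15, 20)
  # reversed events are the censorings at 15 and 20; S drops to 0.5 at 15
  expect_equal(median_followup(t, c(1, 1, 0, 0)), 15)
  expect_identical(is_responder(c("CR", "PR", "SD", "PD")),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_error(is_responder("MR"), "unknown response")
})
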