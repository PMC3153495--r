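test_that("confusion tables count call/truth combinations", {
  calls <- c(rep(TRUE, 4), rep(FALSE, 6))
  ct <- confusion_from_calls(calls, calls)
  expect_equal(c(ct$fp, ct$fn), c(0, 0))
  ct2 <- confusion_from_calls(rep(FALSE, 8), c(1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(c(ct2$tp, ct2$fp, ct2$fn, ct2$tn), c(0, 0, 3, 5))
  expect_error(confusion_from_calls(c(TRUE, FALSE), TRUE), "length")
  expect_error(confusion_table(-1, 2, 3, 4), "nonnegative")
})

test_that("printed-convention metrics reproduce one-decimal table arithmetic", {
  m <- diagnostic_metrics(confusion_table(38, 23, 5, 77), "printed")
  expect_equal(m$sensitivity, 88.4)
  expect_equal(m$specificity, 77.0)
  expect_equal(m$ppv, 62.3)
  expect_equal(m$npv, 93.9)
  expect_equal(m$accuracy, 80.4)
  # likelihood ratios formed from the rounded percentages
  expect_equal(m$lr_plus, 3.843)
  expect_equal(m$lr_minus, 0.151)
  # the exact-proportion LR+ differs in the third decimal
  e <- diagnostic_metrics(confusion_table(38, 23, 5, 77), "exact")
  expect_equal(round(e$lr_plus, 3), 3.842)
})

test_that("exact metrics satisfy the defining count identities and the swap symmetry", {
  set.seed(13)
  for (i in 1:25) {
    ct <- do.call(confusion_table, as.list(1 + rpois(4, 20)))
    m <- diagnostic_metrics(ct, "exact")
    expect_equal(m$sensitivity * (ct$tp + ct$fn), 100 * ct$tp)
    expect_equal(m$specificity * (ct$tn + ct$fp), 100 * ct$tn)
    expect_equal(m$ppv * (ct$tp + ct$fp), 100 * ct$tp)
    expect_equal(m$npv * (ct$tn + ct$fn), 100 * ct$tn)
    sw <- diagnostic_metrics(confusion_table(ct$tn, ct$fn, ct$fp, ct$tp),
                             "exact")
    expect_equal(sw$sensitivity, m$specificity)
    expect_equal(sw$ppv, m$npv)
  }
})

test_that("degenerate denominators are flagged rather than silently dropped", {
  perfect <- diagnostic_metrics(confusion_table(5, 0, 0, 5), "exact")
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_identical(perfect$lr_plus, Inf)
  expect_equal(perfect$lr_minus, 0)
  expect_true("lr_plus" %in% perfect$undefined)
  no_pos <- diagnostic_metrics(confusion_table(0, 2, 0, 8), "exact")
  expect_true("sensitivity" %in% no_pos$undefined)
  expect_true(is.na(no_pos$sensitivity))
})

test_that("Pearson chi-squared matches the closed form and the response-rate contrast", {
  # responders by IHC status: 17/22 vs 5/15
  resp <- matrix(c(17, 5, 5, 10), 2, 2, byrow = TRUE)
  ht <- pearson_chi2(resp)
  expect_equal(round(ht$p_value, 3), 0.008)
  flat <- pearson_chi2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(1 + rpois(4, 15), 2, 2)
    got <- pearson_chi2(m)$statistic
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    shortcut <- sum(m) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(got, shortcut, tolerance = 1e-12)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("Fisher's exact test enumerates hypergeometric tables", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2, 2)), 1 / 3)
  expect_equal(fisher_exact(matrix(c(0, 5, 5, 0), 2, 2)),
               fisher_exact(matrix(c(5, 0, 0, 5), 2, 2)))
  # asymptotic agreement with chi-squared on a large balanced table
  big <- matrix(c(500, 500, 470, 530), 2, 2)
  expect_lt(abs(fisher_exact(big) - pearson_chi2(big)$p_value), 0.02)
})

test_that("the small-sample trigger switches to Fisher's test", {
  small <- matrix(c(2, 1, 1, 3), 2, 2)
  expect_equal(categorical_test(small)$method, "fisher")
  large <- matrix(c(30, 20, 25, 25), 2, 2)
  expect_equal(categorical_test(large)$method, "chi2")
})

test_that("Wilson intervals cover the point estimate and stay inside [0,1]", {
  ci <- wilson_ci(38, 43)
  expect_true(ci["lower"] < 38 / 43 && 38 / 43 < ci["upper"])
  edge <- wilson_ci(0, 10)
  expect_gte(edge["lower"], 0)
  expect_lte(wilson_ci(10, 10)["upper"], 1)
})
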