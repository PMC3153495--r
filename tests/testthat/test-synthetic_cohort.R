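test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(sim_config(seed = 99))
  b <- simulate_cohort(sim_config(seed = 99))
  attr(a, "sim_config") <- attr(b, "sim_config") <- NULL
  expect_identical(a, b)
  c <- simulate_cohort(sim_config(seed = 100))
  expect_false(identical(a$genotype, c$genotype))
  # outcome layer is deterministic too
  oa <- simulate_outcomes(a, sim_config(seed = 99))
  ob <- simulate_outcomes(b, sim_config(seed = 99))
  expect_identical(oa, ob)
})

test_that("genotype shares converge to the configured mixture", {
  co <- simulate_cohort(sim_config(n_patients = 100000, n_low_content = 0,
                                   seed = 21))
  g <- parse_genotype(co$genotype)
  probs <- sim_config()$genotype_probs
  expect_lt(abs(mean(g$is_L858R) - probs[["l858r"]]), 0.01)
  expect_lt(abs(mean(g$is_E746A750) - probs[["e746a750"]]), 0.01)
  expect_lt(abs(mean(!g$is_any_mutation) - probs[["wild"]]), 0.01)
  expect_lt(abs(mean(g$is_del19) - mean(g$is_E746A750) -
                  probs[["del19_other"]]), 0.01)
})

test_that("without cross-reactivity non-carriers essentially never stain", {
  co <- simulate_cohort(sim_config(n_patients = 20000, n_low_content = 0,
                                   seed = 22, cross_reactivity = 0))
  g <- parse_genotype(co$genotype)
  call <- intensity_positive(co$l858r_intensity, co$l858r_percent)
  expect_gte(mean(!call[!g$is_L858R]), 0.995)
})

test_that("mutation prevalence is higher in females and non-smokers as configured", {
  co <- simulate_cohort(sim_config(n_patients = 50000, n_low_content = 0,
                                   seed = 23))
  g <- parse_genotype(co$genotype)
  expect_equal(mean(g$is_any_mutation[co$sex == "female"]), 0.792,
               tolerance = 0.02)
  expect_equal(mean(g$is_any_mutation[co$sex == "male"]), 0.507,
               tolerance = 0.02)
  expect_equal(mean(g$is_any_mutation[co$smoking == "never"]), 0.777,
               tolerance = 0.02)
  expect_equal(mean(g$is_any_mutation[co$smoking == "ever"]), 0.408,
               tolerance = 0.02)
})

test_that("one cross-reactive L747-T751 deletion stains the deletion antibody", {
  co <- simulate_cohort(sim_config(seed = 24))
  cross <- which(co$genotype == "delL747-T751")
  expect_gte(length(cross), 1)
  first <- cross[1]
  expect_true(intensity_positive(co$del19_intensity[first],
                                 co$del19_percent[first]))
})

test_that("simulated outcomes reproduce the configured response and censoring structure", {
  cfg <- sim_config(n_patients = 30000, n_low_content = 0, seed = 25)
  co <- simulate_outcomes(simulate_cohort(cfg), cfg)
  tki <- co[!is.na(co$tki_treated) & co$tki_treated, ]
  expect_equal(mean(tki$responder[tki$ihc_call]), 0.773, tolerance = 0.02)
  expect_equal(mean(tki$responder[!tki$ihc_call]), 0.333, tolerance = 0.03)
  expect_equal(mean(tki$pfs_event), 0.8, tolerance = 0.03)
  expect_true(all(is.na(co$pfs_months[!co$tki_treated])))
  expect_identical(sort(unique(tki$response)), c("PD", "PR", "SD"))
  expect_true(all(is_responder(tki$response) == tki$responder))
  # no censoring means every treated patient has an event
  cfg0 <- sim_config(n_patients = 2000, n_low_content = 0, seed = 26,
                     censor_rate = 0)
  co0 <- simulate_outcomes(simulate_cohort(cfg0), cfg0)
  expect_true(all(co0$pfs_event[co0$tki_treated] == 1))
})

test_that("group KM medians recover the configured PFS medians end to end", {
  cfg <- sim_config(n_patients = 30000, n_low_content = 0, seed = 27)
  co <- simulate_outcomes(simulate_cohort(cfg), cfg)
  tki <- co[co$tki_treated, ]
  med_pos <- km_estimate(tki$pfs_months[tki$ihc_call],
                         tki$pfs_event[tki$ihc_call])$median
  med_neg <- km_estimate(tki$pfs_months[!tki$ihc_call],
                         tki$pfs_event[!tki$ihc_call])$median
  expect_equal(med_pos, 12.0, tolerance = 0.1)
  expect_equal(med_neg, 4.7, tolerance = 0.1)
})

test_that("the ECOG scenario inflates the progression hazard as configured", {
  cfg <- sim_config(n_patients = 60000, n_low_content = 0, seed = 28,
                    ecog_scenario = TRUE, censor_rate = 0.2)
  co <- simulate_outcomes(simulate_cohort(cfg), cfg)
  tki <- co[co$tki_treated, ]
  d <- data.frame(pfs_months = tki$pfs_months, pfs_event = tki$pfs_event,
                  ecog_2_4 = as.integer(tki$ecog_ps >= 2),
                  ihc = as.integer(tki$ihc_call))
  fit <- cox_fit(d, covariates = c("ecog_2_4", "ihc"))
  expect_equal(fit$table$hr[fit$table$term == "ecog_2_4"], 5.52,
               tolerance = 0.1)
})
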