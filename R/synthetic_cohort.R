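# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a surgically resected lung-adenocarcinoma cohort:
#' 143 enrolled tumors plus 14 sections excluded for low tumor content
#' (157 collected in all), genotype mix proportional to 31:10:43:8:50 over
#' E746-A750 deletion / other Del-19 / L858R / other mutation / wild type,
#' mutation prevalence higher in females (79.2% vs 50.7%) and non-smokers
#' (77.7% vs 40.8%), and TKI outcome contrasts of a 77.3% vs 33.3%
#' response rate and 12.0 vs 4.7 month median progression-free survival
#' for IHC-positive vs IHC-negative tumors.
#'
#' The staining model draws each intensity grade by cutting a latent
#' Gaussian at fixed thresholds and each percent-positive from a Beta
#' distribution whose shape depends on the intensity grade.  Tumors
#' carrying the cognate mutation stain their mutation-specific antibody
#' strongly (intensity 2-3, high percent) except for a configurable
#' false-negative minority that does not stain at all.  Non-carrier tumors
#' receive nonspecific mutation-marker staining whose latent mean increases
#' with `cross_reactivity * totalQ/300`, where totalQ is the total-EGFR
#' quickscore — the mechanism by which wild-type tumors with high total
#' EGFR expression produce false positives, and which a combined
#' marker + total-EGFR model can correct.  With `cross_reactivity = 0`
#' non-carriers essentially never stain.  One "other Del-19" tumor per
#' cohort is made cross-reactive with the deletion antibody
#' (the L747-T751 pattern).
#'
#' @param n_patients number of enrolled (analyzable) tumors.
#' @param n_low_content additional collected sections with tumor content
#'   below the enrollment threshold.
#' @param seed integer seed making the cohort reproducible.
#' @param genotype_probs named nonnegative weights over
#'   `e746a750`, `del19_other`, `l858r`, `other`, `wild` (renormalized).
#' @param cross_reactivity nonnegative strength of total-EGFR-driven
#'   nonspecific staining of non-carriers.
#' @param marker_base named latent baselines (`l858r`, `del19`) of
#'   non-carrier marker staining; more negative means less background.
#' @param false_negative named fraction of carriers whose cognate marker
#'   does not stain (`l858r` default 5/43, `del19` default 2/31).
#' @param mut_rate_female,mut_rate_male,mut_rate_nonsmoker,mut_rate_smoker
#'   mutation prevalence conditional on sex / smoking.
#' @param recurrence_rate fraction of patients with tumor recurrence.
#' @param tki_fraction fraction of recurrent patients treated with an
#'   EGFR TKI.
#' @param response_probs named responder probabilities by IHC status
#'   (`pos`, `neg`).
#' @param pfs_medians named median PFS in months by IHC status
#'   (`pos`, `neg`).
#' @param censor_rate expected fraction of TKI-treated patients censored.
#' @param ecog_scenario if `TRUE`, poor performance status (ECOG 2-4)
#'   multiplies the progression hazard by `ecog_hr`.
#' @param ecog_hr hazard ratio for ECOG 2-4 under `ecog_scenario`.
#' @param p_ecog_high probability of ECOG 2-4 (default 9/37).
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_patients = 143,
                       n_low_content = 14,
                       seed = 1L,
                       genotype_probs = c(e746a750 = 31, del19_other = 10,
                                          l858r = 43, other = 8, wild = 50),
                       cross_reactivity = 10,
                       marker_base = c(l858r = -1.95, del19 = -6.25),
                       false_negative = c(l858r = 5 / 43, del19 = 2 / 31),
                       mut_rate_female = 0.792, mut_rate_male = 0.507,
                       mut_rate_nonsmoker = 0.777, mut_rate_smoker = 0.408,
                       recurrence_rate = 80 / 143,
                       tki_fraction = 37 / 80,
                       response_probs = c(pos = 0.773, neg = 0.333),
                       pfs_medians = c(pos = 12.0, neg = 4.7),
                       censor_rate = 0.2,
                       ecog_scenario = FALSE,
                       ecog_hr = 5.52,
                       p_ecog_high = 9 / 37) {
  stopifnot(n_patients >= 1, n_low_content >= 0,
            all(genotype_probs >= 0), sum(genotype_probs) > 0,
            cross_reactivity >= 0,
            all(false_negative >= 0 & false_negative <= 1),
            all(response_probs >= 0 & response_probs <= 1),
            all(pfs_medians > 0),
            censor_rate >= 0, censor_rate < 1)
  gp <- genotype_probs / sum(genotype_probs)
  if (!identical(sort(names(gp)),
                 sort(c("e746a750", "del19_other", "l858r", "other", "wild")))) {
    stop("genotype_probs must be named e746a750, del19_other, l858r, other, wild",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_low_content = as.integer(n_low_content),
                 seed = as.integer(seed),
                 genotype_probs = gp,
                 cross_reactivity = cross_reactivity,
                 marker_base = marker_base,
                 false_negative = false_negative,
                 mut_rate_female = mut_rate_female,
                 mut_rate_male = mut_rate_male,
                 mut_rate_nonsmoker = mut_rate_nonsmoker,
                 mut_rate_smoker = mut_rate_smoker,
                 recurrence_rate = recurrence_rate,
                 tki_fraction = tki_fraction,
                 response_probs = response_probs,
                 pfs_medians = pfs_medians,
                 censor_rate = censor_rate,
                 ecog_scenario = ecog_scenario,
                 ecog_hr = ecog_hr,
                 p_ecog_high = p_ecog_high),
            class = "sim_config")
}

# per-marker staining geometry, fixed by calibration to the observed
# intensity operating points: stained carriers are mostly 2+/3+ with a weak
# minority (L858R: ~87% at 2+ or more among stained carriers); non-carrier
# latent cuts put the cross-reactive grade-2+ exceedance at the observed
# specificity of the 2+ cutoff
CARRIER_GRADES <- list(l858r = c(0.132, 0.368, 0.500),
                       del19 = c(0.000, 0.350, 0.650))
STAIN_CUTS <- list(l858r = c(0.84, 3.63, 6.59),
                   del19 = c(0.67, 2.14, 4.29))
STAIN_NOISE <- list(l858r = 1.4, del19 = 1.4)

# intensity-grade-dependent percent-positive draw (0 when intensity is 0)
draw_percent <- function(intensity) {
  p <- numeric(length(intensity))
  idx <- intensity > 0
  if (any(idx)) {
    i <- intensity[idx]
    p[idx] <- 100 * stats::rbeta(sum(idx), 0.8 + 1.1 * i, 4.0 - 0.9 * i)
  }
  round(p, 0)
}

# cut a latent Gaussian into the 0-3 intensity scale
cut_intensity <- function(latent, cuts) {
  findInterval(latent, cuts)
}

# cognate staining of a mutation carrier: diffuse and high-percent, with a
# grade mix matching the observed intensity operating points (a minority of
# carriers stain only weakly)
draw_carrier_stain <- function(n, grade_probs = c(0, 0.35, 0.65)) {
  intensity <- sample(1:3, n, replace = TRUE, prob = grade_probs)
  percent <- pmin(100, round(100 * stats::rbeta(n, 6, 1.8), 0))
  percent <- pmax(percent, 15)  # cognate staining is diffuse, never focal
  data.frame(intensity = intensity, percent = percent)
}

# nonspecific staining of a non-carrier, driven by total-EGFR quickscore;
# the widening cuts keep cross-reactive staining predominantly mild (1+),
# occasionally moderate, and only exceptionally strong
# tumor-level susceptibility noise scales with the mechanism strength
# (noise_sd is the spread at the reference strength kappa = 10), so
# kappa = 0 switches nonspecific staining off entirely
draw_noncarrier_stain <- function(base, kappa, total_q,
                                  cuts = c(0.9, 2.9, 5.5), noise_sd = 1) {
  latent <- base + kappa * total_q / 300 +
    (kappa / 10) * stats::rnorm(length(total_q), sd = noise_sd)
  intensity <- cut_intensity(latent, cuts)
  data.frame(intensity = intensity, percent = draw_percent(intensity))
}

genotype_string <- function(class, n) {
  switch(class,
    e746a750 = rep("delE746-A750", n),
    del19_other = sample(c("delL747-T751", "delL747-P753", "delE746-T751insQ"),
                         n, replace = TRUE),
    l858r = ifelse(stats::runif(n) < 5 / 43,
                   paste0("L858R+", sample(c("V834L", "E709V", "T790M", "K757N"),
                                           n, replace = TRUE,
                                           prob = c(2, 1, 1, 1))),
                   "L858R"),
    other = sample(c("L861Q", "E709K+G719A", "E709K+G719S", "G719A+L861Q",
                     "N771-H773dupNPH", "K860I+L861Q", "R831C+L861R"),
                   n, replace = TRUE, prob = c(2, 1, 1, 1, 1, 1, 1)),
    wild = rep("wild", n))
}

#' Simulate a synthetic staining cohort
#'
#' Generates one row per collected tumor section: genotype (sequencing
#' truth), staining readings for the two mutation-specific antibodies, the
#' total-EGFR antibody and the pan-cytokeratin control, tumor content, sex
#' and smoking status.  `n_low_content` sections receive tumor content
#' below 60% and are meant to be excluded by [read_cohort()]'s enrollment
#' gate; all others lie above it.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return data.frame with `attr(, "sim_config")` set; columns
#'   `patient_id`, `genotype`, `sex`, `smoking`, `tumor_content`,
#'   `<marker>_intensity`/`<marker>_percent` for markers `l858r`, `del19`,
#'   `total_egfr`, `panck`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients + config$n_low_content
    gclass <- sample(names(config$genotype_probs), n, replace = TRUE,
                     prob = config$genotype_probs)
    genotype <- character(n)
    for (cl in unique(gclass)) {
      idx <- gclass == cl
      genotype[idx] <- genotype_string(cl, sum(idx))
    }
    # one cross-reactive L747-T751 deletion pattern per cohort
    cross_del <- integer(0)
    other_del <- which(gclass == "del19_other")
    if (length(other_del) > 0) {
      cross_del <- other_del[1]
      genotype[cross_del] <- "delL747-T751"
    }
    is_mut <- gclass != "wild"

    # sex and smoking with mutation-dependent prevalence (Bayes inversion of
    # the conditional mutation rates at the cohort's overall mutation rate)
    p_mut <- sum(config$genotype_probs[names(config$genotype_probs) != "wild"])
    p_female <- clamp01((p_mut - config$mut_rate_male) /
                          (config$mut_rate_female - config$mut_rate_male))
    p_ns <- clamp01((p_mut - config$mut_rate_smoker) /
                      (config$mut_rate_nonsmoker - config$mut_rate_smoker))
    p_f_mut <- clamp01(config$mut_rate_female * p_female / p_mut)
    p_f_wt <- clamp01((1 - config$mut_rate_female) * p_female / (1 - p_mut))
    p_ns_mut <- clamp01(config$mut_rate_nonsmoker * p_ns / p_mut)
    p_ns_wt <- clamp01((1 - config$mut_rate_nonsmoker) * p_ns / (1 - p_mut))
    sex <- ifelse(stats::runif(n) < ifelse(is_mut, p_f_mut, p_f_wt),
                  "female", "male")
    smoking <- ifelse(stats::runif(n) < ifelse(is_mut, p_ns_mut, p_ns_wt),
                      "never", "ever")

    # total EGFR expression: genotype-independent, so that nonspecific
    # mutation-marker staining of non-carriers is the only link between
    # total-EGFR level and mutation status
    tot_latent <- stats::rnorm(n, mean = 1.3)
    total_egfr_intensity <- cut_intensity(tot_latent, c(0.0, 1.3, 2.4))
    total_egfr_percent <- draw_percent(total_egfr_intensity)
    total_q <- quickscore(total_egfr_intensity, total_egfr_percent)

    stain_marker <- function(carrier, base, fn_rate, cuts, grade_probs,
                             noise_sd = 1, cross_idx = integer(0)) {
      out <- draw_noncarrier_stain(base, config$cross_reactivity, total_q,
                                   cuts, noise_sd)
      pos <- which(carrier)
      if (length(pos) > 0) {
        st <- draw_carrier_stain(length(pos), grade_probs)
        fn <- stats::runif(length(pos)) < fn_rate
        st$intensity[fn] <- 0
        st$percent[fn] <- 0
        out[pos, ] <- st
      }
      if (length(cross_idx) > 0) {
        out[cross_idx, ] <- draw_carrier_stain(length(cross_idx), grade_probs)
      }
      out
    }
    glab <- parse_genotype(genotype)
    l858r <- stain_marker(glab$is_L858R, config$marker_base[["l858r"]],
                          config$false_negative[["l858r"]],
                          cuts = STAIN_CUTS$l858r,
                          grade_probs = CARRIER_GRADES$l858r,
                          noise_sd = STAIN_NOISE$l858r)
    del19 <- stain_marker(glab$is_E746A750, config$marker_base[["del19"]],
                          config$false_negative[["del19"]],
                          cuts = STAIN_CUTS$del19,
                          grade_probs = CARRIER_GRADES$del19,
                          noise_sd = STAIN_NOISE$del19,
                          cross_idx = cross_del)

    panck_intensity <- sample(2:3, n, replace = TRUE, prob = c(0.15, 0.85))
    panck_percent <- pmin(100, round(100 * stats::rbeta(n, 8, 1), 0))

    tumor_content <- round(stats::runif(n, 62, 95), 0)
    low <- sample.int(n, config$n_low_content)
    tumor_content[low] <- round(stats::runif(config$n_low_content, 20, 58), 0)

    cohort <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      genotype = genotype,
      sex = sex,
      smoking = smoking,
      tumor_content = tumor_content,
      l858r_intensity = l858r$intensity,
      l858r_percent = l858r$percent,
      del19_intensity = del19$intensity,
      del19_percent = del19$percent,
      total_egfr_intensity = total_egfr_intensity,
      total_egfr_percent = total_egfr_percent,
      panck_intensity = panck_intensity,
      panck_percent = panck_percent,
      stringsAsFactors = FALSE
    )
    attr(cohort, "sim_config") <- config
    cohort
  })
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# uniform-censoring upper bound m such that P(Unif(0,m) < Exp(rate)) equals
# the requested censoring fraction (independent censoring, so the
# Kaplan-Meier estimator stays consistent)
censor_bound <- function(rate, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(m) (1 - exp(-rate * m)) / (rate * m) - censor_rate
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Attach recurrence, TKI treatment, response and PFS outcomes
#'
#' Adds the clinical-outcome columns to a simulated (or enrolled) cohort.
#' Recurrence and TKI treatment are Bernoulli; among TKI-treated patients
#' the responder flag is Bernoulli with an IHC-status-dependent rate, the
#' response category is PR for responders and SD/PD for non-responders,
#' and PFS is exponential with the configured group medians under
#' independent uniform censoring calibrated to `censor_rate`.  When
#' `config$ecog_scenario` is on, ECOG 2-4 multiplies the hazard by
#' `config$ecog_hr`.  Deterministic given `seed`.
#'
#' @param cohort a cohort data.frame; if it has no `ihc_call` column, the
#'   conventional single-marker rule (>10% cells at 1+ on either
#'   mutation-specific antibody) is used as the IHC status.
#' @param config a [sim_config()].
#' @param seed RNG seed for the outcome layer (default `config$seed + 1`).
#' @return the cohort with columns `ihc_call`, `recurrence`, `tki_treated`,
#'   `tki_line`, `ecog_ps`, `response`, `responder`, `pfs_months`,
#'   `pfs_event` (outcome columns are `NA` for untreated patients).
#' @export
simulate_outcomes <- function(cohort, config = sim_config(),
                              seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- nrow(cohort)
    if (!"ihc_call" %in% names(cohort)) {
      cohort$ihc_call <-
        intensity_positive(cohort$l858r_intensity, cohort$l858r_percent) |
        intensity_positive(cohort$del19_intensity, cohort$del19_percent)
    }
    cohort$recurrence <- stats::runif(n) < config$recurrence_rate
    cohort$tki_treated <- cohort$recurrence &
      stats::runif(n) < config$tki_fraction
    cohort$tki_line <- ifelse(cohort$tki_treated,
                              sample(1:4, n, replace = TRUE,
                                     prob = c(7, 12, 14, 4)),
                              NA_integer_)
    ecog_high <- stats::runif(n) < config$p_ecog_high
    cohort$ecog_ps <- ifelse(ecog_high, sample(2:4, n, replace = TRUE,
                                               prob = c(6, 2, 1)),
                             sample(0:1, n, replace = TRUE))
    p_resp <- ifelse(cohort$ihc_call, config$response_probs[["pos"]],
                     config$response_probs[["neg"]])
    responder <- stats::runif(n) < p_resp
    nonresp_cat <- sample(c("SD", "PD"), n, replace = TRUE, prob = c(4, 11))
    cohort$responder <- ifelse(cohort$tki_treated, responder, NA)
    cohort$response <- ifelse(cohort$tki_treated,
                              ifelse(responder, "PR", nonresp_cat),
                              NA_character_)

    rate <- log(2) / ifelse(cohort$ihc_call,
                            config$pfs_medians[["pos"]],
                            config$pfs_medians[["neg"]])
    hazard <- rate * ifelse(config$ecog_scenario & cohort$ecog_ps >= 2,
                            config$ecog_hr, 1)
    t_event <- stats::rexp(n, hazard)
    if (config$censor_rate > 0) {
      m_pos <- censor_bound(log(2) / config$pfs_medians[["pos"]],
                            config$censor_rate)
      m_neg <- censor_bound(log(2) / config$pfs_medians[["neg"]],
                            config$censor_rate)
      t_cens <- stats::runif(n, 0, ifelse(cohort$ihc_call, m_pos, m_neg))
    } else {
      t_cens <- rep(Inf, n)
    }
    obs <- pmin(t_event, t_cens)
    cohort$pfs_months <- ifelse(cohort$tki_treated,
                                pmax(round(obs, 1), 0.1), NA_real_)
    cohort$pfs_event <- ifelse(cohort$tki_treated,
                               as.integer(t_event <= t_cens), NA_integer_)
    cohort
  })
}
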