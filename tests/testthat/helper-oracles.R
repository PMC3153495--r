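# O(n^2) Mann-Whitney AUC: pairwise wins plus half-ties
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive closest-to-corner search over all candidate thresholds,
# ties broken toward higher specificity then larger threshold
brute_force_cutoff <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  d2 <- (1 - sens)^2 + (1 - spec)^2
  o <- order(d2, -spec, -thr)
  list(threshold = thr[o[1]], sensitivity = sens[o[1]],
       specificity = spec[o[1]], d2 = d2[o[1]])
}

# stratified paired-bootstrap p value for the AUC difference of two scores
# measured on the same subjects
bootstrap_paired_auc_p <- function(scores_a, scores_b, labels, n_boot,
                                   seed = 1) {
  set.seed(seed)
  pos_idx <- which(labels == 1)
  neg_idx <- which(labels == 0)
  obs <- brute_force_auc(scores_a, labels) - brute_force_auc(scores_b, labels)
  delta <- replicate(n_boot, {
    idx <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
    y <- labels[idx]
    brute_force_auc(scores_a[idx], y) - brute_force_auc(scores_b[idx], y)
  })
  # two-sided p from the centred bootstrap distribution of the difference
  2 * min(mean(delta - obs <= -abs(obs)) + 0.5 * mean(delta - obs == -abs(obs)),
          mean(delta - obs >= abs(obs)) + 0.5 * mean(delta - obs == abs(obs)),
          0.5)
}

# small deterministic cohort with known genotypes and staining, used by the
# feature-building and i/o tests
toy_cohort <- function() {
  data.frame(
    patient_id = sprintf("T%02d", 1:6),
    genotype = c("L858R", "L858R+V834L", "delE746-A750",
                 "delL747-T751", "wild", "wild"),
    sex = rep(c("female", "male"), 3),
    smoking = rep(c("never", "ever"), 3),
    tumor_content = c(90, 85, 80, 75, 70, 95),
    l858r_intensity = c(3, 2, 0, 0, 1, 0),
    l858r_percent = c(90, 60, 0, 0, 30, 0),
    del19_intensity = c(0, 0, 3, 2, 0, 1),
    del19_percent = c(0, 0, 80, 50, 0, 20),
    total_egfr_intensity = c(2, 3, 2, 1, 3, 1),
    total_egfr_percent = c(70, 90, 60, 30, 95, 20),
    panck_intensity = rep(3, 6),
    panck_percent = rep(100, 6),
    stringsAsFactors = FALSE
  )
}

# enrolled (tumor-content-gated) simulated cohort
enrolled_cohort <- function(seed = 1, ...) {
  co <- simulate_cohort(sim_config(seed = seed, ...))
  co[co$tumor_content >= 60, , drop = FALSE]
}
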