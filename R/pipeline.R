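#' Score a cohort under one scheme and evaluate it against sequencing truth
#'
#' For a single-feature scheme the score is the raw feature (intensity or
#' quickscore); for a two-feature scheme it is the predicted mutation
#' probability of the logistic model combining the mutation-marker feature
#' with total-EGFR expression.  The ROC is built over the scores, the
#' closest-to-corner cutoff selected, and the calls at that cutoff are
#' tabulated against the sequencing label.  If the maximum-likelihood
#' logistic fit hits complete separation, the Firth-penalized fit is used
#' and flagged in the result.
#'
#' @param cohort an enrolled cohort data.frame.
#' @param scheme a [scheme_spec()].
#' @return list with `scheme`, `scores`, `labels`, `fit` (or `NULL`),
#'   `firth_fallback`, `roc`, `auc`, `auc_ci`, `cutoff`, `confusion`,
#'   `metrics_exact`, `metrics_printed`.
#' @export
evaluate_scheme <- function(cohort, scheme) {
  feats <- build_features(cohort, scheme)
  fit <- NULL
  firth_fallback <- FALSE
  if (scheme$total_egfr_feature == "none") {
    scores <- drop(feats$x)
  } else {
    fit <- tryCatch(fit_logistic(feats$x, feats$y),
                    error = function(e) {
                      if (grepl("separation", conditionMessage(e))) NULL
                      else stop(e)
                    })
    if (is.null(fit)) {
      fit <- fit_logistic(feats$x, feats$y, firth = TRUE)
      firth_fallback <- TRUE
    }
    scores <- predict_probability(fit, feats$x)
  }
  roc <- roc_curve(scores, feats$y)
  cutoff <- optimal_cutoff(roc)
  calls <- scores >= cutoff$threshold
  confusion <- confusion_from_calls(calls, feats$y)
  list(scheme = scheme, scores = scores, labels = feats$y, fit = fit,
       firth_fallback = firth_fallback, roc = roc, auc = roc$auc,
       auc_ci = auc_ci_delong(scores, feats$y)$ci, cutoff = cutoff,
       confusion = confusion,
       metrics_exact = diagnostic_metrics(confusion, "exact"),
       metrics_printed = diagnostic_metrics(confusion, "printed"))
}

scheme_label <- function(scheme) {
  tot <- if (scheme$total_egfr_feature == "none") ""
         else paste0(" + total EGFR ", scheme$total_egfr_feature)
  paste0(scheme$target, " ", scheme$mutation_feature, tot)
}

#' Evaluate all scoring schemes for one target
#'
#' Runs [evaluate_scheme()] over the six schemes of a target, identifies
#' the best scheme by AUC, and compares it with the intensity-only
#' read-out by the DeLong paired test.
#'
#' @param cohort an enrolled cohort data.frame.
#' @param target `"L858R"` or `"delE746-A750"`.
#' @return list with `evaluations` (named by scheme label), `best_label`,
#'   `best`, `auc_comparison` (best vs intensity-only).
#' @export
evaluate_target <- function(cohort, target = c("L858R", "delE746-A750")) {
  target <- match.arg(target)
  schemes <- all_schemes(target)
  evals <- lapply(schemes, function(s) evaluate_scheme(cohort, s))
  names(evals) <- vapply(evals, function(e) scheme_label(e$scheme), "")
  aucs <- vapply(evals, `[[`, numeric(1), "auc")
  best_label <- names(which.max(aucs))
  intensity_label <- paste0(target, " intensity")
  cmp <- paired_auc_test(evals[[best_label]]$scores,
                         evals[[intensity_label]]$scores,
                         evals[[best_label]]$labels)
  list(evaluations = evals, best_label = best_label,
       best = evals[[best_label]], auc_comparison = cmp)
}

#' Composite detection accuracy across genotype groups
#'
#' Combines the per-marker calls into the clinically relevant composite
#' targets: each single target, all exon-19 deletions detected by the
#' deletion antibody, and the OR of both antibodies against the combined
#' genotypes.
#'
#' @param cohort an enrolled cohort data.frame.
#' @param l858r_call,del_call logical call vectors for the two antibodies.
#' @return named list of lists (`confusion`, `metrics_exact`,
#'   `metrics_printed`) for genotype groups `L858R`, `delE746-A750`,
#'   `all_del19`, `e746a750_or_l858r`, `del19_or_l858r`.
#' @export
composite_accuracy <- function(cohort, l858r_call, del_call) {
  g <- parse_genotype(cohort$genotype)
  rows <- list(
    L858R = list(call = l858r_call, truth = g$is_L858R),
    `delE746-A750` = list(call = del_call, truth = g$is_E746A750),
    all_del19 = list(call = del_call, truth = g$is_del19),
    e746a750_or_l858r = list(call = l858r_call | del_call,
                             truth = g$is_E746A750 | g$is_L858R),
    del19_or_l858r = list(call = l858r_call | del_call,
                          truth = g$is_del19 | g$is_L858R))
  lapply(rows, function(r) {
    ct <- confusion_from_calls(r$call, r$truth)
    list(confusion = ct,
         metrics_exact = diagnostic_metrics(ct, "exact"),
         metrics_printed = diagnostic_metrics(ct, "printed"))
  })
}

#' TKI outcome analysis by IHC status
#'
#' Restricted to TKI-treated patients: response rates by IHC status with
#' the appropriate categorical test (chi-squared, or Fisher's exact when
#' any expected count is below 5), Kaplan-Meier PFS per group with the
#' log-rank test, and a multivariate Cox model over sex, smoking, poor
#' performance status (ECOG 2-4), IHC status and treatment line.
#'
#' @param cohort cohort with outcome columns (`ihc_call`, `tki_treated`,
#'   `responder`, `pfs_months`, `pfs_event`, and optionally `sex`,
#'   `smoking`, `ecog_ps`, `tki_line` for the Cox model).
#' @return list with `n_treated`, `response` (rates and test), `km`
#'   (per-group medians), `logrank`, `cox` (or `NULL` when the covariates
#'   are unavailable or the fit fails).
#' @export
outcome_analysis <- function(cohort) {
  needed <- c("ihc_call", "tki_treated", "responder", "pfs_months", "pfs_event")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort lacks outcome column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tki <- cohort[!is.na(cohort$tki_treated) & cohort$tki_treated, , drop = FALSE]
  if (nrow(tki) == 0) stop("no TKI-treated patients", call. = FALSE)
  pos <- tki$ihc_call
  resp_tab <- matrix(c(sum(tki$responder[pos]), sum(!tki$responder[pos]),
                       sum(tki$responder[!pos]), sum(!tki$responder[!pos])),
                     2, 2, byrow = TRUE,
                     dimnames = list(c("IHC+", "IHC-"),
                                     c("responder", "non-responder")))
  response <- list(
    table = resp_tab,
    rate_pos = if (sum(pos) > 0) mean(tki$responder[pos]) else NA_real_,
    rate_neg = if (sum(!pos) > 0) mean(tki$responder[!pos]) else NA_real_,
    test = categorical_test(resp_tab))
  km <- lapply(split(tki, pos), function(d)
    km_estimate(d$pfs_months, d$pfs_event))
  names(km) <- ifelse(names(km) == "TRUE", "ihc_positive", "ihc_negative")
  lr <- logrank_test(tki$pfs_months, tki$pfs_event, pos)
  cox <- NULL
  cox_covs <- c("sex", "smoking", "ecog_ps", "tki_line")
  if (all(cox_covs %in% names(tki))) {
    d <- data.frame(pfs_months = tki$pfs_months, pfs_event = tki$pfs_event,
                    male = as.integer(tki$sex == "male"),
                    ever_smoker = as.integer(tki$smoking == "ever"),
                    ecog_2_4 = as.integer(tki$ecog_ps >= 2),
                    ihc_positive = as.integer(pos),
                    second_line_plus = as.integer(tki$tki_line >= 2))
    covs <- names(d)[-(1:2)][vapply(d[-(1:2)], function(x)
      length(unique(x)) > 1, logical(1))]
    cox <- tryCatch(cox_fit(d, "pfs_months", "pfs_event", covs),
                    error = function(e) NULL)
  }
  list(n_treated = nrow(tki), response = response,
       km = lapply(km, function(k) list(median = k$median,
                                        median_defined = k$median_defined,
                                        n = k$n, n_events = k$n_events)),
       logrank = lr, cox = if (is.null(cox)) NULL else cox$table)
}

#' Run the full scoring-and-evaluation pipeline
#'
#' Evaluates every scoring scheme for both targets, assembles the composite
#' detection-accuracy rows, runs the paired AUC comparisons, and (when
#' outcome columns are present) the TKI outcome analysis.  The result is a
#' plain list reproducible from the same cohort, suitable for
#' [write_report()].
#'
#' @param cohort an enrolled cohort data.frame (e.g. from [read_cohort()]
#'   or [simulate_cohort()] after the enrollment gate).
#' @param targets which targets to evaluate.
#' @param outcomes run the TKI outcome stage if its columns are present
#'   (default `TRUE`); when absent the stage is skipped with a message.
#' @return list of class `stainclass_report` with elements `targets` (per
#'   target: scheme table and evaluations), `composite`, `outcomes` (or
#'   `NULL`), `meta`.
#' @export
run_pipeline <- function(cohort,
                         targets = c("L858R", "delE746-A750"),
                         outcomes = TRUE) {
  validate_cohort(cohort)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  evals <- lapply(targets, function(tg)
    stage(paste0("scoring:", tg), evaluate_target(cohort, tg)))
  names(evals) <- targets
  best_call <- function(tg) {
    e <- evals[[tg]]$best
    e$scores >= e$cutoff$threshold
  }
  l858r_call <- if ("L858R" %in% targets) best_call("L858R") else NULL
  del_call <- if ("delE746-A750" %in% targets) best_call("delE746-A750") else NULL
  composite <- if (!is.null(l858r_call) && !is.null(del_call)) {
    stage("composite", composite_accuracy(cohort, l858r_call, del_call))
  } else NULL
  out <- NULL
  outcome_cols <- c("ihc_call", "tki_treated", "responder",
                    "pfs_months", "pfs_event")
  if (outcomes) {
    if (all(outcome_cols %in% names(cohort))) {
      out <- stage("outcomes", outcome_analysis(cohort))
    } else {
      message("outcome columns absent; survival stage skipped")
    }
  }
  structure(list(targets = evals, composite = composite, outcomes = out,
                 meta = list(n_patients = nrow(cohort),
                             package_version =
                               as.character(utils::packageVersion("stainclass")),
                             r_version = R.version.string)),
            class = "stainclass_report")
}

#' Summary table of a pipeline report
#'
#' One row per scoring scheme with AUC, DeLong CI, cutoff and the
#' printed-convention diagnostic metrics — the layout of a clinical
#' scoring-comparison table.
#'
#' @param report a `stainclass_report` from [run_pipeline()].
#' @return data.frame.
#' @export
report_scheme_table <- function(report) {
  rows <- list()
  for (tg in names(report$targets)) {
    for (lbl in names(report$targets[[tg]]$evaluations)) {
      e <- report$targets[[tg]]$evaluations[[lbl]]
      m <- e$metrics_printed
      rows[[length(rows) + 1]] <- data.frame(
        scheme = lbl, auc = e$auc,
        auc_lower = e$auc_ci[1], auc_upper = e$auc_ci[2],
        cutoff = e$cutoff$threshold,
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, npv = m$npv, lr_plus = m$lr_plus,
        lr_minus = m$lr_minus, accuracy = m$accuracy,
        firth = e$firth_fallback)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.stainclass_report <- function(x, ...) {
  cat(sprintf("stainclass report: %d patients\n", x$meta$n_patients))
  tab <- report_scheme_table(x)
  tab$auc <- round(tab$auc, 3)
  print(tab[, c("scheme", "auc", "sensitivity", "specificity", "accuracy")],
        row.names = FALSE)
  for (tg in names(x$targets)) {
    cmp <- x$targets[[tg]]$auc_comparison
    cat(sprintf("%s: best scheme '%s'; vs intensity-only AUC %.3f vs %.3f (p = %.3g)\n",
                tg, x$targets[[tg]]$best_label, cmp$auc_a, cmp$auc_b,
                cmp$p_value))
  }
  if (!is.null(x$outcomes)) {
    o <- x$outcomes
    cat(sprintf("TKI outcomes (n = %d): response %.1f%% vs %.1f%% (p = %.3g); log-rank p = %.3g\n",
                o$n_treated, 100 * o$response$rate_pos,
                100 * o$response$rate_neg, o$response$test$p_value,
                o$logrank$p_value))
  }
  invisible(x)
}

# strip closures and heavyweight objects so a report serializes cleanly
report_for_json <- function(report) {
  slim_eval <- function(e) {
    list(scheme = unclass(e$scheme),
         coefficients = if (is.null(e$fit)) NULL else as.list(e$fit$coefficients),
         firth = e$firth_fallback,
         auc = e$auc, auc_ci = e$auc_ci,
         cutoff = unclass(e$cutoff),
         confusion = unclass(e$confusion),
         metrics_printed = unclass(e$metrics_printed)[1:7],
         roc_points = e$roc$points)
  }
  list(
    targets = lapply(report$targets, function(tg) list(
      best = tg$best_label,
      auc_comparison = unclass(tg$auc_comparison),
      evaluations = lapply(tg$evaluations, slim_eval))),
    composite = lapply(report$composite, function(r) list(
      confusion = unclass(r$confusion),
      metrics_printed = unclass(r$metrics_printed)[1:7])),
    outcomes = report$outcomes,
    meta = report$meta)
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `stainclass_report`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_for_json(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
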