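#' Build a 2x2 confusion table from calls and sequencing truth
#'
#' @param calls logical/0-1 classifier calls (IHC positivity).
#' @param truth logical/0-1 sequencing truth.
#' @return object of class `confusion_table`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_from_calls <- function(calls, truth) {
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  if (length(calls) != length(truth)) {
    stop("calls and truth must have equal length", call. = FALSE)
  }
  stopifnot(!anyNA(calls), !anyNA(truth))
  confusion_table(tp = sum(calls & truth), fp = sum(calls & !truth),
                  fn = sum(!calls & truth), tn = sum(!calls & !truth))
}

#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn nonnegative integer counts (true/false
#'   positives/negatives against sequencing truth).
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion table is empty", call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("call+", "call-"), c("truth+", "truth-")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, diagnostic accuracy (all as percentages) and the likelihood
#' ratios LR+ = sens/(1 - spec) and LR- = (1 - sens)/spec.
#'
#' Two rounding conventions are provided.  `"exact"` reports unrounded
#' percentages and forms the likelihood ratios from the unrounded
#' proportions.  `"printed"` reproduces the arithmetic of published
#' clinical tables: sensitivity and specificity (and the other percentages)
#' are first rounded to one decimal percent, and the likelihood ratios are
#' then formed from the *rounded* percentages and rounded to three
#' decimals.  (From the 2x2 table 38/23/5/77 the exact LR+ is
#' (38/43)/(23/100) = 3.842 while the printed convention gives
#' 88.4/23.0 = 3.843 — only the printed convention matches tables typeset
#' from one-decimal percentages.)
#'
#' A metric with a zero denominator is reported as `NA` with its name in
#' the `undefined` attribute; LR+ with specificity 100% is reported as
#' `Inf` and flagged.
#'
#' @param table a [confusion_table()].
#' @param rounding `"exact"` or `"printed"`.
#' @return object of class `metric_set`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (percent), `lr_plus`,
#'   `lr_minus`, `rounding`, `undefined` (character vector of flagged
#'   metrics).
#' @examples
#' diagnostic_metrics(confusion_table(38, 23, 5, 77), "printed")
#' @export
diagnostic_metrics <- function(table, rounding = c("exact", "printed")) {
  stopifnot(inherits(table, "confusion_table"))
  rounding <- match.arg(rounding)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    100 * num / den
  }
  sens <- ratio(table$tp, table$tp + table$fn, "sensitivity")
  spec <- ratio(table$tn, table$tn + table$fp, "specificity")
  ppv <- ratio(table$tp, table$tp + table$fp, "ppv")
  npv <- ratio(table$tn, table$tn + table$fn, "npv")
  acc <- 100 * (table$tp + table$tn) /
    (table$tp + table$fp + table$fn + table$tn)
  if (rounding == "printed") {
    sens <- round(sens, 1); spec <- round(spec, 1)
    ppv <- round(ppv, 1); npv <- round(npv, 1); acc <- round(acc, 1)
  }
  lr_from <- function(num, den, name) {
    if (is.na(num) || is.na(den)) { undef <<- c(undef, name); return(NA_real_) }
    if (den == 0) { undef <<- c(undef, name); return(Inf) }
    if (rounding == "printed") round(num / den, 3) else num / den
  }
  lr_plus <- lr_from(sens, 100 - spec, "lr_plus")
  lr_minus <- lr_from(100 - sens, spec, "lr_minus")
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, accuracy = acc, lr_plus = lr_plus,
                 lr_minus = lr_minus, rounding = rounding,
                 undefined = undef),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.1f%%  specificity %.1f%%  PPV %.1f%%  ",
                     "NPV %.1f%%  LR+ %.3f  LR- %.3f  accuracy %.1f%% [%s]\n"),
              x$sensitivity, x$specificity, x$ppv, x$npv,
              x$lr_plus, x$lr_minus, x$accuracy, x$rounding))
  if (length(x$undefined)) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

as_2x2 <- function(table) {
  if (inherits(table, "confusion_table")) {
    matrix(c(table$tp, table$fp, table$fn, table$tn), 2, 2, byrow = TRUE)
  } else {
    m <- as.matrix(table)
    stopifnot(identical(dim(m), c(2L, 2L)))
    m
  }
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction; p value from the chi-squared distribution
#' with one degree of freedom.  Zero row or column margins are an error.
#'
#' @param table a 2x2 matrix of counts or a [confusion_table()].
#' @return list with `statistic` and `p_value`.
#' @export
pearson_chi2 <- function(table) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin: expected counts are undefined", call. = FALSE)
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p value: the sum of hypergeometric probabilities, at the
#' observed margins, of tables no more probable than the observed one.
#'
#' @param table a 2x2 matrix of counts or a [confusion_table()].
#' @return two-sided p value.
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  unname(stats::fisher.test(m)$p.value)
}

#' Choose between the chi-squared and Fisher's exact test
#'
#' Applies the conventional small-sample trigger: Fisher's exact test when
#' any expected cell count under independence is below 5, Pearson's
#' chi-squared otherwise.
#'
#' @param table a 2x2 matrix of counts or a [confusion_table()].
#' @return list with `method` (`"chi2"` or `"fisher"`), `p_value`, and
#'   `statistic` (`NA` for Fisher).
#' @export
categorical_test <- function(table) {
  m <- as_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(method = "fisher", statistic = NA_real_, p_value = fisher_exact(m))
  } else {
    ht <- pearson_chi2(m)
    list(method = "chi2", statistic = ht$statistic, p_value = ht$p_value)
  }
}

#' Wilson score confidence interval for a proportion
#'
#' Provided as an extension for reporting uncertainty on sensitivity,
#' specificity and predictive values.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return length-2 numeric vector (lower, upper), on the 0-1 scale.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = centre - half, upper = centre + half)
}
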