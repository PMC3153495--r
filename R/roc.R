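#' Empirical ROC curve
#'
#' Builds the empirical receiver operating characteristic of a score for a
#' binary truth, under the convention that a patient is called positive when
#' the score is at least the threshold.  Candidate thresholds are the unique
#' observed scores plus `-Inf` / `+Inf` sentinels, so the (sensitivity,
#' specificity) endpoints (1, 0) and (0, 1) are always present and tied
#' scores share one vertex.  The AUC is computed as the Mann-Whitney
#' statistic (pairwise wins plus half-ties over `n_pos * n_neg`), which
#' equals the trapezoidal area under the (1 - specificity, sensitivity)
#' polyline.
#'
#' @param scores numeric vector, oriented so that larger values are more
#'   suspicious for mutation.
#' @param labels 0/1 (or logical) truth vector of the same length.
#' @return object of class `roc_curve`: list with `points` (data.frame of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("labels contain a single class; ROC needs >=1 positive and >=1 negative",
         call. = FALSE)
  }
  u <- sort(unique(scores))
  thr <- c(-Inf, u, Inf)
  pos_counts <- tabulate(match(scores[labels == 1], u), nbins = length(u))
  neg_counts <- tabulate(match(scores[labels == 0], u), nbins = length(u))
  # sens(t) = P(pos >= t), spec(t) = P(neg < t), via cumulative counts
  pos_ge <- rev(cumsum(rev(pos_counts)))
  neg_lt <- c(0, cumsum(neg_counts)[-length(u)])
  sens <- c(1, pos_ge / n_pos, 0)
  spec <- c(0, neg_lt / n_neg, 1)
  r <- rank(scores)  # midranks handle ties as half-wins
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("empirical ROC: AUC %.4f (%d positives, %d negatives, %d vertices)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve a [roc_curve()].
#' @return the trapezoid area of the (1 - specificity, sensitivity) polyline.
#' @keywords internal
trapezoid_auc <- function(curve) {
  fpr <- 1 - curve$points$specificity
  tpr <- curve$points$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Closest-to-corner optimal cutoff of a ROC curve
#'
#' Selects the ROC vertex minimizing the squared distance to the perfect
#' classifier, d^2 = (1 - sensitivity)^2 + (1 - specificity)^2.  Ties on
#' d^2 are broken toward the higher-specificity vertex (fewer false
#' positives); exact duplicates resolve to the larger threshold.
#'
#' @param curve a [roc_curve()].
#' @return object of class `cutoff_result`: list with `threshold`,
#'   `sensitivity`, `specificity`, `d2`.
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  d2 <- (1 - pts$sensitivity)^2 + (1 - pts$specificity)^2
  o <- order(d2, -pts$specificity, -pts$threshold)
  best <- o[1]
  structure(list(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 d2 = d2[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("optimal cutoff %.4g: sensitivity %.1f%%, specificity %.1f%% (d2 = %.4f)\n",
              x$threshold, 100 * x$sensitivity, 100 * x$specificity, x$d2))
  invisible(x)
}

# DeLong structural components: for each positive the fraction of negatives
# it beats (ties half), and vice versa.  Midrank formulation, O(n log n):
# for a positive with overall midrank R and within-positive midrank R1,
# V10 = (R - R1)/n_neg; symmetrically for negatives.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance and confidence interval for one AUC
#'
#' @param scores,labels as in [roc_curve()].
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `var`, `ci` (DeLong asymptotic interval,
#'   truncated to the 0-1 range).
#' @export
auc_ci_delong <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  comp <- delong_components(as.numeric(scores), labels)
  v <- stats::var(comp$v10) / length(comp$v10) +
    stats::var(comp$v01) / length(comp$v01)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = comp$auc, var = v,
       ci = pmin(1, pmax(0, comp$auc + c(-1, 1) * z * sqrt(v))))
}

#' DeLong test for two paired (correlated) AUCs
#'
#' Compares the AUCs of two scores measured on the same patients with
#' DeLong's nonparametric structural-components estimate of
#' `var(auc_a - auc_b)`, which accounts for the correlation induced by the
#' pairing.  The statistic `z = (auc_a - auc_b)/sd` is referred to the
#' standard normal for a two-sided p value.
#'
#' @param scores_a,scores_b numeric score vectors on the same patients.
#' @param labels common 0/1 truth vector.
#' @return object of class `paired_auc_test`: list with `auc_a`, `auc_b`,
#'   `delta`, `var`, `z`, `p_value`.
#' @export
paired_auc_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  a <- delong_components(as.numeric(scores_a), labels)
  b <- delong_components(as.numeric(scores_b), labels)
  m <- length(a$v10); n <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  if (v <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      stop("degenerate variance: paired AUC difference is nonzero but the DeLong variance estimate is zero",
           call. = FALSE)
    }
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, delta = delta,
                 var = max(v, 0), z = z, p_value = p),
            class = "paired_auc_test")
}

#' @export
print.paired_auc_test <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: %.4f vs %.4f (z = %.3f, p = %.4g)\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}
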