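#' Define an IHC scoring scheme
#'
#' A scheme names the target mutation, how the mutation-specific antibody is
#' quantified (`"intensity"` or `"qscore"`), and whether and how total-EGFR
#' expression enters as a second feature (`"none"`, `"intensity"` or
#' `"qscore"`).  The eight combinations per target cover the single-marker
#' read-outs and the four two-feature combined models.
#'
#' @param target `"L858R"` or `"delE746-A750"`.
#' @param mutation_feature `"intensity"` or `"qscore"`.
#' @param total_egfr_feature `"none"`, `"intensity"` or `"qscore"`.
#' @return an object of class `scheme_spec`.
#' @export
scheme_spec <- function(target = c("L858R", "delE746-A750"),
                        mutation_feature = c("qscore", "intensity"),
                        total_egfr_feature = c("qscore", "intensity", "none")) {
  target <- match.arg(target)
  mutation_feature <- match.arg(mutation_feature)
  total_egfr_feature <- match.arg(total_egfr_feature)
  structure(list(target = target,
                 mutation_feature = mutation_feature,
                 total_egfr_feature = total_egfr_feature),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  tot <- if (x$total_egfr_feature == "none") ""
         else paste0(" + total EGFR ", x$total_egfr_feature)
  cat(sprintf("scheme: %s %s%s\n", x$target, x$mutation_feature, tot))
  invisible(x)
}

#' All scoring schemes for one target
#'
#' The six schemes evaluated per target: the two single-feature read-outs
#' (intensity, quickscore) and the four combined models crossing the
#' mutation-marker feature with the total-EGFR feature.
#'
#' @param target `"L858R"` or `"delE746-A750"`.
#' @return list of [scheme_spec()] objects.
#' @export
all_schemes <- function(target = c("L858R", "delE746-A750")) {
  target <- match.arg(target)
  grid <- expand.grid(mut = c("intensity", "qscore"),
                      tot = c("none", "intensity", "qscore"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scheme_spec(target, grid$mut[i], grid$tot[i]))
}

marker_for_target <- function(target) {
  switch(target, "L858R" = "l858r", "delE746-A750" = "del19",
         stop("unknown target: ", target, call. = FALSE))
}

feature_column <- function(cohort, marker, feature) {
  icol <- paste0(marker, "_intensity")
  pcol <- paste0(marker, "_percent")
  missing <- setdiff(if (feature == "qscore") c(icol, pcol) else icol,
                     names(cohort))
  if (length(missing) > 0) {
    stop(sprintf("cohort is missing stain column(s) required by the scheme: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  switch(feature,
         intensity = as.numeric(cohort[[icol]]),
         qscore = quickscore(cohort[[icol]], cohort[[pcol]]))
}

#' Build the feature matrix and label vector for a scoring scheme
#'
#' One row per patient.  The label is 1 when the sequencing genotype matches
#' the scheme target: for L858R, any genotype containing an L858R component
#' (complex mutations such as `"L858R+V834L"` count); for delE746-A750, only
#' the exact E746-A750 deletion.
#'
#' @param cohort a cohort data.frame with `genotype` and the stain columns
#'   `<marker>_intensity` / `<marker>_percent` needed by the scheme.
#' @param scheme a [scheme_spec()].
#' @return list with `x` (numeric matrix, one column per feature), `y`
#'   (0/1 integer labels) and `scheme`.
#' @export
build_features <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "scheme_spec"))
  if (!"genotype" %in% names(cohort)) {
    stop("cohort has no 'genotype' column", call. = FALSE)
  }
  labels <- parse_genotype(cohort$genotype)
  y <- if (scheme$target == "L858R") labels$is_L858R else labels$is_E746A750
  marker <- marker_for_target(scheme$target)
  x <- cbind(mutation = feature_column(cohort, marker, scheme$mutation_feature))
  colnames(x) <- paste0(marker, "_", scheme$mutation_feature)
  if (scheme$total_egfr_feature != "none") {
    tot <- feature_column(cohort, "total_egfr", scheme$total_egfr_feature)
    x <- cbind(x, tot)
    colnames(x)[2] <- paste0("total_egfr_", scheme$total_egfr_feature)
  }
  list(x = x, y = as.integer(y), scheme = scheme)
}

#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression used to convert IHC features into
#' a predicted mutation probability.  Fitting is plain Newton/IRLS with
#' step-halving so the deviance is non-increasing across iterations; no
#' regularization is applied.  Complete separation (a hyperplane classifies
#' the training data perfectly, driving the deviance to zero and the
#' coefficients to infinity) is detected and raised as an error unless
#' `firth = TRUE`, in which case Firth's bias-reduced penalized likelihood
#' (Jeffreys-prior score correction) is used, which remains finite under
#' separation.
#'
#' @param x numeric feature matrix (no intercept column), or vector.
#' @param y 0/1 labels.
#' @param tol convergence tolerance on the deviance change (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @param firth use Firth's penalized likelihood (default `FALSE`).
#' @return object of class `logit_fit`: list with `coefficients` (intercept
#'   first), `deviance`, `converged`, `n_iter`, `vcov` (inverse observed
#'   information), `firth`.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L, firth = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("labels contain a single class; need at least one case and one control",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- numeric(p)
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  dev_bernoulli <- function(mu) {
    eps <- .Machine$double.xmin
    -2 * sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  }
  dev <- dev_bernoulli(mu)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    XtW <- t(X * w)
    info <- XtW %*% X
    resid <- y - mu
    if (firth) {
      # hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
      h <- rowSums((X %*% solve(info)) * (X * w))
      resid <- resid + h * (0.5 - mu)
    }
    score <- drop(t(X) %*% resid)
    step <- solve(info, score)
    # step-halving: accept only a non-increasing deviance
    ok <- FALSE
    for (half in 0:20) {
      beta_new <- beta + step / 2^half
      eta_new <- drop(X %*% beta_new)
      mu_new <- stats::plogis(eta_new)
      dev_new <- dev_bernoulli(mu_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    delta <- dev - dev_new
    beta <- beta_new; mu <- mu_new; dev <- dev_new
    if (!firth && (dev < 1e-6 || max(abs(beta)) > 1e3)) {
      stop(paste("complete separation detected: a linear combination of the",
                 "features classifies the training data perfectly, so the",
                 "maximum-likelihood estimates diverge.",
                 "Consider fit_logistic(..., firth = TRUE)."), call. = FALSE)
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  w <- pmax(mu * (1 - mu), 1e-12)
  vcov <- solve(t(X * w) %*% X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 deviance = dev, converged = converged, n_iter = iter,
                 vcov = vcov, firth = firth),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("logistic fit (%s): deviance %.4f after %d iterations%s\n",
              if (x$firth) "Firth-penalized" else "maximum likelihood",
              x$deviance, x$n_iter,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients)
  invisible(x)
}

#' Predicted mutation probability from a fitted logistic model
#'
#' Evaluates the fitted probability `plogis(b0 + x %*% b)` for each patient.
#' The prediction is strictly monotone in the linear predictor, so rankings
#' (and hence ROC curves) of a single-feature model coincide with those of
#' the raw feature.
#'
#' @param fit a `logit_fit` from [fit_logistic()].
#' @param x feature matrix or vector with the same columns used in fitting.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, x) {
  stopifnot(inherits(fit, "logit_fit"))
  x <- as.matrix(x)
  if (ncol(x) != length(fit$coefficients) - 1) {
    stop(sprintf("feature dimension (%d) does not match coefficients (%d)",
                 ncol(x), length(fit$coefficients) - 1), call. = FALSE)
  }
  stats::plogis(drop(cbind(1, x) %*% fit$coefficients))
}
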