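#' Kaplan-Meier estimate of a survival function
#'
#' Product-limit estimator of progression-free survival (or any
#' right-censored time-to-event outcome), with the median defined as the
#' smallest time at which the estimated survival drops to 0.5 or below.
#' When the curve never reaches 0.5 the median is reported as `NA` with
#' `median_defined = FALSE`.
#'
#' @param time positive event/censoring times (months).
#' @param event 1 = progression/death observed, 0 = censored.
#' @return object of class `km_fit`: list with `time`, `surv` (step
#'   function values after each distinct event time), `median`,
#'   `median_defined`, `n`, `n_events`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  # median: smallest t with S(t) <= 0.5 (not survfit's midpoint convention)
  hit <- which(fit$surv <= 0.5)
  med <- if (length(hit) > 0) fit$time[hit[1]] else NA_real_
  structure(list(time = fit$time, surv = fit$surv,
                 median = med,
                 median_defined = !is.na(med),
                 n = length(time), n_events = sum(event), fit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (x$median_defined) format(x$median) else "not reached"))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a `km_fit`.
#' @param t times at which to evaluate S(t).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_fit"))
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (length(idx) == 0) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' @param time,event as in [km_estimate()].
#' @param group a factor-like vector with at least two observed levels.
#' @return list with `chisq`, `df`, `p_value`, and the per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("log-rank test needs at least two groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards regression with Efron tie handling
#'
#' Fits a Cox model by partial-likelihood maximization and reports hazard
#' ratios with Wald confidence intervals and p values.  The Efron
#' approximation for tied event times is the default (ties are common with
#' month-resolution follow-up); Breslow is available via `ties`.
#' Non-convergence or a monotone partial likelihood (infinite coefficient,
#' e.g. a group with no events) is raised as an error.
#'
#' @param data data.frame containing the columns named below.
#' @param time_col,event_col column names for time and event indicator.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf confidence level for the hazard-ratio intervals.
#' @return object of class `cox_fit`: data.frame `table` with one row per
#'   model term (`hr`, `lower`, `upper`, `p_value`), plus `n`, `n_events`
#'   and the underlying [survival::coxph] object as `fit`.
#' @export
cox_fit <- function(data, time_col = "pfs_months", event_col = "pfs_event",
                    covariates, ties = c("efron", "breslow"), conf = 0.95) {
  ties <- match.arg(ties)
  stopifnot(all(c(time_col, event_col, covariates) %in% names(data)))
  if (sum(data[[event_col]]) < 1) stop("no events observed", call. = FALSE)
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      stop(sprintf("covariate '%s' is constant", cv), call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge|Loglik converged before",
                conditionMessage(w))) {
        stop(paste("Cox fit failed (monotone likelihood or non-convergence):",
                   conditionMessage(w)), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tab <- data.frame(term = names(beta),
                    hr = exp(beta),
                    lower = exp(beta - z * se),
                    upper = exp(beta + z * se),
                    p_value = 2 * stats::pnorm(-abs(beta / se)),
                    row.names = NULL)
  structure(list(table = tab, n = fit$n, n_events = fit$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model: n = %d, events = %d\n", x$n, x$n_events))
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "hr", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier convention
#'
#' Estimates the median follow-up duration by flipping the event indicator
#' (censorings become the "events"), the standard reverse-KM estimator.
#'
#' @param time,event as in [km_estimate()].
#' @return median follow-up (same units as `time`), `NA` if undefined.
#' @export
median_followup <- function(time, event) {
  km_estimate(time, 1 - event)$median
}

#' Classify treatment response categories into responders
#'
#' Complete and partial responses count as response; stable and
#' progressive disease do not.
#'
#' @param response character vector with values in CR, PR, SD, PD.
#' @return logical vector.
#' @export
is_responder <- function(response) {
  bad <- setdiff(unique(response[!is.na(response)]), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0) {
    stop("unknown response category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  response %in% c("CR", "PR")
}
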