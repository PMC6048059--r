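# Survival association of patient H-scores -------------------------------
#
# Thin, contract-checked layer over the survival package: Kaplan-Meier
# product-limit curves, the log-rank test, and Cox proportional-hazards
# fits with the Efron tie correction, plus the quartile / median-split
# grouping rules used for the published comparisons.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive survival times.
#' @param event Logical (or 0/1) event indicators.
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` — one row per distinct observed time, survival
#'   non-increasing from 1.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event
#' times, 1 degree of freedom.
#'
#' @param time Positive survival times.
#' @param event Event indicators.
#' @param group Two-level grouping vector; each group must contain at
#'   least one event.
#' @return List `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("need exactly two groups", call. = FALSE)
  event <- as.logical(event)
  if (any(tapply(event, g, sum) < 1)) {
    stop("each group needs at least one event", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximises the partial likelihood with the Efron tie correction;
#' standard errors come from the inverse observed information, CIs are
#' Wald (`exp(coef +/- 1.96 se)`), p-values are Wald tests.
#'
#' @param covariates data.frame of covariates (numeric, logical or
#'   factor; no constant columns).
#' @param time Positive survival times.
#' @param event Event indicators; at least `ncol + 1` events.
#' @return Object of class `cox_result`: a data.frame `term`, `coef`,
#'   `hr`, `se`, `ci_low`, `ci_high`, `p`, with attributes `n`,
#'   `n_events` and `converged`.
#' @export
cox_fit <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  event <- as.logical(event)
  if (any(vapply(covariates, function(v) length(unique(v)) < 2L,
                 logical(1)))) {
    stop("constant covariate", call. = FALSE)
  }
  if (sum(event) < ncol(covariates) + 1L) {
    stop("too few events for the number of covariates", call. = FALSE)
  }
  dat <- cbind(covariates, .time = time, .event = event)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(
      stats::as.formula(paste(
        "survival::Surv(.time, .event) ~",
        paste(sprintf("`%s`", names(covariates)), collapse = " + "))),
      data = dat, ties = "efron"
    ),
    warning = function(w) {
      if (grepl("converge|infinit|singular", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  if (anyNA(co)) stop("singular information matrix", call. = FALSE)
  se <- sqrt(diag(fit$var))
  z <- co / se
  out <- data.frame(
    term = names(co), coef = unname(co), hr = exp(unname(co)),
    se = se, ci_low = exp(unname(co) - 1.96 * se),
    ci_high = exp(unname(co) + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z))
  )
  rownames(out) <- NULL
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  attr(out, "converged") <- converged
  attr(out, "loglik") <- fit$loglik
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Quartile labels computed on the combined dataset
#'
#' Cut points are the 25/50/75 empirical percentiles of the combined
#' input (so cohorts analysed separately still share one grouping);
#' ties go to the lower quartile. All-equal input yields a single
#' degenerate quartile with a warning.
#'
#' @param x Numeric H-scores of all cohorts pooled, n >= 8.
#' @return Integer labels 1-4, same order as `x`.
#' @export
split_quartiles <- function(x) {
  if (length(x) < 8L) stop("need at least 8 patients", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(x)) == 1L) {
    warning("all values identical: degenerate quartiles", call. = FALSE)
  }
  1L + (x > q[1]) + (x > q[2]) + (x > q[3])
}

#' Median split into low/high expression
#'
#' `"high"` iff the value exceeds the median of the supplied dataset;
#' ties go to `"low"`.
#'
#' @param x Numeric vector, n >= 2.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  if (length(x) < 2L) stop("need at least 2 patients", call. = FALSE)
  factor(ifelse(x > stats::median(x), "high", "low"),
         levels = c("low", "high"))
}

#' Subgroup analysis: analyte effect within strata of another marker
#'
#' Median-splits patients on the stratifier marker's H-score (combined
#' data), then fits a univariable Cox model of the analyte H-score per
#' unit within each stratum.
#'
#' @param patients data.frame with `time_months`, `event`, and the two
#'   H-score columns.
#' @param stratifier_col Column holding the stratifier H-score.
#' @param analyte_col Column holding the analyte H-score.
#' @return Named list (`low`, `high`) of `cox_result` objects; a
#'   stratum too small to fit raises an error naming the stratum.
#' @export
subgroup_analysis <- function(patients, stratifier_col, analyte_col) {
  stopifnot(all(c(stratifier_col, analyte_col, "time_months", "event")
                %in% names(patients)))
  strata <- median_split(patients[[stratifier_col]])
  out <- list()
  for (lev in levels(strata)) {
    sub <- patients[strata == lev, , drop = FALSE]
    if (nrow(sub) == 0L || sum(as.logical(sub$event)) < 3L) {
      stop("stratum '", lev, "' has too few events for a Cox fit",
           call. = FALSE)
    }
    covs <- sub[, analyte_col, drop = FALSE]
    names(covs) <- "h_score"
    out[[lev]] <- cox_fit(covs, sub$time_months, sub$event)
  }
  out
}
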