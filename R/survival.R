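#' Median split of a continuous marker
#'
#' Dichotomizes patients at the median of a marker (e.g. gene expression):
#' strictly above the median is "high", at or below is "low" (ties go low).
#'
#' @param values numeric vector, length >= 2.
#' @return character vector of "high"/"low" labels, same order.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (anyNA(values)) stop("missing marker values", call. = FALSE)
  med <- stats::median(values)
  if (all(values == values[1])) stop("all values identical: no median split exists", call. = FALSE)
  ifelse(values > med, "high", "low")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` — the survival
#'   step function evaluated at the distinct event/censoring times (censored
#'   times shrink the risk set without a step).
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("length mismatch", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic: at each distinct event
#' time the observed events in group 1 are compared with the hypergeometric
#' expectation given the risk sets, and chi2 = (sum(O - E))^2 / sum(V).
#'
#' @param times,events follow-up data as in [km_estimate()].
#' @param groups two-level group labels (factor/character/binary).
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two non-empty groups required", call. = FALSE)
  if (any(tabulate(g, 2L) == 0L)) stop("one group is empty", call. = FALSE)
  in1 <- g == levels(g)[1]
  ev_times <- sort(unique(times[events == 1]))
  OmE <- 0; V <- 0
  for (tt in ev_times) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(events == 1 & times == tt)
    d1 <- sum(events == 1 & times == tt & in1)
    OmE <- OmE + (d1 - d * n1 / n)
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) OmE^2 / V else 0
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits a single-covariate Cox model by partial likelihood (Efron tie
#' handling) and reports the hazard ratio with its 95% Wald interval and
#' two-sided Wald p-value.
#'
#' @param covariate numeric or binary covariate vector.
#' @param times,events follow-up data.
#' @return list `beta_hat`, `se`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
cox_univariate <- function(covariate, times, events) {
  x <- as.numeric(covariate)
  if (length(unique(x)) < 2L) stop("covariate is constant: no information", call. = FALSE)
  if (length(unique(x)) == 2L) {
    for (lev in unique(x)) {
      if (sum(events[x == lev]) == 0L) {
        stop("a covariate level has no events (monotone likelihood)", call. = FALSE)
      }
    }
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron"),
    warning = function(w) stop("Cox fit did not converge: ", conditionMessage(w), call. = FALSE)
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) {
    stop("Cox fit produced a non-finite estimate (monotone likelihood)", call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  list(beta_hat = beta, se = se, hr = exp(beta),
       ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Chi-squared test of association for a contingency table
#'
#' Pearson chi-squared with df = (r-1)(c-1); the Yates continuity correction
#' is applied automatically to 2x2 tables (and only there), matching the
#' convention of clinical baseline-characteristics tables. A Fisher exact
#' alternative is available for 2x2 tables.
#'
#' @param counts non-negative integer matrix (r x c) with positive total and
#'   no all-zero row or column.
#' @param method `"auto"` (Yates iff 2x2), `"pearson"` (never corrected), or
#'   `"fisher"` (2x2 only).
#' @return list `chi2`, `df`, `p` (for `"fisher"`, `chi2` and `df` are NA).
#' @export
chi_squared_association <- function(counts, method = c("auto", "pearson", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with positive total", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has an all-zero row or column", call. = FALSE)
  }
  if (method == "fisher") {
    if (!all(dim(counts) == c(2L, 2L))) stop("fisher mode is for 2x2 tables", call. = FALSE)
    return(list(chi2 = NA_real_, df = NA_integer_,
                p = stats::fisher.test(counts)$p.value))
  }
  correct <- method == "auto" && all(dim(counts) == c(2L, 2L))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Marker-split survival analysis
#'
#' Convenience wrapper reproducing the usual prognostic-marker workflow:
#' median split of the marker, Kaplan-Meier curves per group, log-rank test
#' and univariate Cox regression on the high-vs-low indicator.
#'
#' @param marker numeric marker per patient.
#' @param times,events follow-up data.
#' @return list `labels`, `km` (list of per-group KM tables), `logrank`,
#'   `cox`.
#' @export
marker_survival <- function(marker, times, events) {
  labels <- median_split(marker)
  km <- lapply(split(seq_along(times), labels), function(idx) {
    km_estimate(times[idx], events[idx])
  })
  list(labels = labels,
       km = km,
       logrank = logrank_test(times, events, labels),
       cox = cox_univariate(as.integer(labels == "high"), times, events))
}
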