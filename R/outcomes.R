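#' Response rates from a clinical table
#'
#' Computes the objective response rate (CR+PR), disease-control rate
#' (CR+PR+SD) and clinical-benefit rate over the evaluable samples (those
#' with a non-missing best response). Printed percentages round to the
#' nearest whole percent, half away from zero, matching how outcome tables
#' display them.
#'
#' @param clin a [ClinicalTable-class] with at least one evaluable sample.
#' @return list: `n_evaluable`, proportions `orr`, `disease_control`,
#'   `clinical_benefit_rate`, and `percent` (named integer vector of the
#'   rounded display percentages).
#' @examples
#' clin <- ClinicalTable(data.frame(
#'   sample_id = paste0("S", 1:35),
#'   best_response = rep(c("CR", "PR", "SD", "PD"), c(1, 12, 6, 16)),
#'   clinical_benefit = rep(c(TRUE, TRUE, FALSE, FALSE), c(13, 2, 4, 16)),
#'   os_months = 1, os_event = TRUE, pfs_months = 1, pfs_event = TRUE))
#' responseRates(clin)$percent
#' @export
responseRates <- function(clin) {
  stopifnot(is(clin, "ClinicalTable"))
  br <- clin$best_response
  ev <- !is.na(br)
  if (!any(ev)) stop("no evaluable sample (all best responses missing)")
  n <- sum(ev)
  orr <- sum(br[ev] %in% c("CR", "PR")) / n
  dc <- sum(br[ev] %in% c("CR", "PR", "SD")) / n
  cb <- sum(clin$clinical_benefit[ev], na.rm = TRUE) / n
  pct <- function(p) floor(100 * p + 0.5)  # half away from zero (p >= 0)
  list(n_evaluable = n, orr = orr, disease_control = dc,
       clinical_benefit_rate = cb,
       percent = c(orr = pct(orr), disease_control = pct(dc),
                   clinical_benefit = pct(cb)))
}

#' Kaplan-Meier product-limit estimator
#'
#' Wraps [survival::survfit()] and returns the step function together with a
#' median defined as the earliest time at which survival drops to 0.5 or
#' below (`NA` = not reached).
#'
#' @param times non-negative event/censoring times.
#' @param events logical (or 0/1) event indicators.
#' @return list: `time`, `surv`, `n_risk`, `n_event` (at the observed event
#'   times), and `median`.
#' @export
kaplanMeier <- function(times, events) {
  if (length(times) != length(events)) stop("length mismatch")
  if (any(times < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- fit$time[fit$surv <= 0.5]
  curve <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                n_event = fit$n.event,
                median = if (length(med)) min(med) else NA_real_)
  class(curve) <- "km_curve"
  curve
}

#' @rdname kaplanMeier
#' @param curve a curve from `kaplanMeier`.
#' @param t time(s) at which to evaluate the right-continuous survival step
#'   function (1 before the first event time).
#' @export
survivalAt <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (length(i)) curve$surv[max(i)] else 1
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points, median",
      if (is.na(x$median)) "not reached" else sprintf("%.3g", x$median), "\n")
  invisible(x)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling via
#' [survival::coxph()]; 95% confidence intervals are
#' `exp(estimate +/- 1.96 SE)`.
#'
#' @param times,events right-censored endpoint.
#' @param covariates numeric vector, matrix or data.frame of covariates; a
#'   constant covariate (no information) is rejected, and non-convergence or
#'   separation raises a structured error.
#' @return data.frame: `term`, `log_hr`, `hr`, `ci_lower`, `ci_upper`,
#'   `se`, `wald_p`.
#' @export
coxPH <- function(times, events, covariates) {
  if (sum(events) < 1) stop("at least one event required")
  X <- as.data.frame(covariates)
  if (ncol(X) == 1L && is.null(colnames(covariates)))
    colnames(X) <- "covariate"
  for (nm in colnames(X)) {
    x <- X[[nm]]
    if (!all(is.finite(as.numeric(x))))
      stop("non-finite covariate: ", nm)
    if (length(unique(x)) < 2L)
      stop("covariate '", nm, "' is constant (no information)")
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, as.integer(events)) ~ .,
                    data = X, ties = "efron"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w)))
  if (any(!is.finite(stats::coef(fit))))
    stop("Cox fit produced non-finite coefficients (separation?)")
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  data.frame(term = names(est), log_hr = unname(est), hr = exp(unname(est)),
             ci_lower = exp(unname(est) - 1.96 * se),
             ci_upper = exp(unname(est) + 1.96 * se),
             se = unname(se),
             wald_p = 2 * stats::pnorm(-abs(unname(est) / se)),
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison via [survival::survdiff()].
#'
#' @param times,events right-censored endpoint.
#' @param group two-level grouping, both groups non-empty.
#' @return list: `chisq` (1 df), `p`.
#' @export
logrankTest <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("exactly two non-empty groups required")
  fit <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  list(chisq = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact p by the probability-mass rule (sum over tables with
#' fixed margins whose probability does not exceed the observed table's), as
#' implemented by [stats::fisher.test()]; the reported odds ratio is the
#' conditional maximum-likelihood estimate (not the sample odds ratio).
#'
#' @param table 2x2 matrix of non-negative integer counts with no all-zero
#'   margin.
#' @return list: `odds_ratio`, `p`.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all-zero margin")
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom, via [stats::kruskal.test()]. When all values are equal the
#' tie-corrected statistic is undefined (0/0); it is reported as 0 here.
#'
#' @param values numeric vector.
#' @param groups grouping with at least two non-empty levels.
#' @return list: `H`, `df`, `p`.
#' @export
kruskalWallisTest <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("at least two groups required")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Multivariable logistic regression for response association
#'
#' Maximum-likelihood logistic fit of a binary response on a molecular call
#' plus adjustment covariates, reporting per-term estimates, standard errors
#' and Wald p values. Complete or quasi-complete separation is detected
#' (non-finite or runaway estimates / fitted probabilities of 0 or 1) and
#' flagged per term rather than silently reported.
#'
#' @param response binary outcome (logical or 0/1), both classes present.
#' @param predictors data.frame of the molecular call and adjustment
#'   covariates.
#' @return data.frame: `term`, `estimate`, `se`, `wald_p`, `separation`.
#' @export
adjustedLogistic <- function(response, predictors) {
  response <- as.integer(as.logical(response))
  if (length(unique(response)) < 2L)
    stop("both response classes must be present")
  df <- data.frame(.response = response, as.data.frame(predictors))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.response ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # diverging estimate with blown-up SE is the fingerprint of separation,
  # whether or not glm managed to emit its boundary warning
  separation <- (abs(est) > 10 & se > 10) | (sep_warned & abs(est) > 10)
  if (any(separation))
    warning("separation detected for term(s): ",
            paste(names(est)[separation], collapse = ", "))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             wald_p = 2 * stats::pnorm(-abs(unname(est) / se)),
             separation = unname(separation),
             stringsAsFactors = FALSE)
}
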