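## Survival analysis of candidate hub genes: median dichotomization of
## expression, Kaplan-Meier product-limit curves, the two-group log-rank
## test, and Cox proportional-hazards fits (Breslow ties, Wald CIs).
## Estimation is delegated to the survival package; this module defines
## the analysis surface and the report shape.

#' Split subjects at the median expression
#'
#' `high` is strictly above the median; values equal to the median go to
#' `low`.
#'
#' @param expression numeric vector, length >= 2.
#' @return character vector of `"high"`/`"low"`.
#' @export
dichotomize_by_median <- function(expression) {
  if (length(expression) < 2) stop_survival("need at least 2 subjects")
  if (length(unique(expression)) == 1)
    stop_survival("all expression values identical; no median split possible")
  ifelse(expression > median(expression), "high", "low")
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; censored
#' observations leave the curve unchanged and only shrink the risk set.
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return data frame (time, n_risk, n_event, survival) at the distinct
#'   event times.
#' @export
km_estimate <- function(times, events) {
  if (any(times <= 0)) stop_survival("times must be positive")
  if (!all(events %in% c(0, 1))) stop_survival("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], survival = fit$surv[keep])
}

#' Two-group log-rank test
#'
#' Standard log-rank: observed-minus-expected event counts over the
#' shared risk sets, chi-square on 1 degree of freedom.
#'
#' @param times,events pooled times and event indicators.
#' @param group two-level group labels aligned to the subjects.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop_survival("log-rank needs exactly two non-empty groups")
  if (sum(events) == 0)
    stop_survival("no events observed; log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq, df = 1, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Breslow tie handling by default (Efron available), Newton-Raphson to
#' tolerance 1e-9, Wald 95% confidence intervals
#' `exp(beta +- 1.96 SE)` from the observed information.
#'
#' @param cohort a `SurvivalCohort` data frame with `time` and `event`.
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` or `"efron"`.
#' @return an object of class `CoxFit`: data frame `coefficients`
#'   (term, beta, hr, se, ci_lower, ci_upper, z, p) plus `loglik`,
#'   `iterations`.
#' @export
cox_fit <- function(cohort, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(cohort$event) < 1) stop_survival("need at least one event")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = cohort, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    error = function(e) stop_survival("Cox fit failed: %s", conditionMessage(e)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop_survival("Cox fit did not converge (possible monotone likelihood): %s",
                      conditionMessage(w))
      suppressWarnings(
        survival::coxph(fml, data = cohort, ties = ties,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 50)))
    })
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)))
    stop_survival("Cox fit produced non-finite coefficients (singular design?)")
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(
    coefficients = data.frame(
      term = names(beta), beta = unname(beta), hr = exp(unname(beta)),
      se = unname(se),
      ci_lower = exp(unname(beta) - 1.96 * unname(se)),
      ci_upper = exp(unname(beta) + 1.96 * unname(se)),
      z = unname(beta / se),
      p = 2 * pnorm(-abs(unname(beta / se))),
      stringsAsFactors = FALSE),
    loglik = fit$loglik[2], iterations = fit$iter
  ), class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat("CoxFit (Breslow partial likelihood)\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Survival report for one gene
#'
#' Median-dichotomizes the gene's expression, then reports the log-rank
#' test, the univariate Cox hazard ratio (high vs low) with its 95%
#' Wald interval, and the Kaplan-Meier curves of both groups. Fully
#' deterministic given the cohort.
#'
#' @param expression numeric expression values aligned to the cohort
#'   rows.
#' @param cohort a `SurvivalCohort` (needs `time`, `event`).
#' @param gene gene label for the report.
#' @return list with `gene`, `hr`, `ci_lower`, `ci_upper`,
#'   `logrank_chisq`, `logrank_p`, `n_high`, `n_low`, `km_high`,
#'   `km_low`.
#' @export
gene_survival_report <- function(expression, cohort, gene = "gene") {
  if (length(expression) != nrow(cohort))
    stop_survival("expression not aligned to cohort (%d vs %d subjects)",
                  length(expression), nrow(cohort))
  grp <- dichotomize_by_median(expression)
  lr <- logrank_test(cohort$time, cohort$event, grp)
  df <- data.frame(time = cohort$time, event = cohort$event,
                   high = as.integer(grp == "high"))
  cf <- cox_fit(df, "high")
  hi <- grp == "high"
  list(gene = gene,
       hr = cf$coefficients$hr[1],
       ci_lower = cf$coefficients$ci_lower[1],
       ci_upper = cf$coefficients$ci_upper[1],
       cox_p = cf$coefficients$p[1],
       logrank_chisq = lr$chisq, logrank_p = lr$p,
       n_high = sum(hi), n_low = sum(!hi),
       km_high = km_estimate(cohort$time[hi], cohort$event[hi]),
       km_low = km_estimate(cohort$time[!hi], cohort$event[!hi]))
}
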