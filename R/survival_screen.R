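## Univariate prognostic screening of signature proteins.
##
## Cox proportional-hazards regression on continuous log2 expression (Efron
## tie handling) and median-split Kaplan-Meier curves with the log-rank
## test, as used to screen the top signature proteins against bladder-cancer
## outcomes.

check_cohort <- function(cohort, gene) {
  need <- c("time", "event")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort))) {
    stopf("cohort must be a data.frame with columns 'time' and 'event'")
  }
  if (!gene %in% names(cohort)) stopf("gene '%s' not in cohort", gene)
  if (any(cohort$time <= 0)) stopf("all follow-up times must be > 0")
  if (anyNA(cohort[[gene]])) stopf("missing expression for gene '%s'", gene)
  if (nrow(cohort) < 2) stopf("need at least 2 patients")
  if (sum(cohort$event) < 1) stopf("cohort has no events")
  invisible(TRUE)
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits `Surv(time, event) ~ expression` for one gene on continuous log2
#' expression with Efron tie handling. The hazard ratio is per unit (i.e.
#' per doubling of expression), with a 95% Wald interval and p-value.
#' Monotone-likelihood non-convergence is reported via `converged`.
#'
#' @param cohort Data.frame with columns `time` (months), `event` (0/1) and
#'   one column per gene of log2 expression.
#' @param gene Gene column to test.
#' @return Data.frame row: `gene`, `hazard_ratio`, `ci_lower`, `ci_upper`,
#'   `p_value`, `beta`, `se`, `converged`.
#' @export
cox_univariate <- function(cohort, gene) {
  check_cohort(cohort, gene)
  d <- data.frame(time = cohort$time, event = cohort$event,
                  x = cohort[[gene]])
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, data = d,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-8)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, data = d,
                        ties = "efron"))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- beta / se
  data.frame(
    gene = gene,
    hazard_ratio = exp(beta),
    ci_lower = exp(beta - stats::qnorm(0.975) * se),
    ci_upper = exp(beta + stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    beta = beta,
    se = se,
    converged = is.null(attr(fit, "flagged")),
    stringsAsFactors = FALSE
  )
}

#' Median-split Kaplan-Meier curves with log-rank test
#'
#' Splits the cohort at the median expression of `gene` (values equal to the
#' median go to the low group), estimates product-limit survival curves per
#' side, and compares them by a two-group log-rank test (1 df).
#'
#' @inheritParams cox_univariate
#' @return List with `fit` (a `survfit` object), `group` (factor low/high
#'   per patient), `chisq`, `p_value`.
#' @export
km_logrank_median_split <- function(cohort, gene) {
  check_cohort(cohort, gene)
  x <- cohort[[gene]]
  med <- stats::median(x)
  grp <- factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
  if (any(table(grp) < 2)) {
    stopf("degenerate median split for gene '%s'", gene)
  }
  d <- data.frame(time = cohort$time, event = cohort$event, group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- lr$chisq
  list(fit = fit, group = grp, chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
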