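## Survival association of fusion burden: group definitions, Kaplan-Meier
## estimation, log-rank test and Cox proportional-hazards regression
## (module surface over the survival package, which is the field's standard
## implementation of these estimators).

#' Grouping specification for survival analyses
#'
#' @param mode `"burden_median"` (dichotomize the per-sample fusion burden
#'   at the cohort median: group 1 means burden >= median) or
#'   `"fusion_status"` (group 1 means the target fusion is detected in the
#'   sample within the confidence scope).
#' @param confidenceScope `"high_only"`, `"combined"` or `"all"`.
#' @param targetFusion canonical key of the target fusion (required for
#'   `"fusion_status"`).
#' @return a validated list of class `"GroupingSpec"`.
#' @export
groupingSpec <- function(mode = c("burden_median", "fusion_status"),
                         confidenceScope = "high_only",
                         targetFusion = NULL) {
  mode <- match.arg(mode)
  if (mode == "fusion_status" && is.null(targetFusion))
    stop("mode 'fusion_status' requires a target fusion key")
  if (mode == "burden_median" && !is.null(targetFusion))
    stop("targetFusion is only meaningful for mode 'fusion_status'")
  structure(
    list(
      mode = mode, confidenceScope = confidenceScope,
      targetFusion = if (!is.null(targetFusion)) .canonicalizeKeyString(targetFusion)
    ),
    class = "GroupingSpec"
  )
}

#' Assign samples to prognostic groups
#'
#' In `burden_median` mode, group 1 contains samples whose burden is greater
#' than or equal to the cohort median. In `fusion_status` mode, group 1
#' contains samples in which the target fusion is detected within the
#' confidence scope of the call set's deduplicated calls.
#'
#' @param burdens result of [perSampleBurden()] (burden_median mode).
#' @param callSet a [FusionCallSet-class] (fusion_status mode).
#' @param spec a [groupingSpec()].
#' @param sampleIds sample universe for fusion_status mode (defaults to the
#'   samples in the call set).
#' @param combinedKeys combined key set when `confidenceScope = "combined"`.
#' @return named integer vector of 0/1 group labels.
#' @export
assignGroups <- function(burdens = NULL, callSet = NULL, spec,
                         sampleIds = NULL, combinedKeys = NULL) {
  stopifnot(inherits(spec, "GroupingSpec"))
  if (spec$mode == "burden_median") {
    if (is.null(burdens)) stop("burden_median mode requires a burden table")
    bt <- burdens$burden
    med <- burdens$median_burden
    groups <- stats::setNames(as.integer(bt$burden >= med), bt$sample_id)
  } else {
    if (is.null(callSet)) stop("fusion_status mode requires a call set")
    calls <- .scopeCalls(analysisCalls(callSet), spec$confidenceScope, combinedKeys)
    carriers <- unique(calls$sample_id[calls$key == spec$targetFusion])
    if (is.null(sampleIds)) sampleIds <- unique(fusionCalls(callSet)$sample_id)
    groups <- stats::setNames(as.integer(sampleIds %in% carriers), sampleIds)
  }
  if (length(unique(groups)) < 2L)
    warning("all samples fall into a single group; downstream tests will refuse to run")
  groups
}

#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator (censored subjects leave the risk set
#' after their time; S(0) = 1) and returns the curve together with a step
#' lookup.
#'
#' @param time event/censoring times (months by convention).
#' @param event 0/1 event indicators.
#' @return list with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` Greenwood), `survivalAt(t)` lookup
#'   function, and the underlying `survfit` object.
#' @export
kmFit <- function(time, event) {
  if (length(time) < 1L) stop("need at least one sample")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  curve <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv, std_err = fit$std.err
  )
  survivalAt <- function(t) {
    vapply(t, function(tt) {
      i <- which(curve$time <= tt)
      if (!length(i)) 1 else curve$surv[max(i)]
    }, numeric(1))
  }
  list(curve = curve, survivalAt = survivalAt, fit = fit)
}

#' Log-rank test
#'
#' Standard log-rank comparison of the survival distributions of two or
#' more groups (chi-square on g-1 degrees of freedom).
#'
#' @param time event/censoring times.
#' @param event 0/1 event indicators.
#' @param group group labels.
#' @return list `chi_square`, `df`, `p`.
#' @export
logRankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank test needs at least two non-empty groups")
  if (sum(event) == 0) {
    warning("zero events; log-rank p set to 1")
    return(list(chi_square = 0, df = nlevels(droplevels(group)) - 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(
    chi_square = unname(sd$chisq), df = df,
    p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  )
}

#' Cox proportional-hazards regression
#'
#' Fits the Cox model by partial likelihood (Breslow ties by default, Efron
#' optionally) and reports, per covariate, the log hazard ratio, its
#' standard error, the 95% Wald confidence interval (beta +/- 1.96 SE) and
#' the Wald p-value.
#'
#' @param time event/censoring times.
#' @param event 0/1 event indicators.
#' @param covariates data.frame of numeric covariates (e.g. dichotomized
#'   burden group and GGG on a continuous scale).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `coefficients` (data.frame `covariate`, `logHR`, `se`,
#'   `ci_low`, `ci_high`, `p`), `converged`, `n`, `n_events`.
#' @export
coxFit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(event) < 2L) stop("need at least two events")
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop(sprintf(
      "covariate(s) constant across samples: %s",
      paste(names(covariates)[const], collapse = ", ")
    ))
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- tryCatch(
    survival::coxph(form, data = dat, ties = ties),
    error = function(e) e, warning = function(w) w
  )
  flagged <- inherits(fit, "condition")
  if (flagged) {
    # refit quietly to inspect; monotone likelihood / singular information
    fit2 <- suppressWarnings(try(
      survival::coxph(form, data = dat, ties = ties), silent = TRUE
    ))
    if (inherits(fit2, "try-error") ||
        any(!is.finite(sqrt(diag(fit2$var)))) ||
        any(abs(stats::coef(fit2)) > 15)) {
      return(list(
        coefficients = NULL, converged = FALSE,
        n = length(time), n_events = sum(event),
        message = conditionMessage(fit)
      ))
    }
    fit <- fit2
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  coefs <- data.frame(
    covariate = names(covariates),
    logHR = unname(beta),
    se = unname(se),
    ci_low = unname(beta - 1.96 * se),
    ci_high = unname(beta + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE
  )
  list(
    coefficients = coefs, converged = TRUE,
    n = length(time), n_events = sum(event)
  )
}
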