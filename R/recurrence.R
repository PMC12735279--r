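#' Two-year recurrence survival analysis
#'
#' Time-to-event runs from anticoagulant discontinuation to confirmed
#' recurrence, administratively censored at 24 months. Within each
#' provoked/unprovoked stratum the high- vs low-PRS groups are compared by
#' Kaplan-Meier curves, the two-group log-rank test and a univariable Cox
#' model with Efron tie handling.
#'
#' @name recurrence
NULL

RECURRENCE_CAP_MONTHS <- 24

#' Truncate follow-up at the administrative cap
#'
#' @param time Months of follow-up (non-negative).
#' @param event 1 recurrence, 0 censored.
#' @param cap Administrative cap in months.
#' @return Data frame `time`, `event` with times clipped to `cap` and events
#'   beyond the cap converted to censorings.
#' @export
truncate_followup <- function(time, event, cap = RECURRENCE_CAP_MONTHS) {
  if (any(time < 0, na.rm = TRUE)) stop("negative follow-up time")
  over <- !is.na(time) & time > cap
  data.frame(time = pmin(time, cap),
             event = ifelse(over, 0L, as.integer(event)))
}

#' Kaplan-Meier estimate with Greenwood confidence bands
#'
#' Product-limit estimator over the distinct event times, with log-scale
#' Greenwood 95% intervals.
#'
#' @param time Months of follow-up.
#' @param event 1 recurrence, 0 censored.
#' @return Data frame: `time`, `n_risk`, `n_event`, `survival`, `ci_low`,
#'   `ci_high` at each distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("no records")
  if (any(time < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, ci_low = fit$lower, ci_high = fit$upper)
}

#' Two-group log-rank test
#'
#' @param time,event Follow-up records.
#' @param group Two-level group label per subject.
#' @return List with `chisq` (1 df statistic) and `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly two non-empty groups")
  if (sum(event) == 0L) stop("log-rank undefined with no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Univariable Cox hazard ratio (Efron ties)
#'
#' @param time,event Follow-up records.
#' @param group Two-level label; the hazard ratio contrasts the second level
#'   against the first.
#' @return List with `hr`, `ci` (Wald 95%), `p_value`, `monotone` (TRUE when
#'   the partial likelihood is monotone — for example all events in one
#'   group — and no finite estimate exists).
#' @export
cox_fit <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("group indicator must vary")
  if (sum(event) == 0L) stop("Cox fit undefined with no events")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "efron"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 1e3) {
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_, monotone = TRUE))
  }
  z <- stats::qnorm(0.975)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * z * se),
       p_value = 2 * stats::pnorm(-abs(beta) / se), monotone = FALSE)
}

#' PRS-stratified recurrence analysis
#'
#' For each provoked/unprovoked stratum with adequate group sizes: KM curves
#' per PRS group, log-rank test and Cox HR (high vs low). Strata with fewer
#' than 2 subjects in either PRS group are skipped with a warning.
#'
#' @param cohort A `vte_cohort` whose cases carry `risk_class`,
#'   `time_months`, `event`.
#' @param prs PRS table from [prs_stage()] (needs `subject_id`, `prs_group`).
#' @param cap Administrative censoring cap in months.
#' @return Named list per stratum, each with `km` (per-group KM tables),
#'   `logrank`, `cox`, `n` per group; plus `summary`, a per-stratum data
#'   frame of the test results.
#' @export
recurrence_analysis <- function(cohort, prs, cap = RECURRENCE_CAP_MONTHS) {
  s <- cohort$subjects
  cases <- s[s$status == "case", , drop = FALSE]
  if (any(is.na(cases$risk_class)) || any(is.na(cases$time_months)))
    stop("all cases must carry risk_class and follow-up for recurrence analysis")
  cases$prs_group <- prs$prs_group[match(cases$subject_id, prs$subject_id)]
  if (any(is.na(cases$prs_group))) stop("PRS group missing for some cases")
  out <- list()
  rows <- list()
  for (stratum in c("provoked", "unprovoked")) {
    cs <- cases[cases$risk_class == stratum, , drop = FALSE]
    if (nrow(cs) == 0L) next
    tally <- table(factor(cs$prs_group, levels = c("low", "high")))
    if (any(tally < 2L)) {
      warning("stratum '", stratum, "' skipped: PRS group with < 2 subjects")
      next
    }
    fu <- truncate_followup(cs$time_months, cs$event, cap)
    km <- lapply(split(fu, cs$prs_group), function(g)
      km_estimate(g$time, g$event))
    lr <- tryCatch(logrank_test(fu$time, fu$event, cs$prs_group),
                   error = function(e) list(chisq = NA_real_,
                                            p_value = NA_real_))
    grp <- factor(cs$prs_group, levels = c("low", "high"))
    cx <- tryCatch(cox_fit(fu$time, fu$event, grp),
                   error = function(e) list(hr = NA_real_,
                                            ci = c(NA_real_, NA_real_),
                                            p_value = NA_real_,
                                            monotone = NA))
    out[[stratum]] <- list(km = km, logrank = lr, cox = cx,
                           n = as.integer(tally))
    rows[[stratum]] <- data.frame(
      stratum = stratum, n_low = tally[["low"]], n_high = tally[["high"]],
      events = sum(fu$event), logrank_chisq = lr$chisq,
      logrank_p = lr$p_value, hr_high_vs_low = cx$hr,
      hr_ci_low = cx$ci[1], hr_ci_high = cx$ci[2], hr_p = cx$p_value,
      stringsAsFactors = FALSE)
  }
  out$summary <- if (length(rows) > 0L) {
    sm <- do.call(rbind, rows); rownames(sm) <- NULL; sm
  } else {
    data.frame()
  }
  out
}
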