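#' Case-control association statistics
#'
#' Per-variant machinery for the panel scan: allele frequencies, 2x2 tables
#' in allele or subject units, cross-product odds ratios with Woolf
#' (log-scale normal) or exact conditional confidence intervals, chi-square /
#' Fisher test selection on expected counts, dominant/recessive genotype
#' collapse, and covariate-adjusted logistic regression estimates.
#'
#' @name association
NULL

#' Construct a 2x2 exposure table
#'
#' Cells follow the epidemiological layout: `a` case-exposed, `b`
#' case-unexposed, `c` control-exposed, `d` control-unexposed. A table with a
#' zero margin is flagged degenerate rather than rejected.
#'
#' @param a,b,c,d Non-negative counts.
#' @param unit `"allele"` or `"subject"`.
#' @return A list of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, unit = c("allele", "subject")) {
  unit <- match.arg(unit)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(is.na(cells))) stop("cell counts must be non-negative")
  degenerate <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  structure(list(a = a, b = b, c = c, d = d, unit = unit,
                 degenerate = degenerate),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two unit=%s%s>\n", x$unit,
              if (x$degenerate) ", degenerate" else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Effect-allele frequency from dosages
#' @param dosages Per-subject effect-allele dosages (0/1/2, NA allowed).
#' @return Allele frequency among non-missing subjects.
#' @export
effect_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("all dosages missing")
  sum(d) / (2 * length(d))
}

#' Allele-count 2x2 table for a variant
#' @param case_dosages,control_dosages Per-subject dosages (NA dropped).
#' @return `two_by_two` in allele units.
#' @export
allelic_table <- function(case_dosages, control_dosages) {
  ca <- case_dosages[!is.na(case_dosages)]
  co <- control_dosages[!is.na(control_dosages)]
  two_by_two(sum(ca), 2 * length(ca) - sum(ca),
             sum(co), 2 * length(co) - sum(co), unit = "allele")
}

#' Cross-product odds ratio
#'
#' `ad/(bc)`. With a single zero cell the estimate is reported as `Inf`
#' (zero in `b` or `c`) or `0` (zero in `a` or `d`); with two or more zero
#' cells the OR is undefined and an error is raised.
#'
#' @param table A `two_by_two`.
#' @return Positive real, `0`, or `Inf`.
#' @export
odds_ratio <- function(table) {
  cells <- c(table$a, table$b, table$c, table$d)
  nz <- sum(cells == 0)
  if (nz >= 2) stop("odds ratio undefined: two or more zero cells")
  if (table$b == 0 || table$c == 0) return(Inf)
  table$a * table$d / (table$b * table$c)
}

#' Odds ratio from a frequency pair
#'
#' `[p1/(1-p1)] / [p0/(1-p0)]` — the allelic OR written in terms of the
#' case and control effect-allele frequencies.
#'
#' @param p1,p0 Case and control frequencies in (0, 1).
#' @return Odds ratio.
#' @export
or_from_eaf <- function(p1, p0) {
  if (any(c(p1, p0) <= 0) || any(c(p1, p0) >= 1))
    stop("frequencies must lie strictly between 0 and 1")
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-scale normal interval `exp(log OR +/- z * sqrt(1/a+1/b+1/c+1/d))`.
#' Requires all cells positive; tables with zero cells should use
#' [exact_ci()].
#'
#' @param table A `two_by_two` with all cells positive.
#' @param level Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
woolf_ci <- function(table, level = 0.95) {
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0))
    stop("Woolf CI requires all cells positive; use exact_ci()")
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log(odds_ratio(table))
  se <- sqrt(sum(1 / cells))
  exp(lor + c(-1, 1) * z * se)
}

# log unnormalized noncentral hypergeometric weights over the support of
# cell a, for conditional odds psi (log scale)
cond_log_weights <- function(support, r1, r2, c1, log_psi) {
  lchoose(r1, support) + lchoose(r2, c1 - support) + support * log_psi
}

cond_tail <- function(a, r1, r2, c1, log_psi, upper) {
  support <- seq.int(max(0L, c1 - r2), min(c1, r1))
  lw <- cond_log_weights(support, r1, r2, c1, log_psi)
  lw <- lw - max(lw)
  w <- exp(lw)
  sel <- if (upper) support >= a else support <= a
  sum(w[sel]) / sum(w)
}

#' Exact conditional confidence interval for an odds ratio
#'
#' Fisher-type interval obtained by inverting the one-sided tail
#' probabilities of the noncentral hypergeometric distribution of the
#' case-exposed cell, conditioning on both margins. A zero cell yields an
#' appropriately one-sided interval (finite bound plus 0 or `Inf`); a table
#' with no exposure information yields `(0, Inf)`.
#'
#' @param table A `two_by_two`.
#' @param level Confidence level.
#' @return Numeric `c(low, high)`; bounds may be `0` or `Inf`.
#' @export
exact_ci <- function(table, level = 0.95) {
  a <- table$a; r1 <- table$a + table$b; r2 <- table$c + table$d
  c1 <- table$a + table$c
  alpha <- (1 - level) / 2
  lo_sup <- max(0, c1 - r2); hi_sup <- min(c1, r1)
  if (lo_sup == hi_sup) return(c(0, Inf))   # margins determine the table
  solve_log_psi <- function(target_fun) {
    f <- function(lp) target_fun(lp) - alpha
    lo <- -50; hi <- 50
    if (f(lo) * f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  lower <- if (a == lo_sup) 0 else {
    lp <- solve_log_psi(function(lp) cond_tail(a, r1, r2, c1, lp, upper = TRUE))
    exp(lp)
  }
  upper <- if (a == hi_sup) Inf else {
    lp <- solve_log_psi(function(lp) cond_tail(a, r1, r2, c1, lp, upper = FALSE))
    exp(lp)
  }
  c(lower, upper)
}

#' Case-control association test with expected-count selection
#'
#' Pearson chi-square without continuity correction when every expected cell
#' count is at least 5, otherwise the two-sided Fisher exact test
#' (point-probability method). The rule the study states, with the
#' conventional cutoff of 5.
#'
#' @param table A `two_by_two`.
#' @return List with `p_value`, `test_used` (`"chi_square"`/`"fisher"`) and
#'   `statistic` (chi-square statistic or NA).
#' @export
association_test <- function(table) {
  m <- matrix(c(table$a, table$b, table$c, table$d), 2, byrow = TRUE)
  if (table$degenerate)
    return(list(p_value = 1, test_used = "degenerate", statistic = NA_real_))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(p_value = unname(ht$p.value), test_used = "chi_square",
         statistic = unname(ht$statistic))
  } else {
    ht <- stats::fisher.test(m)
    list(p_value = unname(ht$p.value), test_used = "fisher",
         statistic = NA_real_)
  }
}

#' Collapse genotype counts under a dominant or recessive model
#'
#' Dominant: carriers of at least one effect allele are exposed. Recessive:
#' only homozygous-effect subjects are exposed.
#'
#' @param case_counts,control_counts Length-3 vectors `(n00, n01, n02)` of
#'   subjects with 0, 1, 2 effect alleles.
#' @param model `"dominant"` or `"recessive"`.
#' @return `two_by_two` in subject units.
#' @export
genetic_model_collapse <- function(case_counts, control_counts,
                                   model = c("dominant", "recessive")) {
  model <- match.arg(model)
  stopifnot(length(case_counts) == 3L, length(control_counts) == 3L,
            all(case_counts >= 0), all(control_counts >= 0))
  expo <- function(n) if (model == "dominant") n[2] + n[3] else n[3]
  unex <- function(n) sum(n) - expo(n)
  two_by_two(expo(case_counts), unex(case_counts),
             expo(control_counts), unex(control_counts), unit = "subject")
}

genotype_counts <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

code_dosage <- function(dosage, coding) {
  switch(coding,
         additive  = as.numeric(dosage),
         dominant  = as.numeric(dosage >= 1),
         recessive = as.numeric(dosage == 2),
         stop("unknown genotype coding: ", coding))
}

#' Covariate-adjusted odds ratio by logistic regression
#'
#' Maximum-likelihood logistic fit of case status on the coded genotype and
#' the requested covariates (age and BMI continuous, sex as a male indicator).
#' Convergence by relative log-likelihood change < 1e-8 within 100
#' iterations. Complete separation is flagged and returns no estimate; a
#' collinear design is an error naming the offending columns.
#'
#' @param cohort A `vte_cohort`.
#' @param rsid Variant to model.
#' @param covariates Subset of `c("age", "sex", "bmi")` (possibly empty).
#' @param coding Genotype coding: `"additive"`, `"dominant"`, `"recessive"`.
#' @return List with `adjusted_or`, `adjusted_ci` (Wald 95%), `adjusted_p`,
#'   `converged`, `separation`.
#' @export
logistic_adjusted_or <- function(cohort, rsid,
                                 covariates = c("age", "sex", "bmi"),
                                 coding = c("additive", "dominant",
                                            "recessive")) {
  coding <- match.arg(coding)
  if (!rsid %in% rownames(cohort$genotypes))
    stop("rsid not in cohort genotypes: ", rsid)
  s <- cohort$subjects
  df <- data.frame(
    y = as.integer(s$status == "case"),
    g = code_dosage(cohort$genotypes[rsid, s$subject_id], coding))
  for (cv in covariates) {
    df[[cv]] <- switch(cv,
                       age = as.numeric(s$age),
                       bmi = as.numeric(s$bmi),
                       sex = as.integer(s$sex == "male"),
                       stop("unknown covariate: ", cv))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2L) stop("outcome must include both classes")
  x <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(x))]]
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  beta <- co["g", "Estimate"]; se <- co["g", "Std. Error"]
  eps <- 1e-8
  separated <- !fit$converged ||
    (any(fit$fitted.values > 1 - eps) && any(fit$fitted.values < eps) &&
       abs(beta) > 10)
  if (separated)
    return(list(adjusted_or = NA_real_, adjusted_ci = c(NA_real_, NA_real_),
                adjusted_p = NA_real_, converged = fit$converged,
                separation = TRUE))
  z <- stats::qnorm(0.975)
  list(adjusted_or = exp(beta),
       adjusted_ci = exp(beta + c(-1, 1) * z * se),
       adjusted_p = co["g", "Pr(>|z|)"],
       converged = fit$converged, separation = FALSE)
}

#' Scan the panel for case-control association
#'
#' One result row per variant per model. Allelic rows use allele-count 2x2
#' tables; dominant/recessive rows use subject-count collapse. Degenerate
#' (for example monomorphic) variants are retained with flags, never dropped.
#' Covariate-adjusted logistic estimates are added for variants whose
#' unadjusted p-value is below `adjust_when_p_below` (set to 1 to adjust
#' everything, 0 to disable).
#'
#' @param cohort A `vte_cohort` (typically after [apply_qc()]).
#' @param models Subset of `c("allelic", "dominant", "recessive")`.
#' @param covariates Covariates for the adjusted model.
#' @param adjust_when_p_below Unadjusted-p threshold gating adjustment.
#' @param ci_level Confidence level for interval estimates.
#' @return Data frame with one row per variant x model.
#' @export
association_scan <- function(cohort,
                             models = c("allelic", "dominant", "recessive"),
                             covariates = c("age", "sex", "bmi"),
                             adjust_when_p_below = 0.05,
                             ci_level = 0.95) {
  models <- match.arg(models, several.ok = TRUE)
  ca_ids <- case_ids(cohort); co_ids <- control_ids(cohort)
  rows <- list()
  for (rs in rownames(cohort$genotypes)) {
    dca <- cohort$genotypes[rs, ca_ids]
    dco <- cohort$genotypes[rs, co_ids]
    for (model in models) {
      tab <- if (model == "allelic") allelic_table(dca, dco)
             else genetic_model_collapse(genotype_counts(dca),
                                         genotype_counts(dco), model)
      res <- summarize_table(tab, ci_level)
      test <- association_test(tab)
      row <- data.frame(
        rsid = rs, model = model,
        eaf_case = effect_allele_frequency(dca),
        eaf_control = effect_allele_frequency(dco),
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        or_estimate = res$or, ci_low = res$ci[1], ci_high = res$ci[2],
        ci_method = res$method,
        p_value = test$p_value, test_used = test$test_used,
        degenerate = tab$degenerate,
        adjusted_or = NA_real_, adjusted_ci_low = NA_real_,
        adjusted_ci_high = NA_real_, adjusted_p = NA_real_,
        stringsAsFactors = FALSE)
      if (!tab$degenerate && !is.na(test$p_value) &&
          test$p_value < adjust_when_p_below) {
        coding <- switch(model, allelic = "additive", model)
        adj <- tryCatch(
          logistic_adjusted_or(cohort, rs, covariates, coding),
          error = function(e) NULL)
        if (!is.null(adj) && !adj$separation) {
          row$adjusted_or <- adj$adjusted_or
          row$adjusted_ci_low <- adj$adjusted_ci[1]
          row$adjusted_ci_high <- adj$adjusted_ci[2]
          row$adjusted_p <- adj$adjusted_p
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# OR + CI for one table, routing zero-cell tables to the exact interval
summarize_table <- function(tab, ci_level = 0.95) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (tab$degenerate || sum(cells == 0) >= 2) {
    return(list(or = NA_real_, ci = exact_ci(tab, ci_level),
                method = "exact"))
  }
  or <- odds_ratio(tab)
  if (any(cells == 0)) list(or = or, ci = exact_ci(tab, ci_level),
                            method = "exact")
  else list(or = or, ci = woolf_ci(tab, ci_level), method = "woolf")
}
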