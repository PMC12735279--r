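#' Retrospective power for case-control association
#'
#' Power of the two-sided level-alpha comparison of exposure proportions
#' between cases and controls, for the allelic (log-additive, two alleles per
#' subject) test or for dominant/recessive subject-level exposure under
#' Hardy-Weinberg genotype proportions. The default method enumerates the two
#' independent binomial exposure counts exactly and pushes every attainable
#' table through the same chi-square/Fisher selection rule as
#' [association_test()]; a closed-form normal approximation (pooled-variance
#' null, unpooled alternative) is available for large designs.
#'
#' @name power
NULL

# alternative-group exposure probability implied by an odds ratio
or_to_p <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

exposure_prob <- function(eaf, model) {
  switch(model,
         allelic   = eaf,
         dominant  = 1 - (1 - eaf)^2,
         recessive = eaf^2,
         stop("unknown model: ", model))
}

# two-sided Fisher p by the point-probability method, vectorizable per table
fisher_p_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  support <- seq.int(max(0L, c1 - (c + d)), min(c1, r1))
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Power of the case-control exposure test
#'
#' @param n_case,n_control Subject counts per group.
#' @param eaf Control effect-allele frequency, strictly in (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio (> 0) on the exposure
#'   scale of `model`.
#' @param alpha Two-sided significance level.
#' @param model `"allelic"` (allele-count units), `"dominant"` or
#'   `"recessive"` (subject units, HWE exposure frequencies).
#' @param method `"exact"` (binomial enumeration through the test-selection
#'   rule), `"approx"` (normal approximation with pooled null variance), or
#'   `"auto"` (default: exact whenever the enumeration grid stays small, as
#'   it does at this study's sample sizes; approx otherwise).
#' @return Rejection probability in [0, 1].
#' @examples
#' power_of(122, 87, eaf = 0.36, or_alt = 1.94)
#' @export
power_of <- function(n_case, n_control, eaf, or_alt, alpha = 0.05,
                     model = c("allelic", "dominant", "recessive"),
                     method = c("auto", "exact", "approx")) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(n_case >= 1, n_control >= 1, or_alt > 0)
  if (!(eaf > 0 && eaf < 1)) stop("eaf must lie strictly between 0 and 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  p0 <- exposure_prob(eaf, model)
  p1 <- or_to_p(p0, or_alt)
  mult <- if (model == "allelic") 2L else 1L
  n1 <- mult * n_case; n0 <- mult * n_control
  if (method == "auto")
    method <- if ((n1 + 1) * (n0 + 1) <= 2e6) "exact" else "approx"
  if (method == "approx") {
    power_approx(n1, n0, p1, p0, alpha)
  } else {
    power_enumerate(n1, n0, p1, p0, alpha)
  }
}

power_approx <- function(n1, n0, p1, p0, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  delta <- abs(p1 - p0)
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  stats::pnorm((delta - z * se0) / se1) + stats::pnorm((-delta - z * se0) / se1)
}

# exact power by summing binomial probabilities over the rejection region of
# the chi-square/Fisher-selected test applied to every attainable table
power_enumerate <- function(n1, n0, p1, p0, alpha) {
  x1 <- 0:n1; x0 <- 0:n0
  w1 <- stats::dbinom(x1, n1, p1); w0 <- stats::dbinom(x0, n0, p0)
  A <- matrix(x1, n1 + 1L, n0 + 1L)
  C <- matrix(x0, n1 + 1L, n0 + 1L, byrow = TRUE)
  B <- n1 - A; D <- n0 - C
  n <- n1 + n0
  c1 <- A + C; c2 <- B + D
  degenerate <- c1 == 0L | c2 == 0L
  expected_min <- pmin(c1 * n1, c1 * n0, c2 * n1, c2 * n0) / n
  use_chisq <- !degenerate & expected_min >= 5
  stat <- n * (A * D - B * C)^2 / (as.numeric(n1) * n0 * c1 * c2)
  reject <- matrix(FALSE, n1 + 1L, n0 + 1L)
  crit <- stats::qchisq(1 - alpha, df = 1)
  reject[use_chisq] <- stat[use_chisq] > crit
  fisher_idx <- which(!degenerate & !use_chisq)
  if (length(fisher_idx) > 0L) {
    pf <- vapply(fisher_idx, function(k) {
      fisher_p_2x2(A[k], B[k], C[k], D[k])
    }, numeric(1))
    reject[fisher_idx] <- pf < alpha
  }
  W <- outer(w1, w0)
  sum(W[reject])
}

#' Smallest detectable odds ratio at a target power
#'
#' Bisection (to 1e-4 on the OR scale) for the smallest OR > 1 whose power
#' reaches `target_power`.
#'
#' @inheritParams power_of
#' @param target_power Required power, in (alpha, 1).
#' @return Odds ratio > 1.
#' @export
detectable_or <- function(n_case, n_control, eaf, alpha = 0.05,
                          target_power = 0.80,
                          model = c("allelic", "dominant", "recessive"),
                          method = c("auto", "exact", "approx")) {
  model <- match.arg(model); method <- match.arg(method)
  if (!(target_power > alpha && target_power < 1))
    stop("target_power must lie in (alpha, 1)")
  f <- function(or) power_of(n_case, n_control, eaf, or, alpha,
                             model = model, method = method) - target_power
  hi <- 2
  while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
  if (f(hi) < 0) stop("target power unattainable below OR = 1e4")
  lo <- 1 + 1e-6
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}

#' Power grid over EAFs and odds ratios
#'
#' @inheritParams power_of
#' @param eafs,ors Numeric vectors spanning the grid.
#' @return Data frame with one row per (eaf, or) cell, including the
#'   detectable OR at 80% power for each EAF.
#' @export
power_grid <- function(n_case, n_control, eafs, ors, alpha = 0.05,
                       model = "allelic", method = "auto") {
  grid <- expand.grid(eaf = eafs, or_alt = ors, KEEP.OUT.ATTRS = FALSE)
  grid$power <- mapply(function(e, o)
    power_of(n_case, n_control, e, o, alpha, model = model, method = method),
    grid$eaf, grid$or_alt)
  det <- vapply(eafs, function(e)
    detectable_or(n_case, n_control, e, alpha, model = model, method = method),
    numeric(1))
  grid$detectable_or_80 <- det[match(grid$eaf, eafs)]
  grid
}
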