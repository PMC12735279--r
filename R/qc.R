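#' Genotyping quality control
#'
#' Per-variant QC mirrors the panel's validation criteria: a call-rate filter
#' (pass when strictly greater than the minimum, default 95%) and an exact
#' Hardy-Weinberg equilibrium test computed in controls only (fail when
#' p <= alpha). Replicate concordance supports inter-assay reproducibility
#' checks.
#'
#' @name qc
NULL

#' Per-variant call rate
#' @param genotypes rsID x subject dosage matrix.
#' @return Named numeric vector: non-missing fraction per variant.
#' @export
call_rate <- function(genotypes) {
  if (length(genotypes) == 0L) stop("empty genotype matrix")
  rowMeans(!is.na(genotypes))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test given the allele counts: the p-value is the sum of
#' the probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. The conditional distribution
#' of the heterozygote count h given n subjects and n_eff effect alleles is
#' proportional to 2^h * n! / ((n_eff-h)/2)! h! ((n_oth-h)/2)!.
#'
#' @param n_hom_ref Homozygous-reference subject count.
#' @param n_het Heterozygous subject count.
#' @param n_hom_eff Homozygous-effect subject count.
#' @return Two-sided exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_eff) {
  counts <- c(n_hom_ref, n_het, n_hom_eff)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero")
  n_eff <- 2L * n_hom_eff + n_het    # effect-allele copies
  n_oth <- 2L * n_hom_ref + n_het
  hs <- hwe_het_support(n_eff, n_oth)
  logp <- hwe_log_prob(hs, n, n_eff, n_oth)
  logp <- logp - max(logp)
  probs <- exp(logp) / sum(exp(logp))
  obs <- probs[match(n_het, hs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# attainable heterozygote counts for fixed allele totals (parity constraint)
hwe_het_support <- function(n_eff, n_oth) {
  hmax <- min(n_eff, n_oth)
  seq.int(hmax %% 2L, hmax, by = 2L)
}

hwe_log_prob <- function(h, n, n_eff, n_oth) {
  h * log(2) + lgamma(n + 1) -
    lgamma((n_eff - h) / 2 + 1) - lgamma(h + 1) - lgamma((n_oth - h) / 2 + 1)
}

#' Concordance between two genotyping runs
#'
#' Fraction of cells, non-missing in both runs, with identical dosage.
#'
#' @param run_a,run_b rsID x subject dosage matrices with identical dimnames.
#' @return Concordant fraction in [0, 1].
#' @export
replicate_concordance <- function(run_a, run_b) {
  if (!identical(dim(run_a), dim(run_b)) ||
      !identical(dimnames(run_a), dimnames(run_b)))
    stop("replicate runs must share rsIDs and subject ids")
  both <- !is.na(run_a) & !is.na(run_b)
  if (!any(both)) stop("no cells non-missing in both runs")
  sum(run_a[both] == run_b[both]) / sum(both)
}

#' Apply per-variant QC filters to a cohort
#'
#' Drops variants whose call rate is not strictly greater than
#' `call_rate_min` or whose control-only HWE exact p-value is <= `hwe_alpha`
#' (set `hwe_alpha = 0` to disable the HWE filter). Monomorphic control sites
#' have a single attainable configuration and so always pass HWE (p = 1).
#'
#' @param cohort A `vte_cohort`.
#' @param call_rate_min Minimum call rate; pass requires rate > this value.
#' @param hwe_alpha HWE significance level; p <= alpha fails.
#' @return List with `cohort` (filtered) and `report` (per-variant data frame
#'   with call rate, HWE p, flags and kept status; thresholds as attributes).
#' @export
apply_qc <- function(cohort, call_rate_min = 0.95, hwe_alpha = 0.05) {
  ctrl <- cohort$genotypes[, control_ids(cohort), drop = FALSE]
  if (ncol(ctrl) == 0L && hwe_alpha > 0)
    stop("cohort has no controls for the HWE stage")
  cr <- call_rate(cohort$genotypes)
  hwe_p <- vapply(rownames(ctrl), function(rs) {
    d <- ctrl[rs, ]
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NA_real_)
    hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  }, numeric(1))
  low_cr <- !(cr > call_rate_min)
  hwe_fail <- if (hwe_alpha > 0) !is.na(hwe_p) & hwe_p <= hwe_alpha
              else rep(FALSE, length(cr))
  keep <- !low_cr & !hwe_fail
  report <- data.frame(
    rsid = rownames(cohort$genotypes),
    call_rate = as.numeric(cr),
    hwe_p_controls = as.numeric(hwe_p),
    flag_low_call_rate = low_cr,
    flag_hwe_fail = hwe_fail,
    kept = keep,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "call_rate_min") <- call_rate_min
  attr(report, "hwe_alpha") <- hwe_alpha
  if (!any(keep)) warning("all variants removed by QC")
  filtered <- cohort
  filtered$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  filtered$panel <- new_panel(cohort$panel[cohort$panel$rsid %in%
                                             rownames(filtered$genotypes), ],
                              name = attr(cohort$panel, "panel_name"),
                              genome_build = attr(cohort$panel, "genome_build"))
  list(cohort = filtered, report = report)
}
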