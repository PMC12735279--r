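#' Polygenic risk score
#'
#' The score is the weighted sum of effect-allele dosages,
#' `PRS = sum_i beta_i * dosage_i`, with `beta_i = log(OR_i)` taken from the
#' panel's literature ORs by default or from in-cohort allelic estimates.
#' Scores are standardized against the control distribution
#' (`z = (raw - mean_controls) / sd_controls`) and subjects are stratified by
#' a median split or by configurable z bins.
#'
#' @name prs
NULL

#' Build the per-variant weight set
#'
#' @param panel A `vte_panel`.
#' @param source `"literature"` (default) or `"cohort"`.
#' @param cohort_scan Output of [association_scan()] (allelic rows) supplying
#'   in-cohort ORs when `source = "cohort"`. Variants whose in-cohort OR is
#'   undefined (zero cells, monomorphic) fall back to the literature OR and
#'   are flagged.
#' @return Data frame with `rsid`, `beta`, `source` per variant.
#' @export
prs_weights <- function(panel, source = c("literature", "cohort"),
                        cohort_scan = NULL) {
  source <- match.arg(source)
  beta <- vapply(seq_len(nrow(panel)), function(i)
    weight_of(panel[i, , drop = FALSE]), numeric(1))
  used <- rep("literature", nrow(panel))
  if (source == "cohort") {
    if (is.null(cohort_scan)) stop("source = \"cohort\" requires cohort_scan")
    sc <- cohort_scan[cohort_scan$model == "allelic", ]
    idx <- match(panel$rsid, sc$rsid)
    or <- sc$or_estimate[idx]
    usable <- !is.na(or) & is.finite(or) & or > 0
    beta[usable] <- log(or[usable])
    used[usable] <- "cohort"
  }
  data.frame(rsid = panel$rsid, beta = beta, source = used,
             stringsAsFactors = FALSE)
}

#' Raw polygenic risk score per subject
#'
#' @param genotypes rsID x subject dosage matrix.
#' @param weights Data frame with `rsid` and `beta` covering every genotyped
#'   variant.
#' @param missing_policy How to handle missing dosages: substitute the mean
#'   control dosage of the variant (`"mean_dosage_controls"`, default, keeps
#'   scores comparable across subjects) or treat them as zero (`"zero"`).
#' @param control_ids Subject ids defining the control reference for the
#'   mean-dosage policy (required for that policy).
#' @return Data frame with `subject_id`, `raw_prs` and `n_missing` (dosages
#'   imputed or zeroed per subject).
#' @export
compute_prs <- function(genotypes, weights,
                        missing_policy = c("mean_dosage_controls", "zero"),
                        control_ids = NULL) {
  missing_policy <- match.arg(missing_policy)
  absent <- setdiff(rownames(genotypes), weights$rsid)
  if (length(absent) > 0L)
    stop("no weight for genotyped variant(s): ", paste(absent, collapse = ", "))
  beta <- weights$beta[match(rownames(genotypes), weights$rsid)]
  if (any(!is.finite(beta))) stop("all weights must be finite")
  filled <- genotypes
  n_missing <- colSums(is.na(genotypes))
  if (any(is.na(genotypes))) {
    if (missing_policy == "zero") {
      filled[is.na(filled)] <- 0L
    } else {
      if (is.null(control_ids))
        stop("mean_dosage_controls policy requires control_ids")
      ctrl <- genotypes[, intersect(control_ids, colnames(genotypes)),
                        drop = FALSE]
      mu <- rowMeans(ctrl, na.rm = TRUE)
      mu[is.nan(mu)] <- 0
      idx <- which(is.na(filled), arr.ind = TRUE)
      filled[idx] <- mu[idx[, 1]]
    }
  }
  data.frame(subject_id = colnames(genotypes),
             raw_prs = as.numeric(crossprod(filled, beta)),
             n_missing = as.integer(n_missing),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardize raw scores against the control distribution
#'
#' @param raw Data frame from [compute_prs()] (or any frame with
#'   `subject_id`, `raw_prs`).
#' @param control_ids Ids of the reference controls (>= 2, non-degenerate).
#' @return Data frame with an added `z_prs` column; the control mean and SD
#'   are stored as attributes `control_mean`, `control_sd`.
#' @export
standardize_prs <- function(raw, control_ids) {
  ref <- raw$raw_prs[raw$subject_id %in% control_ids]
  if (length(ref) < 2L) stop("need at least 2 control scores to standardize")
  mu <- mean(ref); sd_ <- stats::sd(ref)
  if (!is.finite(sd_) || sd_ == 0) stop("control PRS standard deviation is zero")
  out <- raw
  out$z_prs <- (raw$raw_prs - mu) / sd_
  attr(out, "control_mean") <- mu
  attr(out, "control_sd") <- sd_
  out
}

#' Median split into low/high PRS groups
#'
#' Scores strictly above the reference median are `"high"`; ties at the
#' median go to `"low"` so the high group strictly exceeds the median.
#'
#' @param scores Named or plain numeric vector of standardized scores for the
#'   subjects to label.
#' @param reference Scores over which the median is computed (default: the
#'   scores themselves — the study splits patients at the patient-cohort
#'   median).
#' @return Character vector `"low"`/`"high"` aligned with `scores`.
#' @export
median_split <- function(scores, reference = scores) {
  if (length(scores) < 2L) stop("need at least 2 subjects to split")
  med <- stats::median(reference)
  labels <- ifelse(scores > med, "high", "low")
  if (all(labels == "low"))
    warning("degenerate split: no score exceeds the reference median")
  labels
}

#' Odds ratio of case status by PRS bin
#'
#' Bins standardized scores at `bin_edges` (left-open, right-closed; outer
#' bins unbounded) and contrasts each bin against the reference bin with a
#' cross-product OR (Woolf CI, exact CI on zero cells).
#'
#' @param z Standardized scores per subject.
#' @param status `"case"`/`"control"` per subject.
#' @param bin_edges Ordered interior edges; default: quartiles of the control
#'   scores.
#' @param reference_bin Index of the reference bin (default 1, the lowest).
#' @param ci_level Confidence level.
#' @return Data frame with per-bin counts, OR vs reference and CI.
#' @export
or_by_prs_bin <- function(z, status, bin_edges = NULL, reference_bin = 1L,
                          ci_level = 0.95) {
  stopifnot(length(z) == length(status))
  if (is.null(bin_edges))
    bin_edges <- unname(stats::quantile(z[status == "control"],
                                        c(0.25, 0.5, 0.75)))
  bin_edges <- sort(unique(bin_edges))
  if (length(bin_edges) < 1L) stop("need at least one bin edge (two bins)")
  breaks <- c(-Inf, bin_edges, Inf)
  bins <- cut(z, breaks = breaks, include.lowest = TRUE)
  n_bins <- nlevels(bins)
  if (reference_bin < 1L || reference_bin > n_bins)
    stop("reference_bin out of range")
  ref_case <- sum(status == "case" & as.integer(bins) == reference_bin)
  ref_ctrl <- sum(status == "control" & as.integer(bins) == reference_bin)
  if (ref_case + ref_ctrl == 0L) stop("reference bin is empty")
  if (ref_case == 0L || ref_ctrl == 0L)
    stop("reference bin must contain both cases and controls")
  if (ref_case + ref_ctrl == length(z))
    stop("no contrast: every subject falls in the reference bin")
  out <- lapply(seq_len(n_bins), function(b) {
    n_case <- sum(status == "case" & as.integer(bins) == b)
    n_ctrl <- sum(status == "control" & as.integer(bins) == b)
    if (b == reference_bin) {
      return(data.frame(bin = levels(bins)[b], n_case = n_case,
                        n_control = n_ctrl, or_estimate = 1,
                        ci_low = NA_real_, ci_high = NA_real_,
                        reference = TRUE, stringsAsFactors = FALSE))
    }
    tab <- two_by_two(n_case, ref_case, n_ctrl, ref_ctrl, unit = "subject")
    res <- summarize_table(tab, ci_level)
    data.frame(bin = levels(bins)[b], n_case = n_case, n_control = n_ctrl,
               or_estimate = res$or, ci_low = res$ci[1], ci_high = res$ci[2],
               reference = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full PRS stage for a cohort
#'
#' Computes raw scores, standardizes against the cohort's controls, and
#' labels cases low/high at the configured median reference.
#'
#' @param cohort A `vte_cohort`.
#' @param weights Weight set from [prs_weights()] (default: literature
#'   weights of the cohort's panel).
#' @param missing_policy See [compute_prs()].
#' @param split_reference `"cases"` (default: the patient-cohort median, as
#'   in the recurrence analysis) or `"all"`.
#' @return Data frame per subject: `subject_id`, `status`, `raw_prs`,
#'   `z_prs`, `prs_group`; control mean/SD as attributes.
#' @export
prs_stage <- function(cohort, weights = prs_weights(cohort$panel),
                      missing_policy = "mean_dosage_controls",
                      split_reference = c("cases", "all")) {
  split_reference <- match.arg(split_reference)
  raw <- compute_prs(cohort$genotypes, weights, missing_policy,
                     control_ids = control_ids(cohort))
  std <- standardize_prs(raw, control_ids(cohort))
  std$status <- cohort$subjects$status[match(std$subject_id,
                                             cohort$subjects$subject_id)]
  ref <- if (split_reference == "cases") std$z_prs[std$status == "case"]
         else std$z_prs
  std$prs_group <- median_split(std$z_prs, reference = ref)
  attr(std, "split_reference") <- split_reference
  std
}
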