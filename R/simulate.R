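#' Synthetic cohort generator
#'
#' Generates case-control cohorts with the statistical structure the
#' analysis assumes: Hardy-Weinberg genotypes at per-group effect-allele
#' frequencies (controls at the panel's published control frequencies, cases
#' at the published case frequencies — a marginal emulation of the
#' case-control contrast), demographic covariates matching the study
#' population, provoked/unprovoked strata and exponential two-year
#' recurrence times with a configurable hazard ratio between PRS groups.
#' Every draw is reproducible from `(config, seed)`.
#'
#' @name synthetic
NULL

#' Default simulation configuration
#'
#' Defaults reproduce the study conditions: 122 cases / 87 controls; the
#' bundled panel's case/control frequencies; age median 44.5 (IQR 32-57),
#' BMI 24.5 +/- 4.0, 55% male; 70.5% provoked cases; exponential recurrence
#' over a 24-month window with monthly baseline hazard 0.028 in the provoked
#' stratum (group HR 1) and 0.014 in the unprovoked low-PRS group with HR
#' 3.53 for high PRS, calibrated so the overall two-year recurrence fraction
#' is about 0.49.
#'
#' @param n_case,n_control Group sizes.
#' @param panel Panel with `eaf_case`/`eaf_control` columns (or supply
#'   `case_or` for logistic selection instead of marginal case frequencies).
#' @param case_or Optional per-variant conditional OR vector (named by rsid):
#'   cases are then drawn by logistic selection from the control frequencies
#'   rather than from marginal case frequencies. Supplying both case
#'   frequencies and `case_or` is an error at generation time.
#' @param age_median,age_iqr,bmi_mean,bmi_sd,male_fraction Covariate design.
#' @param diagnosis_probs DVT / PE / DVT_PE proportions among cases.
#' @param provoked_fraction Provoked share of cases.
#' @param hazard_provoked,hazard_unprovoked_low Monthly baseline hazards.
#' @param hr_provoked,hr_unprovoked High- vs low-PRS hazard ratio per stratum.
#' @param followup_cap Administrative censoring cap, months.
#' @param missing_rate Per-call missingness probability.
#' @param seed Master seed (integer).
#' @return Config list.
#' @export
sim_config <- function(n_case = 122L, n_control = 87L,
                       panel = load_panel(), case_or = NULL,
                       age_median = 44.5, age_iqr = c(32, 57),
                       bmi_mean = 24.5, bmi_sd = 4.0,
                       male_fraction = 0.55,
                       diagnosis_probs = c(DVT = 0.795, PE = 0.131,
                                           DVT_PE = 0.074),
                       provoked_fraction = 0.705,
                       hazard_provoked = 0.028,
                       hazard_unprovoked_low = 0.014,
                       hr_provoked = 1.0, hr_unprovoked = 3.53,
                       followup_cap = 24, missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1,
            hazard_provoked > 0, hazard_unprovoked_low > 0,
            missing_rate >= 0, missing_rate < 1)
  list(n_case = as.integer(n_case), n_control = as.integer(n_control),
       panel = panel, case_or = case_or,
       age_median = age_median, age_iqr = age_iqr,
       bmi_mean = bmi_mean, bmi_sd = bmi_sd, male_fraction = male_fraction,
       diagnosis_probs = diagnosis_probs,
       provoked_fraction = provoked_fraction,
       hazard_provoked = hazard_provoked,
       hazard_unprovoked_low = hazard_unprovoked_low,
       hr_provoked = hr_provoked, hr_unprovoked = hr_unprovoked,
       followup_cap = followup_cap, missing_rate = missing_rate,
       seed = as.integer(seed))
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Dosages drawn with genotype probabilities `(1-p)^2, 2p(1-p), p^2`.
#'
#' @param n Number of subjects.
#' @param eaf Effect-allele frequency in [0, 1].
#' @param seed Optional seed for a self-contained draw.
#' @return Integer dosage vector of length `n`.
#' @export
simulate_genotypes <- function(n, eaf, seed = NULL) {
  stopifnot(eaf >= 0, eaf <= 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE,
         prob = c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2))
}

# truncated-normal helper used for ages and BMI
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort with ground truth
#'
#' Controls are drawn at the panel's control frequencies; cases at the
#' panel's case frequencies (marginal emulation), or by logistic selection
#' when `config$case_or` is supplied. Case recurrence times are exponential
#' with stratum- and PRS-group-specific hazards (the generator computes each
#' case's literature-weighted PRS and median-splits to assign groups, so the
#' genotype-to-recurrence link the analysis estimates is present in the
#' data), censored at the follow-up cap.
#'
#' @param config From [sim_config()].
#' @return List with `cohort` (a `vte_cohort`) and `truth` (generating
#'   frequencies, true allelic ORs, hazards, group assignments, seed).
#' @export
generate_cohort <- function(config = sim_config()) {
  panel <- config$panel
  has_case_eaf <- "eaf_case" %in% names(panel) && !all(is.na(panel$eaf_case))
  if (!is.null(config$case_or) && has_case_eaf)
    stop("supply either case frequencies in the panel or case_or, not both")
  if (is.null(config$case_or) && !has_case_eaf)
    stop("panel lacks eaf_case and no case_or supplied")
  if (!"eaf_control" %in% names(panel))
    stop("panel lacks eaf_control")
  set.seed(config$seed)
  n_ca <- config$n_case; n_co <- config$n_control
  ids <- sprintf("S%04d", seq_len(n_ca + n_co))
  ca_ids <- ids[seq_len(n_ca)]
  co_ids <- ids[n_ca + seq_len(n_co)]

  gt <- matrix(NA_integer_, nrow(panel), n_ca + n_co,
               dimnames = list(panel$rsid, ids))
  for (i in seq_len(nrow(panel)))
    gt[i, co_ids] <- simulate_genotypes(n_co, panel$eaf_control[i])
  if (is.null(config$case_or)) {
    for (i in seq_len(nrow(panel)))
      gt[i, ca_ids] <- simulate_genotypes(n_ca, panel$eaf_case[i])
  } else {
    gt[, ca_ids] <- draw_cases_logistic(panel, config$case_or, n_ca)
  }

  subjects <- data.frame(
    subject_id = ids,
    status = c(rep("case", n_ca), rep("control", n_co)),
    age = round(rnorm_trunc(n_ca + n_co, config$age_median,
                            diff(config$age_iqr) / 1.349, 18, 95), 1),
    sex = ifelse(stats::runif(n_ca + n_co) < config$male_fraction,
                 "male", "female"),
    bmi = round(rnorm_trunc(n_ca + n_co, config$bmi_mean, config$bmi_sd,
                            15, 45), 1),
    diagnosis = NA_character_, risk_class = NA_character_,
    time_months = NA_real_, event = NA_integer_,
    stringsAsFactors = FALSE)
  subjects$diagnosis[seq_len(n_ca)] <-
    sample(names(config$diagnosis_probs), n_ca, replace = TRUE,
           prob = config$diagnosis_probs)
  subjects$risk_class[seq_len(n_ca)] <-
    ifelse(stats::runif(n_ca) < config$provoked_fraction,
           "provoked", "unprovoked")

  # PRS group drives the recurrence hazard: literature-weighted score of the
  # simulated genotypes, median split among cases
  w <- prs_weights(panel)
  raw_case <- compute_prs(gt[, ca_ids, drop = FALSE], w,
                          missing_policy = "zero")
  prs_group <- median_split(raw_case$raw_prs)

  hazard <- ifelse(subjects$risk_class[seq_len(n_ca)] == "provoked",
                   config$hazard_provoked *
                     ifelse(prs_group == "high", config$hr_provoked, 1),
                   config$hazard_unprovoked_low *
                     ifelse(prs_group == "high", config$hr_unprovoked, 1))
  t_event <- stats::rexp(n_ca, rate = hazard)
  cap <- config$followup_cap
  subjects$time_months[seq_len(n_ca)] <- round(pmin(t_event, cap), 2)
  subjects$event[seq_len(n_ca)] <- as.integer(t_event <= cap)

  if (config$missing_rate > 0) {
    mask <- stats::runif(length(gt)) < config$missing_rate
    gt[mask] <- NA_integer_
  }

  cohort <- assemble_cohort(panel, gt, subjects)
  eaf_co <- panel$eaf_control
  eaf_ca <- if (is.null(config$case_or)) panel$eaf_case else NA_real_
  true_or <- if (is.null(config$case_or)) {
    ifelse(eaf_ca > 0 & eaf_ca < 1 & eaf_co > 0 & eaf_co < 1,
           (eaf_ca / (1 - eaf_ca)) / (eaf_co / (1 - eaf_co)), NA_real_)
  } else {
    unname(config$case_or[panel$rsid])
  }
  truth <- list(seed = config$seed,
                eaf_case = eaf_ca, eaf_control = eaf_co,
                true_allelic_or = true_or, rsid = panel$rsid,
                prs_group_cases = stats::setNames(prs_group, ca_ids),
                hazard_provoked = config$hazard_provoked,
                hazard_unprovoked_low = config$hazard_unprovoked_low,
                hr_provoked = config$hr_provoked,
                hr_unprovoked = config$hr_unprovoked,
                followup_cap = cap)
  list(cohort = cohort, truth = truth)
}

# logistic selection of case genotypes: oversample at control frequencies,
# accept into the case pool with probability prop. to the conditional odds
draw_cases_logistic <- function(panel, case_or, n_case) {
  beta <- log(case_or[panel$rsid])
  if (any(is.na(beta))) stop("case_or must cover every panel rsid")
  got <- 0L
  out <- matrix(NA_integer_, nrow(panel), n_case,
                dimnames = list(panel$rsid, NULL))
  while (got < n_case) {
    m <- max(2L * (n_case - got), 50L)
    pool <- vapply(seq_len(nrow(panel)), function(i)
      simulate_genotypes(m, panel$eaf_control[i]), integer(m))
    score <- as.numeric(pool %*% beta)
    accept <- stats::runif(m) < stats::plogis(score - stats::median(score))
    take <- which(accept)[seq_len(min(sum(accept), n_case - got))]
    if (length(take) > 0L) {
      out[, got + seq_along(take)] <- t(pool[take, , drop = FALSE])
      got <- got + length(take)
    }
  }
  out
}

#' Write a cohort fixture to disk
#'
#' Emits `panel.tsv`, `cohort.vcf`, `phenotypes.tsv` and (when truth is
#' given) `truth.json` into `dir`. The VCF uses synthetic positions (the
#' panel is rsID-keyed; positions are bookkeeping only) and encodes the
#' panel's `-` deletion allele with an `A` anchor base. Files round-trip
#' through the readers to an equal cohort and are byte-identical for a fixed
#' seed.
#'
#' @param cohort A `vte_cohort`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list to serialize.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir, truth = NULL) {
  if (ncol(cohort$genotypes) == 0L) stop("empty cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  write_vcf(cohort$genotypes, cohort$panel, file.path(dir, "cohort.vcf"))
  write_phenotypes(cohort$subjects, file.path(dir, "phenotypes.tsv"))
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# minimal VCF 4.2 writer: GT-only, one synthetic position per panel variant
write_vcf <- function(dosage, panel, path) {
  idx <- match(rownames(dosage), panel$rsid)
  if (any(is.na(idx))) stop("dosage rows must match panel rsids")
  ref <- panel$reference_allele[idx]
  alt <- panel$effect_allele[idx]
  anchored <- ref == "-" | alt == "-"
  ref <- ifelse(ref == "-", "A", ifelse(anchored, paste0("A", ref), ref))
  alt <- ifelse(alt == "-", "A", ifelse(anchored, paste0("A", alt), alt))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(dosage)), function(i) {
    gts <- ifelse(is.na(dosage[i, ]), "./.",
                  gt_code[as.character(dosage[i, ])])
    paste(c("1", 1000L * i, rownames(dosage)[i], ref[i], alt[i],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vteprs synthetic cohort (positions are synthetic bookkeeping)",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a fixture directory back into a cohort
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `cohort` and `truth` (NULL when absent).
#' @export
read_fixture <- function(dir) {
  panel <- load_panel(file.path(dir, "panel.tsv"))
  gt <- read_genotypes_vcf(file.path(dir, "cohort.vcf"), panel)
  subjects <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path)
           else NULL
  list(cohort = assemble_cohort(panel, gt, subjects), truth = truth)
}
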