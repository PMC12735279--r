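#' Cohort assembly: genotypes joined to phenotypes
#'
#' Genotypes are held as an effect-allele dosage matrix (variants in rows,
#' subjects in columns, values 0/1/2 or NA) oriented to the panel's effect
#' allele. Phenotypes carry case/control status, the adjustment covariates
#' (age, sex, BMI) and, for cases, the diagnosis, provoked/unprovoked class
#' and the two-year recurrence follow-up record.
#'
#' @name cohort
NULL

#' Read a genotype dosage table
#'
#' TSV with rsIDs in the first column (`rsid`) and one column per subject;
#' cells must be 0, 1, 2 or NA (count of effect-allele copies).
#'
#' @param path Path to the TSV.
#' @param panel A `vte_panel`; every rsID in the file must be in the panel.
#' @return Integer matrix (rsID x subject) with NA for missing calls.
#' @export
read_genotype_table <- function(path, panel) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"rsid" %in% names(df)) stop("genotype table must have an 'rsid' column")
  rsids <- df$rsid
  mat <- as.matrix(df[, setdiff(names(df), "rsid"), drop = FALSE])
  bad <- which(!(is.na(mat) | mat %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid dosage '%s' at rsid %s, subject %s",
                 mat[bad[1, 1], bad[1, 2]], rsids[bad[1, 1]],
                 colnames(mat)[bad[1, 2]]))
  storage.mode(mat) <- "integer"
  rownames(mat) <- rsids
  check_matrix_against_panel(mat, panel)
  mat
}

#' Write a genotype dosage table
#' @param dosage rsID x subject integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(dosage, path) {
  df <- data.frame(rsid = rownames(dosage), dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_matrix_against_panel <- function(mat, panel) {
  extra <- setdiff(rownames(mat), panel$rsid)
  if (length(extra) > 0L)
    stop("genotype rsID(s) absent from panel: ", paste(extra, collapse = ", "))
  invisible(mat)
}

# Trim the longest common leading prefix of a REF/ALT pair so that VCF
# anchor-base indel encodings (e.g. T/TC) compare equal to the panel's
# "-"/"C" convention.
trim_common_prefix <- function(a, b) {
  a <- unname(a); b <- unname(b)
  n <- 0L
  while (n < min(nchar(a), nchar(b)) &&
         substr(a, n + 1L, n + 1L) == substr(b, n + 1L, n + 1L)) n <- n + 1L
  # keep at least an empty token, rendered as "-"
  norm <- function(x) { x <- substr(x, n + 1L, nchar(x)); if (x == "") "-" else x }
  c(norm(a), norm(b))
}

#' Read panel genotypes from a VCF file
#'
#' Sites are matched to the panel primarily by the VCF ID field; unmatched
#' panel variants are recorded as all-missing with a warning. Dosage counts
#' copies of the panel effect allele: when the VCF ALT allele is the effect
#' allele the ALT count is used directly, and when the orientation is flipped
#' (REF is the effect allele) the dosage is re-oriented as `2 - alt count`
#' with a message. Indel anchor bases are trimmed before allele comparison so
#' a `-` deletion allele matches its VCF encoding.
#'
#' @param path VCF 4.x file (plain or gzipped) with GT.
#' @param panel A `vte_panel`.
#' @return Integer dosage matrix (panel rsIDs x subjects).
#' @export
read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  subjects <- colnames(gt)
  mat <- matrix(NA_integer_, nrow = nrow(panel), ncol = length(subjects),
                dimnames = list(panel$rsid, subjects))
  for (i in seq_len(nrow(panel))) {
    j <- match(panel$rsid[i], fix[, "ID"])
    if (is.na(j)) {
      warning("panel variant ", panel$rsid[i],
              " absent from VCF; recorded as all-missing")
      next
    }
    alleles <- trim_common_prefix(fix[j, "REF"], fix[j, "ALT"])
    alt_count <- count_alt_alleles(gt[j, ])
    if (identical(alleles[2], panel$effect_allele[i])) {
      mat[i, ] <- alt_count
    } else if (identical(alleles[1], panel$effect_allele[i])) {
      message("VCF orientation flipped for ", panel$rsid[i],
              "; dosage re-oriented as 2 - ALT count")
      mat[i, ] <- 2L - alt_count
    } else {
      warning("alleles for ", panel$rsid[i], " (", fix[j, "REF"], "/",
              fix[j, "ALT"], ") do not match panel ", panel$effect_allele[i],
              "/", panel$reference_allele[i], "; treating ALT as effect allele")
      mat[i, ] <- alt_count
    }
  }
  mat
}

# Count ALT alleles in a vector of GT strings; non-parsable or missing -> NA.
count_alt_alleles <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & grepl("^[01]([/|][01])?$", gt)
  split_ok <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(split_ok, function(a) sum(a == "1"), integer(1))
  bad <- !is.na(gt) & !ok & !grepl("^\\.([/|]\\.)?$", gt)
  if (any(bad))
    warning("unparseable GT value(s), recorded as missing: ",
            paste(unique(gt[bad]), collapse = ", "))
  out
}

#' Read a phenotype table
#'
#' TSV with columns `subject_id`, `status` (case/control), `age`, `sex`
#' (male/female), `bmi`, and optionally `diagnosis` (DVT/PE/DVT_PE),
#' `risk_class` (provoked/unprovoked), `time_months`, `event` (0/1).
#' Diagnosis, risk class and follow-up may only be present for cases;
#' follow-up requires a non-negative time, and an event flag requires a time.
#'
#' @param path Path to the TSV.
#' @return A data frame of subjects, one row each.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("subject_id", "status", "age", "sex", "bmi")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("phenotype file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (opt in c("diagnosis", "risk_class", "time_months", "event"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  validate_subjects(df)
}

validate_subjects <- function(df) {
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id(s): ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad) > 0L) stop("status must be case/control, got: ",
                             paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$sex)), c("male", "female"))
  if (length(bad) > 0L) stop("sex must be male/female, got: ",
                             paste(bad, collapse = ", "))
  if (any(df$age < 0, na.rm = TRUE)) stop("negative age")
  if (any(df$bmi <= 0, na.rm = TRUE)) stop("non-positive BMI")
  bad <- setdiff(stats::na.omit(unique(df$diagnosis)), c("DVT", "PE", "DVT_PE"))
  if (length(bad) > 0L) stop("unknown diagnosis value(s): ",
                             paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$risk_class)),
                 c("provoked", "unprovoked"))
  if (length(bad) > 0L) stop("unknown risk_class value(s): ",
                             paste(bad, collapse = ", "))
  ctrl <- df$status == "control"
  case_only <- c("diagnosis", "risk_class", "time_months", "event")
  for (col in case_only) {
    offender <- df$subject_id[ctrl & !is.na(df[[col]])]
    if (length(offender) > 0L)
      stop("control subject(s) with case-only field '", col, "': ",
           paste(offender, collapse = ", "))
  }
  if (any(df$time_months < 0, na.rm = TRUE))
    stop("negative follow-up time for: ",
         paste(df$subject_id[!is.na(df$time_months) & df$time_months < 0],
               collapse = ", "))
  orphan_event <- !is.na(df$event) & is.na(df$time_months)
  if (any(orphan_event))
    stop("event flag without follow-up time for: ",
         paste(df$subject_id[orphan_event], collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$event)), c(0, 1))
  if (length(bad) > 0L) stop("event must be 0/1, got: ",
                             paste(bad, collapse = ", "))
  df
}

#' Write a phenotype table
#' @param subjects Subject data frame as returned by [read_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Assemble a cohort from panel, genotypes and phenotypes
#'
#' Joins the dosage matrix to the subject table. Subjects without genotypes
#' are dropped with a warning; genotyped ids with no phenotype row are an
#' error. For association use the cohort must contain at least one case and
#' one control; set `allow_one_class = TRUE` for PRS-only use.
#'
#' @param panel A `vte_panel`.
#' @param genotypes rsID x subject dosage matrix.
#' @param subjects Subject data frame.
#' @param allow_one_class Permit a cohort without both outcome classes.
#' @return A list of class `vte_cohort` with elements `panel`, `genotypes`,
#'   `subjects`.
#' @export
assemble_cohort <- function(panel, genotypes, subjects,
                            allow_one_class = FALSE) {
  validate_panel(panel)
  check_matrix_against_panel(genotypes, panel)
  subjects <- validate_subjects(subjects)
  orphan_gt <- setdiff(colnames(genotypes), subjects$subject_id)
  if (length(orphan_gt) > 0L)
    stop("genotyped subject(s) missing from phenotypes: ",
         paste(orphan_gt, collapse = ", "))
  keep <- subjects$subject_id %in% colnames(genotypes)
  if (!any(keep)) stop("no subjects shared between genotypes and phenotypes")
  if (any(!keep))
    warning(sum(!keep), " subject(s) without genotypes dropped: ",
            paste(subjects$subject_id[!keep], collapse = ", "))
  subjects <- subjects[keep, , drop = FALSE]
  rownames(subjects) <- NULL
  genotypes <- genotypes[, subjects$subject_id, drop = FALSE]
  n_case <- sum(subjects$status == "case")
  n_control <- sum(subjects$status == "control")
  if (!allow_one_class && (n_case == 0L || n_control == 0L))
    stop("cohort must contain at least one case and one control ",
         "(set allow_one_class = TRUE for PRS-only use)")
  structure(list(panel = panel, genotypes = genotypes, subjects = subjects),
            class = "vte_cohort")
}

#' @export
print.vte_cohort <- function(x, ...) {
  cat(sprintf(
    "<vte_cohort> %d variants x %d subjects (%d cases, %d controls)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    sum(x$subjects$status == "case"), sum(x$subjects$status == "control")))
  invisible(x)
}

case_ids <- function(cohort) {
  cohort$subjects$subject_id[cohort$subjects$status == "case"]
}
control_ids <- function(cohort) {
  cohort$subjects$subject_id[cohort$subjects$status == "control"]
}
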